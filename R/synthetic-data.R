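# Synthetic household survey generator.
#
# The generator builds a fully specified "truth" network for a model
# variant, draws complete records by ancestral sampling, and then removes
# the source-side block from a subset of records, emulating a field study
# in which some households' collection points were never sampled. Root
# marginals follow the study's printed frequencies; conditional tables that
# the study does not print are free parameters with monotone
# risk-increasing defaults (risk factors can only raise the detection
# probability).

#' Default root marginals of the truth network
#'
#' Probabilities are given over each node's canonical state order. Values
#' with a printed empirical counterpart follow it; the rest are documented
#' free parameters (see the methods vignette).
#'
#' @return Named list of probability vectors.
#' @export
default_marginals <- function() {
  list(
    still_practise_open_defecation = c(yes = 0.327, no = 0.673),
    livestock_nearby_house = c(yes = 0.667, no = 0.333),
    floor_cleanliness = c(dirty = 0.60, clean = 0.40),
    faeces_around = c(yes = 0.60, no = 0.40),
    garbage_around = c(yes = 0.89, no = 0.11),
    flies_around = c(yes = 0.70, no = 0.30),
    storage_covered = c(yes = 0.77, no = 0.23),
    storage_cracked = c(yes = 0.04, no = 0.96),
    place_of_storage = c(easy_to_contaminate = 0.51, not_easy_to_contaminate = 0.49),
    household_water_treatment = c(yes_treat = 0.56, no = 0.44),
    type_of_poc = c(piped = 0.318, well = 0.272, spring = 0.174,
                    river = 0.020, other = 0.216),
    fullness_level = c(almost_empty = 0.10, one_quarter = 0.15, half = 0.25,
                       three_quarter = 0.25, full = 0.25),
    # well-side SI variables (model 2); probability of the risk state
    cracked_structure = c(yes = 0.35, no = 0.65),
    livestock_nearby_poc = c(yes = 0.50, no = 0.50),
    proper_fencing = c(yes = 0.30, no = 0.70),
    excreta_garbage_nearby = c(yes = 0.40, no = 0.60),
    prone_to_erosion = c(yes = 0.35, no = 0.65),
    latrine_within_10m = c(yes = 0.25, no = 0.75)
  )
}

#' Default effect sizes of the truth network's conditional tables
#'
#' `poc_detect` gives P(detected at the source) by source type (model 1).
#' The remaining entries parameterize logistic risk scores: the POU outcome
#' uses `alpha_pou` plus `beta_poc` when the source water is contaminated,
#' `beta_hwt` when water is untreated, `beta_env`/`beta_storage` per level
#' of the contamination-chance intermediates (low = 0, moderate = 1,
#' high = 2), and `beta_fullness` scaled by emptiness (full = 0 ...
#' almost_empty = 1). Model 2's source table uses `alpha_poc_well` plus
#' `beta_well_si` per risk factor present. All are free parameters: the
#' study prints none of these tables.
#'
#' @return Named list of numeric effect parameters.
#' @export
default_effects <- function() {
  list(
    poc_detect = c(piped = 0.10, well = 0.42, spring = 0.10, river = 0.83,
                   other = 0.30),
    alpha_pou = -3.65,
    beta_poc = 1.3,
    beta_hwt = 0.47,
    beta_env = 0.32,
    beta_storage = 0.38,
    beta_fullness = 1.3,
    alpha_poc_well = -1.6,
    beta_well_si = 0.5
  )
}

#' Fully specified generating network for a model variant
#'
#' Builds the variant's structure, fixes root priors at the default
#' marginals, sets the source-water table (per-type detection rates for
#' model 1, a monotone logistic in the number of well-side risk factors for
#' model 2) and a monotone risk-increasing POU outcome table. A seed
#' multiplies the free logistic coefficients by small log-normal jitter
#' (sd 0.15 on the log scale), giving a family of plausible truths that all
#' share the printed marginals; `seed = NULL` returns the exact defaults.
#'
#' @param variant Variant tag or [model_variant()].
#' @param seed Optional jitter seed for the free effect parameters.
#' @param marginals Root marginals, as [default_marginals()].
#' @param effects Effect parameters, as [default_effects()].
#' @param semantics Index-rule direction mapping.
#' @return A `bbn` network with all CPTs specified (intermediates locked).
#' @export
default_truth <- function(variant, seed = NULL,
                          marginals = default_marginals(),
                          effects = default_effects(),
                          semantics = c("contamination_risk", "literal")) {
  variant <- model_variant(variant)
  net <- build_model(variant, semantics = match.arg(semantics))
  inv <- si_variables()
  states <- .net_states(net)

  if (!is.null(seed)) {
    jit <- with_seed(seed, stats::rlnorm(6, 0, 0.15))
    for (i in seq_along(c("beta_poc", "beta_hwt", "beta_env", "beta_storage",
                          "beta_fullness", "beta_well_si"))) {
      nm <- c("beta_poc", "beta_hwt", "beta_env", "beta_storage",
              "beta_fullness", "beta_well_si")[i]
      effects[[nm]] <- effects[[nm]] * jit[i]
    }
  }

  set_cpt <- function(name, prob) {
    dimnames(prob) <- dimnames(net$cpts[[name]]$prob)
    net$cpts[[name]]$prob <<- prob
  }

  # root priors
  for (v in names(net$nodes)) {
    cpt <- net$cpts[[v]]
    if (length(cpt$parents) || cpt$locked) next
    pr <- marginals[[v]]
    if (is.null(pr))
      stop_sibbn(sprintf("no default marginal for root node '%s'", v),
                 "sibbn_invalid_config")
    if (!identical(names(pr), states[[v]]))
      stop_sibbn(sprintf("marginal for '%s' must be named in canonical state order", v),
                 "sibbn_invalid_config")
    set_cpt(v, matrix(as.numeric(pr), nrow = 1))
  }

  # source-water quality
  if (variant$poc_mode == "type") {
    det <- effects$poc_detect[states$type_of_poc]
    set_cpt("ecoli_poc", cbind(detected = unname(det),
                               not_detected = 1 - unname(det)))
  } else {
    grid <- parent_grid(states[.WELL_SI_PARENTS])
    names(grid) <- .WELL_SI_PARENTS
    nrisk <- rowSums(vapply(.WELL_SI_PARENTS, function(p)
      as.integer(grid[[p]] != inv[[p]]$best_state), integer(nrow(grid))))
    det <- stats::plogis(effects$alpha_poc_well + effects$beta_well_si * nrisk)
    set_cpt("ecoli_poc", cbind(detected = det, not_detected = 1 - det))
  }

  # POU outcome: logistic risk score over its parents
  out_parents <- net$cpts$ecoli_pou$parents
  grid <- parent_grid(states[out_parents])
  names(grid) <- out_parents
  level <- c(low = 0, moderate = 1, high = 2)
  empt <- c(almost_empty = 1, one_quarter = 0.75, half = 0.5,
            three_quarter = 0.25, full = 0)
  lp <- effects$alpha_pou +
    effects$beta_poc * (grid$ecoli_poc == "detected") +
    effects$beta_hwt * (grid$household_water_treatment == "no") +
    effects$beta_env * level[grid$chance_contamination_environment] +
    effects$beta_storage * level[grid$chance_contamination_storage]
  if (variant$fullness_included)
    lp <- lp + effects$beta_fullness * empt[grid$fullness_level]
  det <- stats::plogis(unname(lp))
  set_cpt("ecoli_pou", cbind(detected = det, not_detected = 1 - det))

  build_network(net$nodes, net$cpts) -> out
  out$variant <- variant$tag
  out$semantics <- net$semantics
  out
}

#' Draw survey records from a network by ancestral sampling
#'
#' Samples n complete records node by node in topological order;
#' intermediate nodes, having deterministic tables, always equal the index
#' of their sampled parents. Reproducible per seed.
#'
#' @param truth A fully specified `bbn` network.
#' @param n Number of records.
#' @param seed Sampling seed.
#' @return Data frame with one character column per node and attribute
#'   `variant` copied from the network (if present).
#' @export
sample_table <- function(truth, n, seed = 1) {
  stopifnot(inherits(truth, "bbn"), n >= 1)
  states <- .net_states(truth)
  comp <- .compile_net(truth)
  m <- matrix(NA_integer_, n, length(comp$names),
              dimnames = list(NULL, comp$names))
  with_seed(seed, {
    for (v in truth$order) {
      fam <- comp$fam[[v]]
      ridx <- .row_index(m[, fam$pid, drop = FALSE], fam$strides)
      p <- fam$prob[ridx, , drop = FALSE]
      cum <- p %*% upper.tri(diag(ncol(p)), diag = TRUE)
      u <- stats::runif(n)
      m[, v] <- 1L + as.integer(rowSums(u > cum))
    }
  })
  out <- as.data.frame(lapply(stats::setNames(comp$names, comp$names),
                              function(v) states[[v]][m[, v]]),
                       stringsAsFactors = FALSE)
  attr(out, "variant") <- truth$variant
  out
}

#' Source-side variable block of a variant
#'
#' The fields that are jointly absent when a household's collection point
#' was not visited: the source descriptors plus the source water-quality
#' result.
#'
#' @param variant Variant tag or [model_variant()].
#' @return Character vector of node names.
#' @export
poc_block <- function(variant) {
  variant <- model_variant(variant)
  c(if (variant$poc_mode == "type") "type_of_poc" else .WELL_SI_PARENTS,
    "ecoli_poc")
}

#' Remove the source-side block from a random subset of records
#'
#' Sets every field of the source block to missing in `poc_missing` records
#' chosen uniformly at random (missing completely at random); all other
#' fields are untouched, so a record is either fully observed on the source
#' side or not at all.
#'
#' @param table Survey data frame (as from [sample_table()]).
#' @param poc_missing Number of records to blank, `0 <= poc_missing <= n`.
#' @param seed Selection seed.
#' @param block Columns forming the source block; defaults to
#'   [poc_block()] of the table's variant attribute, or, failing that, the
#'   source columns present in the table.
#' @return The table with the block set to `NA` in the selected records and
#'   attribute `poc_missing_rows` recording their indices.
#' @export
apply_missingness <- function(table, poc_missing, seed = 1, block = NULL) {
  n <- nrow(table)
  if (poc_missing < 0 || poc_missing > n)
    stop_sibbn("poc_missing must lie between 0 and the record count",
               "sibbn_invalid_config")
  if (is.null(block)) {
    block <- if (!is.null(attr(table, "variant"))) poc_block(attr(table, "variant"))
             else intersect(c("type_of_poc", .WELL_SI_PARENTS, "ecoli_poc"),
                            names(table))
  }
  miss <- setdiff(block, names(table))
  if (length(miss))
    stop_sibbn(sprintf("block column(s) absent from the table: %s",
                       paste(miss, collapse = ", ")), "sibbn_invalid_config")
  if (poc_missing == 0) {
    attr(table, "poc_missing_rows") <- integer(0)
    return(table)
  }
  rows <- with_seed(seed, sort(sample.int(n, poc_missing)))
  table[rows, block] <- NA_character_
  attr(table, "poc_missing_rows") <- rows
  table
}

#' Generate a complete synthetic study: truth, records, missingness
#'
#' Convenience wrapper reproducing the emulated study conditions in one
#' call: a truth network for the variant, `n` sampled households, and the
#' source block removed from `poc_missing` of them.
#'
#' @param variant Variant tag or [model_variant()].
#' @param n Number of households (default 328, the emulated study size).
#' @param poc_missing Records without source-side data (default 49).
#' @param seed Master seed; the truth jitter, sampling and missingness draws
#'   use distinct streams derived from it.
#' @param jitter_truth Logical; if `TRUE` (default) the truth's free effect
#'   parameters are jittered from the seed, see [default_truth()].
#' @return An object of class `truth_bundle`: list with `truth` (the
#'   generating `bbn`), `table` (the survey records with missingness
#'   applied), `complete` (the records before missingness) and
#'   `missing_rows`.
#' @export
simulate_survey <- function(variant, n = 328, poc_missing = 49, seed = 1,
                            jitter_truth = TRUE) {
  variant <- model_variant(variant)
  truth <- default_truth(variant, seed = if (jitter_truth) seed else NULL)
  complete <- sample_table(truth, n, seed = seed + 1L)
  table <- apply_missingness(complete, poc_missing, seed = seed + 2L)
  structure(list(truth = truth, table = table, complete = complete,
                 missing_rows = attr(table, "poc_missing_rows"),
                 variant = variant$tag, seed = seed),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf("Synthetic survey: variant %s, %d households, %d without source data (seed %s)\n",
              x$variant, nrow(x$table), length(x$missing_rows), format(x$seed)))
  invisible(x)
}
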