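# The four sanitary-inspection network variants.
#
# Outer SI variables are binary and scored: the state describing the best
# (lowest-risk) situation earns 1 point. Each cluster sums its parents'
# scores into a deterministic three-level intermediate node giving the
# chance of (re)contamination from that pathway. Model 1 explains source
# water quality by the type of source (piped/well/spring/river/other);
# model 2 restricts to wells and uses six well-side SI variables instead.
# "B" variants add the storage fullness level, an external (non-SI)
# variable, as a further parent of the outcome.

.CATEGORIES <- c("low", "moderate", "high")

#' Sanitary-inspection variable inventory
#'
#' Every variable used by the four model variants: its name, its states (in
#' canonical order), the state awarded score 1 (the best situation; `NA` for
#' variables that are not additively scored), its cluster and its node role.
#'
#' @return A named list of `si_variable` records, each a list with fields
#'   `name`, `states`, `best_state`, `cluster`, `role`.
#' @export
si_variables <- function() {
  v <- function(name, states, best_state, cluster, role = "outer_SI")
    structure(list(name = name, states = states, best_state = best_state,
                   cluster = cluster, role = role), class = "si_variable")
  vars <- list(
    # surrounding environment / hygiene cluster (six scored parents)
    v("still_practise_open_defecation", c("yes", "no"), "no", "environment_hygiene"),
    v("livestock_nearby_house", c("yes", "no"), "no", "environment_hygiene"),
    v("floor_cleanliness", c("dirty", "clean"), "clean", "environment_hygiene"),
    v("faeces_around", c("yes", "no"), "no", "environment_hygiene"),
    v("garbage_around", c("yes", "no"), "no", "environment_hygiene"),
    v("flies_around", c("yes", "no"), "no", "environment_hygiene"),
    # water storage cluster (three scored parents)
    v("storage_covered", c("yes", "no"), "yes", "water_storage"),
    v("storage_cracked", c("yes", "no"), "no", "water_storage"),
    v("place_of_storage", c("easy_to_contaminate", "not_easy_to_contaminate"),
      "not_easy_to_contaminate", "water_storage"),
    # household water treatment
    v("household_water_treatment", c("yes_treat", "no"), "yes_treat", "hwt",
      role = "treatment"),
    # point-of-collection cluster, model 1: type of source
    v("type_of_poc", c("piped", "well", "spring", "river", "other"), NA_character_,
      "poc"),
    # point-of-collection cluster, model 2: well-side SI variables
    v("cracked_structure", c("yes", "no"), "no", "poc"),
    v("livestock_nearby_poc", c("yes", "no"), "no", "poc"),
    v("proper_fencing", c("yes", "no"), "yes", "poc"),
    v("excreta_garbage_nearby", c("yes", "no"), "no", "poc"),
    v("prone_to_erosion", c("yes", "no"), "no", "poc"),
    v("latrine_within_10m", c("yes", "no"), "no", "poc"),
    # external variable (B variants)
    v("fullness_level", c("almost_empty", "one_quarter", "half", "three_quarter",
                          "full"), "full", "external", role = "external"),
    # water-quality nodes
    v("ecoli_poc", c("detected", "not_detected"), "not_detected", "poc",
      role = "water_quality"),
    v("ecoli_pou", c("detected", "not_detected"), NA_character_, "external",
      role = "water_quality")
  )
  stats::setNames(vars, vapply(vars, `[[`, character(1), "name"))
}

.ENV_PARENTS <- c("still_practise_open_defecation", "livestock_nearby_house",
                  "floor_cleanliness", "faeces_around", "garbage_around",
                  "flies_around")
.STORAGE_PARENTS <- c("storage_covered", "storage_cracked", "place_of_storage")
.WELL_SI_PARENTS <- c("cracked_structure", "livestock_nearby_poc", "proper_fencing",
                      "excreta_garbage_nearby", "prone_to_erosion",
                      "latrine_within_10m")

#' Score one sanitary-inspection observation
#'
#' Score 1 is awarded when the observed state equals the variable's best
#' (lowest-risk) state, e.g. 1 for "yes" on storage covered and 1 for "no"
#' on storage cracked; any other legal state scores 0.
#'
#' @param var An `si_variable` (from [si_variables()]) or a variable name.
#' @param observed Observed state label.
#' @return Integer 0 or 1.
#' @export
score_variable <- function(var, observed) {
  if (is.character(var)) {
    inv <- si_variables()
    if (!(var %in% names(inv)))
      stop_sibbn(sprintf("unknown SI variable '%s'", var), "sibbn_unknown_node")
    var <- inv[[var]]
  }
  stopifnot(inherits(var, "si_variable"))
  if (!(observed %in% var$states))
    stop_sibbn(sprintf("unknown state '%s' for variable '%s'", observed, var$name),
               "sibbn_unknown_state")
  if (is.na(var$best_state))
    stop_sibbn(sprintf("variable '%s' is not additively scored", var$name),
               "sibbn_not_scored")
  as.integer(observed == var$best_state)
}

#' Build an index rule for a cluster's intermediate node
#'
#' A rule maps the total score of a cluster's parents to one of three
#' categories. `cuts` gives the literal score bands (as quoted cut-offs,
#' e.g. storage: 0-1 / 2 / 3); under the default contamination-risk
#' semantics a *high* total (good hygiene) maps to a *low* chance of
#' contamination, i.e. the band labels `low` and `high` are swapped
#' relative to the literal reading. `semantics = "literal"` keeps the bands
#' exactly as written.
#'
#' @param parents Character vector of scored parent variable names.
#' @param cuts Named list `low`/`moderate`/`high` of integer score values;
#'   together the bands must partition `0:length(parents)`.
#' @param semantics `"contamination_risk"` (default) or `"literal"`.
#' @return An object of class `index_rule`.
#' @export
index_rule <- function(parents, cuts,
                       semantics = c("contamination_risk", "literal")) {
  semantics <- match.arg(semantics)
  stopifnot(is.character(parents), length(parents) >= 1)
  if (!setequal(names(cuts), .CATEGORIES))
    stop_sibbn("cuts must have exactly the names low, moderate, high",
               "sibbn_invalid_rule")
  all_scores <- sort(unlist(cuts))
  if (!identical(as.integer(all_scores), 0:length(parents)))
    stop_sibbn(sprintf(
      "cut-offs must partition 0..%d with no gaps or overlaps", length(parents)),
      "sibbn_invalid_rule")
  structure(list(parents = parents,
                 cuts = lapply(cuts, as.integer),
                 semantics = semantics),
            class = "index_rule")
}

#' The storage-cluster rule (cut-offs 0-1 / 2 / 3)
#' @inheritParams index_rule
#' @return An `index_rule` over the three storage-condition variables.
#' @export
storage_rule <- function(semantics = c("contamination_risk", "literal")) {
  index_rule(.STORAGE_PARENTS,
             cuts = list(low = 0:1, moderate = 2L, high = 3L),
             semantics = match.arg(semantics))
}

#' The environment-hygiene cluster rule (cut-offs 0-2 / 3-4 / 5-6)
#' @inheritParams index_rule
#' @return An `index_rule` over the six environment-hygiene variables.
#' @export
environment_rule <- function(semantics = c("contamination_risk", "literal")) {
  index_rule(.ENV_PARENTS,
             cuts = list(low = 0:2, moderate = 3:4, high = 5:6),
             semantics = match.arg(semantics))
}

#' Map a vector of scores to the cluster category
#'
#' Sums the parents' 0/1 scores and maps the total through the rule's bands
#' and semantics.
#'
#' @param rule An [index_rule()].
#' @param scores Integer vector of 0/1 scores, one per rule parent.
#' @return `"low"`, `"moderate"` or `"high"` (chance of contamination under
#'   the default semantics; literal band label otherwise).
#' @export
cluster_index <- function(rule, scores) {
  stopifnot(inherits(rule, "index_rule"))
  if (length(scores) != length(rule$parents))
    stop_sibbn(sprintf("expected %d scores, got %d",
                       length(rule$parents), length(scores)), "sibbn_invalid_rule")
  if (!all(scores %in% c(0L, 1L)))
    stop_sibbn("scores must all be 0 or 1", "sibbn_invalid_rule")
  total <- sum(scores)
  lit <- .CATEGORIES[vapply(.CATEGORIES,
                            function(lb) total %in% rule$cuts[[lb]], logical(1))]
  if (rule$semantics == "literal") return(lit)
  c(low = "high", moderate = "moderate", high = "low")[[lit]]
}

#' Deterministic (locked) CPT of an intermediate node
#'
#' One row per combination of the parents' states; all probability mass on
#' the category given by [cluster_index()] for that combination. The table
#' is locked so parameter learning leaves it untouched, mirroring a manually
#' populated index table.
#'
#' @param rule An [index_rule()].
#' @param child Name of the intermediate node.
#' @param variables Variable inventory (defaults to [si_variables()]).
#' @return A locked [bbn_cpt()] over the states low/moderate/high.
#' @export
deterministic_cpt <- function(rule, child, variables = si_variables()) {
  stopifnot(inherits(rule, "index_rule"))
  vars <- variables[rule$parents]
  if (any(vapply(vars, is.null, logical(1))))
    stop_sibbn("rule parents missing from the variable inventory", "sibbn_unknown_node")
  pstates <- lapply(vars, `[[`, "states")
  grid <- parent_grid(pstates)
  names(grid) <- rule$parents
  prob <- matrix(0, nrow(grid), length(.CATEGORIES),
                 dimnames = list(NULL, .CATEGORIES))
  for (i in seq_len(nrow(grid))) {
    scores <- vapply(rule$parents, function(p)
      score_variable(vars[[p]], grid[i, p]), integer(1))
    prob[i, cluster_index(rule, scores)] <- 1
  }
  bbn_cpt(child, parents = rule$parents, prob = prob, locked = TRUE)
}

#' Dichotomize an E. coli plate count
#'
#' @param cfu Non-negative integer count(s) of colony-forming units per 1 ml.
#' @return `"not_detected"` where the count is 0, `"detected"` otherwise.
#' @export
discretize_ecoli <- function(cfu) {
  if (any(is.na(cfu)) || any(cfu < 0))
    stop_sibbn("CFU counts must be non-negative", "sibbn_invalid_value")
  ifelse(cfu == 0, "not_detected", "detected")
}

#' Model variant descriptor
#'
#' The tag fully determines the variant: models 1A/1B explain source-water
#' quality by the type of source, models 2A/2B by six well-side SI
#' variables; B variants additionally include the storage fullness level as
#' a parent of the outcome.
#'
#' @param tag One of `"1A"`, `"1B"`, `"2A"`, `"2B"` (or an existing
#'   `model_variant`, returned as is).
#' @return An object of class `model_variant` with fields `tag`, `poc_mode`
#'   (`"type"` or `"well_si"`) and `fullness_included`.
#' @export
model_variant <- function(tag) {
  if (inherits(tag, "model_variant")) return(tag)
  tag <- as.character(tag)
  if (!(tag %in% c("1A", "1B", "2A", "2B")))
    stop_sibbn(sprintf("unknown model variant '%s' (use 1A, 1B, 2A or 2B)", tag),
               "sibbn_invalid_variant")
  structure(list(tag = tag,
                 poc_mode = if (substr(tag, 1, 1) == "1") "type" else "well_si",
                 fullness_included = substr(tag, 2, 2) == "B"),
            class = "model_variant")
}

# node set of a variant, in insertion order
.variant_nodes <- function(variant) {
  variant <- model_variant(variant)
  poc <- if (variant$poc_mode == "type") "type_of_poc" else .WELL_SI_PARENTS
  c(.ENV_PARENTS, "chance_contamination_environment",
    .STORAGE_PARENTS, "chance_contamination_storage",
    "household_water_treatment", poc, "ecoli_poc",
    if (variant$fullness_included) "fullness_level",
    "ecoli_pou")
}

# parents of the POU outcome node
.outcome_parents <- function(variant) {
  variant <- model_variant(variant)
  c("ecoli_poc", "household_water_treatment",
    "chance_contamination_environment", "chance_contamination_storage",
    if (variant$fullness_included) "fullness_level")
}

#' Build a model variant as a network specification
#'
#' Assembles the structure of one of the four variants: the six
#' environment-hygiene variables feeding a locked intermediate, the three
#' storage variables feeding a second locked intermediate, household water
#' treatment, the source-water side per the variant's mode, optionally the
#' fullness level, and the POU outcome with parents \{E. coli at POC, HWT,
#' both intermediates\} (+ fullness for B variants). All unlocked CPTs are
#' initialized via [initialize_cpts()].
#'
#' @param variant Variant tag or [model_variant()].
#' @param init `"uniform"` or `"random"` initialization of unlocked tables.
#' @param seed Seed for random initialization.
#' @param semantics Direction mapping for the index rules, see [index_rule()].
#' @return A validated `bbn` network; its `variant` field records the tag.
#' @export
build_model <- function(variant, init = c("uniform", "random"), seed = NULL,
                        semantics = c("contamination_risk", "literal")) {
  variant <- model_variant(variant)
  init <- match.arg(init)
  semantics <- match.arg(semantics)
  inv <- si_variables()
  node_names <- .variant_nodes(variant)

  nodes <- list()
  cpts <- list()
  add_root <- function(name) {
    vr <- inv[[name]]
    nodes[[name]] <<- bbn_node(name, vr$states, role = vr$role)
    k <- length(vr$states)
    cpts[[name]] <<- bbn_cpt(name, prob = rep(1 / k, k))
  }
  for (nm in setdiff(node_names,
                     c("chance_contamination_environment",
                       "chance_contamination_storage", "ecoli_poc", "ecoli_pou")))
    add_root(nm)

  nodes$chance_contamination_environment <-
    bbn_node("chance_contamination_environment", .CATEGORIES, role = "intermediate")
  cpts$chance_contamination_environment <-
    deterministic_cpt(environment_rule(semantics), "chance_contamination_environment", inv)
  nodes$chance_contamination_storage <-
    bbn_node("chance_contamination_storage", .CATEGORIES, role = "intermediate")
  cpts$chance_contamination_storage <-
    deterministic_cpt(storage_rule(semantics), "chance_contamination_storage", inv)

  poc_parents <- if (variant$poc_mode == "type") "type_of_poc" else .WELL_SI_PARENTS
  nodes$ecoli_poc <- bbn_node("ecoli_poc", inv$ecoli_poc$states, role = "water_quality")
  nrow_poc <- prod(vapply(inv[poc_parents], function(x) length(x$states), integer(1)))
  cpts$ecoli_poc <- bbn_cpt("ecoli_poc", parents = poc_parents,
                            prob = matrix(0.5, nrow_poc, 2))

  out_parents <- .outcome_parents(variant)
  sizes <- vapply(out_parents, function(p) length(nodes[[p]]$states), integer(1))
  nodes$ecoli_pou <- bbn_node("ecoli_pou", inv$ecoli_pou$states, role = "water_quality")
  cpts$ecoli_pou <- bbn_cpt("ecoli_pou", parents = out_parents,
                            prob = matrix(0.5, prod(sizes), 2))

  net <- build_network(nodes[node_names], cpts[node_names])
  net <- initialize_cpts(net, mode = init, seed = seed)
  net$variant <- variant$tag
  net$semantics <- semantics
  net
}
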