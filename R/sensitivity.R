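# Predictive inference (delta-P sweeps) and what-if scenario simulation.

#' Spread of a set of updated probabilities
#'
#' The delta-P summary of one node: the difference between the highest and
#' lowest updated outcome probability across the node's states. `NA` entries
#' (states that could not be asserted) are ignored.
#'
#' @param values Numeric vector of updated probabilities (any scale).
#' @return `max(values) - min(values)`.
#' @examples
#' delta_p(c(56, 77))                  # 21
#' delta_p(c(58, 64, 70, 75, 74))      # 17
#' @export
delta_p <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values))
    stop_sibbn("delta_p needs at least one non-missing value", "sibbn_invalid_value")
  max(values) - min(values)
}

#' Node-by-node predictive inference sweep
#'
#' For every node other than the outcome and every one of its states, sets
#' that state as hard evidence (posterior mass 1), recomputes the outcome
#' posterior, and records the designated state's updated probability in
#' percent. Per node, delta-P is the spread (max - min) across its states.
#' States with zero prior probability cannot be asserted; they are reported
#' as `NA` with a warning and excluded from the spread.
#'
#' @param net A fitted `bbn` network.
#' @param outcome Outcome node name.
#' @param designated Outcome state whose updated probability is tracked
#'   (default `"not_detected"`, the reporting convention of the sweep
#'   tables).
#' @return An object of class `delta_p_table`: list with `table` (data frame
#'   node/state/updated_pct), `delta_p` (named per-node spread, percentage
#'   points), `baseline_pct` (no-evidence outcome probability, percent),
#'   `outcome`, `designated`.
#' @export
predictive_inference <- function(net, outcome = "ecoli_pou",
                                 designated = "not_detected") {
  stopifnot(inherits(net, "bbn"))
  if (!(outcome %in% names(net$nodes)))
    stop_sibbn(sprintf("unknown outcome node '%s'", outcome), "sibbn_unknown_node")
  if (!(designated %in% net$nodes[[outcome]]$states))
    stop_sibbn(sprintf("'%s' is not a state of '%s'", designated, outcome),
               "sibbn_unknown_state")
  baseline <- 100 * posterior(net, outcome)$posterior[[designated]]
  nodes <- setdiff(net$order, outcome)
  rows <- list()
  dp <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    prior <- posterior(net, v)$posterior
    upd <- stats::setNames(rep(NA_real_, length(prior)), names(prior))
    for (s in names(prior)) {
      if (prior[[s]] <= 0) {
        warning(sprintf("state '%s' of node '%s' has zero prior probability; skipped",
                        s, v), call. = FALSE)
        next
      }
      ev <- stats::setNames(s, v)
      upd[[s]] <- 100 * posterior(net, outcome, evidence = ev)$posterior[[designated]]
    }
    dp[[v]] <- delta_p(upd)
    rows[[v]] <- data.frame(node = v, state = names(upd),
                            updated_pct = unname(upd))
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 delta_p = dp, baseline_pct = unname(baseline),
                 outcome = outcome, designated = designated),
            class = "delta_p_table")
}

#' @export
print.delta_p_table <- function(x, digits = 0, ...) {
  cat(sprintf("Predictive inference sweep: P(%s = %s), baseline %.1f%%\n",
              x$outcome, x$designated, x$baseline_pct))
  ord <- names(sort(x$delta_p, decreasing = TRUE))
  for (v in ord) {
    tb <- x$table[x$table$node == v, ]
    cat(sprintf("  %-36s dP = %4.1f  [%s]\n", v, x$delta_p[[v]],
                paste(sprintf("%s: %s", tb$state,
                              ifelse(is.na(tb$updated_pct), "NA",
                                     formatC(tb$updated_pct, digits = digits,
                                             format = "f"))),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write a delta-P table as delimited text
#'
#' One row per (node, state) with the updated probability and the node's
#' delta-P, mirroring the layout of a predictive-inference summary table.
#'
#' @param x A `delta_p_table`.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_delta_p <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "delta_p_table"))
  out <- x$table
  out$delta_p <- x$delta_p[out$node]
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a what-if scenario
#'
#' Asserts the scenario's states as joint hard evidence and reports the
#' updated probability of the designated outcome state (percent) next to the
#' no-evidence baseline.
#'
#' @param net A fitted `bbn` network.
#' @param scenario Named character vector/list mapping nodes to asserted
#'   states; must not assert the outcome.
#' @param outcome Outcome node name.
#' @param designated Outcome state to report.
#' @return List with `updated_pct`, `baseline_pct`, `evidence`, `outcome`,
#'   `designated` (class `sibbn_scenario`).
#' @export
run_scenario <- function(net, scenario, outcome = "ecoli_pou",
                         designated = "not_detected") {
  stopifnot(inherits(net, "bbn"))
  ev <- .check_evidence(net, scenario)
  if (outcome %in% names(ev))
    stop_sibbn("the scenario must not assert the outcome node", "sibbn_bad_evidence")
  baseline <- 100 * posterior(net, outcome)$posterior[[designated]]
  upd <- if (length(ev))
    100 * posterior(net, outcome, evidence = ev)$posterior[[designated]]
  else baseline
  structure(list(updated_pct = unname(upd), baseline_pct = unname(baseline),
                 evidence = ev, outcome = outcome, designated = designated),
            class = "sibbn_scenario")
}

#' @export
print.sibbn_scenario <- function(x, ...) {
  cat(sprintf("Scenario: P(%s = %s) = %.1f%% (baseline %.1f%%), %d node(s) asserted\n",
              x$outcome, x$designated, x$updated_pct, x$baseline_pct,
              length(x$evidence)))
  invisible(x)
}

#' Best-case scenario of a model variant
#'
#' Asserts the best (score-1) state of every scored outer SI variable
#' present in the variant, household water treatment performed, no E. coli
#' detected at the source, and (for B variants) a full storage container.
#' Intermediate nodes are never asserted: their deterministic tables imply
#' them from the outer nodes.
#'
#' @param variant Variant tag or [model_variant()].
#' @return Named character vector usable as the `scenario` of
#'   [run_scenario()].
#' @export
best_states <- function(variant) {
  variant <- model_variant(variant)
  inv <- si_variables()
  nodes <- setdiff(.variant_nodes(variant),
                   c("chance_contamination_environment",
                     "chance_contamination_storage", "ecoli_pou"))
  sc <- character(0)
  for (v in nodes) {
    best <- inv[[v]]$best_state
    if (!is.na(best)) sc[v] <- best
  }
  sc
}
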