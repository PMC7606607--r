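# Exact inference by variable elimination.
#
# Factors are plain R arrays whose dimnames carry the variable names and
# state labels (always in the declared canonical order). Probabilities stay
# in linear space with one normalization at the end: the networks handled
# here are small (<= ~20 nodes), so underflow is not a practical concern and
# linear space keeps results directly comparable with brute-force
# enumeration.

.factor_vars <- function(f) names(dimnames(f))

# CPT -> factor array over c(parents, child); column-major fill matches the
# canonical row order (first parent fastest, child slowest).
.cpt_factor <- function(net, node) {
  cpt <- net$cpts[[node]]
  states <- .net_states(net)
  dn <- c(states[cpt$parents], stats::setNames(list(states[[node]]), node))
  array(as.vector(cpt$prob), dim = vapply(dn, length, integer(1)), dimnames = dn)
}

# Condition a factor on evidence: fix observed dimensions, drop them.
# Returns a scalar if every dimension is observed.
.f_reduce <- function(f, ev) {
  vars <- .factor_vars(f)
  hit <- intersect(vars, names(ev))
  if (!length(hit)) return(f)
  idx <- lapply(vars, function(v) if (v %in% hit) ev[[v]] else TRUE)
  out <- do.call(`[`, c(list(f), idx, list(drop = FALSE)))
  keep <- !(vars %in% hit)
  if (!any(keep)) return(as.vector(out))
  array(as.vector(out), dim = dim(out)[keep], dimnames = dimnames(out)[keep])
}

# Product of two factors over the union of their scopes. `states` is the
# network-wide state list so the result dimensions keep canonical state order.
.f_product <- function(f1, f2, states) {
  if (!is.array(f1)) return(f2 * as.vector(f1))
  if (!is.array(f2)) return(f1 * as.vector(f2))
  v1 <- .factor_vars(f1); v2 <- .factor_vars(f2)
  vars <- union(v1, v2)
  dn <- states[vars]
  grid <- parent_grid(dn)
  names(grid) <- vars
  a1 <- f1[as.matrix(grid[, v1, drop = FALSE])]
  a2 <- f2[as.matrix(grid[, v2, drop = FALSE])]
  array(a1 * a2, dim = vapply(dn, length, integer(1)), dimnames = dn)
}

# Sum a variable out of a factor.
.f_marginalize <- function(f, var) {
  vars <- .factor_vars(f)
  rest <- setdiff(vars, var)
  if (!length(rest)) return(sum(f))
  p <- aperm(f, c(rest, var))
  d <- dim(p)
  m <- matrix(p, nrow = prod(d[-length(d)]), ncol = d[length(d)])
  array(rowSums(m), dim = d[-length(d)], dimnames = dimnames(p)[rest])
}

# Min-degree elimination order over the moralized interaction graph implied
# by the current factor scopes; ties broken by node-name order.
.elim_order <- function(scopes, elim) {
  ord <- character(0)
  remaining <- sort(elim)
  while (length(remaining)) {
    deg <- vapply(remaining, function(v) {
      hit <- vapply(scopes, function(s) v %in% s, logical(1))
      length(setdiff(unique(unlist(scopes[hit])), v))
    }, integer(1))
    v <- remaining[order(deg, remaining)][1]
    hit <- vapply(scopes, function(s) v %in% s, logical(1))
    scopes <- c(scopes[!hit],
                list(setdiff(unique(unlist(scopes[hit])), v)))
    ord <- c(ord, v)
    remaining <- setdiff(remaining, v)
  }
  ord
}

.check_evidence <- function(net, ev) {
  if (is.null(ev) || !length(ev)) return(stats::setNames(character(0), character(0)))
  ev <- unlist(ev)
  states <- .net_states(net)
  bad <- setdiff(names(ev), names(net$nodes))
  if (length(bad))
    stop_sibbn(sprintf("evidence names unknown node(s): %s",
                       paste(bad, collapse = ", ")), "sibbn_unknown_node")
  if (anyDuplicated(names(ev)))
    stop_sibbn("evidence sets the same node twice", "sibbn_bad_evidence")
  for (v in names(ev)) {
    if (!(ev[[v]] %in% states[[v]]))
      stop_sibbn(sprintf("unknown state '%s' for node '%s'", ev[[v]], v),
                 "sibbn_unknown_state")
  }
  ev
}

# Variable elimination: unnormalized factor over `keep` given evidence.
# Returns list(factor = array over keep (canonical state order; NULL when
# keep is empty), total = P(evidence)).
.ve <- function(net, keep, ev, elim_order = NULL) {
  states <- .net_states(net)
  facs <- lapply(names(net$nodes), function(v) .cpt_factor(net, v))
  const <- 1
  if (length(ev)) {
    facs <- lapply(facs, .f_reduce, ev = ev)
    scal <- !vapply(facs, is.array, logical(1))
    if (any(scal)) {
      const <- prod(unlist(facs[scal]))
      facs <- facs[!scal]
    }
  }
  elim <- setdiff(names(net$nodes), c(keep, names(ev)))
  if (is.null(elim_order)) {
    elim_order <- .elim_order(lapply(facs, .factor_vars), elim)
  } else {
    if (!setequal(elim_order, elim))
      stop_sibbn("elim_order must be a permutation of the unobserved, non-query nodes",
                 "sibbn_bad_elim_order")
  }
  for (v in elim_order) {
    hit <- vapply(facs, function(f) v %in% .factor_vars(f), logical(1))
    if (!any(hit)) next
    prod_f <- Reduce(function(a, b) .f_product(a, b, states), facs[hit])
    marg <- .f_marginalize(prod_f, v)
    facs <- facs[!hit]
    if (is.array(marg)) facs <- c(facs, list(marg)) else const <- const * marg
  }
  if (!length(facs)) {
    return(list(factor = NULL, total = const))
  }
  res <- Reduce(function(a, b) .f_product(a, b, states), facs)
  res <- res * const
  if (length(keep) > 1L) res <- aperm(res, keep)
  list(factor = res, total = sum(res))
}

#' Exact posterior distribution of one node given evidence
#'
#' Computes P(query | evidence) by variable elimination (min-degree ordering,
#' name-order tie-break). Evidence whose probability is exactly zero raises a
#' classed error (`sibbn_impossible_evidence`) rather than returning a zero
#' vector, so callers such as the EM E-step can distinguish a contradictory
#' observation from numerical underflow.
#'
#' @param net A `bbn` network.
#' @param query Node name to query; must not appear in the evidence.
#' @param evidence Named character vector/list of observed states (may be
#'   empty or `NULL`).
#' @param elim_order Optional explicit elimination order (a permutation of
#'   the unobserved non-query nodes); exact inference is invariant to it.
#' @return An object of class `bbn_posterior`: list with `query`, `posterior`
#'   (named probability vector in the node's declared state order) and
#'   `evidence`.
#' @export
posterior <- function(net, query, evidence = NULL, elim_order = NULL) {
  stopifnot(inherits(net, "bbn"))
  if (!(query %in% names(net$nodes)))
    stop_sibbn(sprintf("unknown query node '%s'", query), "sibbn_unknown_node")
  ev <- .check_evidence(net, evidence)
  if (query %in% names(ev))
    stop_sibbn("query node must not be part of the evidence", "sibbn_bad_evidence")
  r <- .ve(net, keep = query, ev = ev, elim_order = elim_order)
  if (r$total <= 0)
    stop_sibbn("evidence has probability zero under this network",
               "sibbn_impossible_evidence")
  p <- as.vector(r$factor) / r$total
  names(p) <- net$nodes[[query]]$states
  structure(list(query = query, posterior = p, evidence = ev),
            class = "bbn_posterior")
}

#' @export
print.bbn_posterior <- function(x, digits = 4, ...) {
  cat(sprintf("P(%s | %s)\n", x$query,
              if (length(x$evidence))
                paste(names(x$evidence), x$evidence, sep = "=", collapse = ", ")
              else "no evidence"))
  print(round(x$posterior, digits))
  invisible(x)
}

#' Probability of an evidence set
#'
#' P(evidence): the joint probability summed over all unobserved nodes.
#' Empty evidence has probability 1; a full assignment reduces to
#' [joint_probability()].
#'
#' @inheritParams posterior
#' @return A probability in \[0, 1\].
#' @export
evidence_probability <- function(net, evidence = NULL) {
  stopifnot(inherits(net, "bbn"))
  ev <- .check_evidence(net, evidence)
  if (!length(ev)) return(1)
  .ve(net, keep = character(0), ev = ev)$total
}

#' Predicted probability of a designated outcome state for one record
#'
#' Uses every non-missing field of the record (except the outcome itself) as
#' evidence; missing fields are simply absent and therefore marginalized
#' over, which is how the 49 households without source samples are handled.
#'
#' @param net A `bbn` network.
#' @param record Named character vector/list of observed states; `NA` entries
#'   are treated as missing.
#' @param outcome Outcome node name.
#' @param state Designated outcome state whose probability is returned.
#' @return P(outcome = state | observed fields), a single number.
#' @export
predict_outcome <- function(net, record, outcome, state = "detected") {
  if (!(outcome %in% names(net$nodes)))
    stop_sibbn(sprintf("unknown outcome node '%s'", outcome), "sibbn_unknown_node")
  if (!(state %in% net$nodes[[outcome]]$states))
    stop_sibbn(sprintf("'%s' is not a state of '%s'", state, outcome),
               "sibbn_unknown_state")
  record <- unlist(record)
  record <- record[!is.na(record)]
  record <- record[names(record) != outcome]
  record <- record[names(record) %in% names(net$nodes)]
  p <- posterior(net, outcome, evidence = record)
  unname(p$posterior[[state]])
}
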