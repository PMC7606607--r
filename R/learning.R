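# Maximum-likelihood and EM estimation of unlocked CPTs from survey records.
#
# The estimator works on an integer-coded copy of the network and data. The
# E-step exploits the structure of survey missingness: records are grouped by
# their missingness pattern and, within a pattern, by the observed states of
# the variables appearing in the families that touch a missing variable.
# Because every variable outside the missing set is observed, the posterior
# over the missing variables factorizes through those families alone, so one
# small exact enumeration per unique group serves all its records. Survey
# data with block-missing source fields (many records sharing one pattern
# and few distinct observed contexts) therefore cost almost nothing beyond
# plain counting.

.compile_net <- function(net) {
  nm <- names(net$nodes)
  states <- .net_states(net)
  k <- vapply(states, length, integer(1))
  fam <- lapply(nm, function(v) {
    cpt <- net$cpts[[v]]
    pid <- match(cpt$parents, nm)
    sizes <- k[pid]
    strides <- if (length(pid)) cumprod(c(1L, sizes[-length(sizes)])) else integer(0)
    list(pid = pid, strides = strides, prob = unname(cpt$prob),
         locked = cpt$locked, nrow = nrow(cpt$prob))
  })
  names(fam) <- nm
  list(names = nm, states = states, k = k, fam = fam)
}

.row_index <- function(mat, strides) {
  if (!ncol(mat)) return(rep.int(1L, nrow(mat)))
  as.integer(1L + (mat - 1L) %*% strides)
}

.encode_table <- function(data, comp) {
  n <- nrow(data)
  miss_cols <- setdiff(comp$names, names(data))
  m <- matrix(NA_integer_, n, length(comp$names),
              dimnames = list(NULL, comp$names))
  for (v in intersect(comp$names, names(data))) {
    val <- as.character(data[[v]])
    idx <- match(val, comp$states[[v]])
    bad <- which(!is.na(val) & is.na(idx))
    if (length(bad))
      stop_sibbn(sprintf("record %d: '%s' is not a state of node '%s'",
                         bad[1], val[bad[1]], v), "sibbn_illegal_state")
    m[, v] <- idx
  }
  m
}

# Expected sufficient statistics and observed-data log-likelihood under the
# current parameters. Returns list(counts = per-node matrices, loglik).
.estep <- function(comp, m) {
  n <- nrow(m)
  V <- length(comp$names)
  counts <- lapply(seq_len(V), function(v)
    matrix(0, comp$fam[[v]]$nrow, comp$k[v]))
  ll <- numeric(n)
  na <- is.na(m)
  key <- apply(na, 1L, function(z) paste(which(z), collapse = ","))

  for (kk in sort(unique(key))) {
    rows <- which(key == kk)
    M <- if (nzchar(kk)) as.integer(strsplit(kk, ",", fixed = TRUE)[[1]]) else integer(0)

    # families untouched by the missing set: exact counting
    for (v in seq_len(V)) {
      fam <- comp$fam[[v]]
      if (any(c(fam$pid, v) %in% M)) next
      ridx <- .row_index(m[rows, fam$pid, drop = FALSE], fam$strides)
      cidx <- m[rows, v]
      pr <- fam$prob[cbind(ridx, cidx)]
      zero <- which(pr <= 0)
      if (length(zero))
        stop_sibbn(sprintf(
          "record %d has probability zero under the current parameters (node '%s')",
          rows[zero[1]], comp$names[v]), "sibbn_impossible_record")
      ll[rows] <- ll[rows] + log(pr)
      if (!fam$locked) {
        tb <- tabulate(ridx + (cidx - 1L) * fam$nrow,
                       nbins = fam$nrow * comp$k[v])
        counts[[v]] <- counts[[v]] + matrix(tb, fam$nrow, comp$k[v])
      }
    }
    if (!length(M)) next

    # families touching missing variables: exact enumeration over the
    # missing grid, shared by all records with the same observed context
    Tn <- which(vapply(seq_len(V), function(v)
      any(c(comp$fam[[v]]$pid, v) %in% M), logical(1)))
    Rvars <- setdiff(unique(unlist(lapply(Tn, function(v)
      c(comp$fam[[v]]$pid, v)))), M)
    grid <- as.matrix(do.call(expand.grid, lapply(comp$k[M], seq_len)))
    grows <- nrow(grid)
    sub <- if (length(Rvars))
      do.call(paste, c(as.data.frame(m[rows, Rvars, drop = FALSE]), sep = ","))
    else rep("", length(rows))
    for (sk in sort(unique(sub))) {
      rr <- rows[sub == sk]
      w <- length(rr)
      G <- matrix(m[rr[1], ], grows, V, byrow = TRUE)
      G[, M] <- grid
      gw <- rep(1, grows)
      cells <- vector("list", length(Tn))
      for (j in seq_along(Tn)) {
        v <- Tn[j]; fam <- comp$fam[[v]]
        ridx <- .row_index(G[, fam$pid, drop = FALSE], fam$strides)
        cidx <- G[, v]
        gw <- gw * fam$prob[cbind(ridx, cidx)]
        cells[[j]] <- ridx + (cidx - 1L) * fam$nrow
      }
      s <- sum(gw)
      if (s <= 0)
        stop_sibbn(sprintf(
          "record %d: observed fields have probability zero under the current parameters",
          rr[1]), "sibbn_impossible_record")
      ll[rr] <- ll[rr] + log(s)
      wn <- gw / s * w
      for (j in seq_along(Tn)) {
        v <- Tn[j]; fam <- comp$fam[[v]]
        if (fam$locked) next
        add <- rowsum(wn, cells[[j]])
        idx <- as.integer(rownames(add))
        counts[[v]][idx] <- counts[[v]][idx] + add[, 1]
      }
    }
  }
  list(counts = counts, loglik = sum(sort(ll)))
}

# counts -> parameters; rows with zero mass and zero prior become uniform
.mstep <- function(comp, counts, prior_count) {
  for (v in seq_along(comp$fam)) {
    fam <- comp$fam[[v]]
    if (fam$locked) next
    kc <- comp$k[v]
    cnt <- counts[[v]] + prior_count
    tot <- rowSums(cnt)
    new <- cnt / tot
    new[tot == 0, ] <- 1 / kc
    comp$fam[[v]]$prob <- new
  }
  comp
}

.comp_to_net <- function(comp, net) {
  for (v in comp$names) {
    prob <- comp$fam[[v]]$prob
    dimnames(prob) <- dimnames(net$cpts[[v]]$prob)
    net$cpts[[v]]$prob <- prob
  }
  net
}

#' Maximum-likelihood CPT estimation from complete data
#'
#' Closed-form smoothed relative frequencies: each unlocked CPT row becomes
#' (cell count + `prior_count`) / (row total + `prior_count` x number of
#' child states). Rows never observed (and `prior_count` 0) become uniform.
#' Locked tables are returned unchanged.
#'
#' @param net A `bbn` network supplying structure and state vocabulary.
#' @param data Data frame of records, one column per node, character states;
#'   no missing values allowed (use [em_fit()] for incomplete data).
#' @param prior_count Non-negative symmetric pseudo-count added to every
#'   child-state cell (default 0: plain relative frequencies).
#' @return A `bbn` network with re-estimated unlocked CPTs.
#' @export
ml_estimate <- function(net, data, prior_count = 0) {
  stopifnot(inherits(net, "bbn"), prior_count >= 0)
  comp <- .compile_net(net)
  m <- .encode_table(data, comp)
  obs_cols <- intersect(comp$names, names(data))
  if (anyNA(m[, obs_cols]))
    stop_sibbn("ml_estimate requires complete data; use em_fit for missing values",
               "sibbn_missing_data")
  if (length(obs_cols) < length(comp$names))
    stop_sibbn(sprintf("ml_estimate requires every node observed; missing column(s): %s",
                       paste(setdiff(comp$names, obs_cols), collapse = ", ")),
               "sibbn_missing_data")
  counts <- lapply(seq_along(comp$names), function(v) {
    fam <- comp$fam[[v]]
    ridx <- .row_index(m[, fam$pid, drop = FALSE], fam$strides)
    cidx <- m[, v]
    matrix(tabulate(ridx + (cidx - 1L) * fam$nrow, nbins = fam$nrow * comp$k[v]),
           fam$nrow, comp$k[v])
  })
  comp <- .mstep(comp, counts, prior_count)
  .comp_to_net(comp, net)
}

#' Initialize unlocked CPTs
#'
#' @param net A `bbn` network.
#' @param mode `"uniform"` (every row flat) or `"random"` (rows drawn as
#'   normalized positive variates, reproducible from `seed`).
#' @param seed Seed for `mode = "random"`.
#' @return The network with re-initialized unlocked CPTs; locked tables are
#'   untouched.
#' @export
initialize_cpts <- function(net, mode = c("uniform", "random"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "bbn"))
  with_seed(seed, {
    for (v in names(net$cpts)) {
      cpt <- net$cpts[[v]]
      if (cpt$locked) next
      d <- dim(cpt$prob)
      new <- if (mode == "uniform") {
        matrix(1 / d[2], d[1], d[2])
      } else {
        r <- matrix(stats::rgamma(prod(d), shape = 1), d[1], d[2])
        r / rowSums(r)
      }
      dimnames(new) <- dimnames(cpt$prob)
      net$cpts[[v]]$prob <- new
    }
    net
  })
}

#' Fit unlocked CPTs by expectation-maximization
#'
#' Alternates an exact E-step (expected sufficient statistics per record,
#' marginalizing over each record's missing fields under the current
#' parameters) with the closed-form M-step of [ml_estimate()]. The
#' observed-data log-likelihood is non-decreasing across iterations; the fit
#' stops when the relative gain drops below `tol` or after `max_iter`
#' iterations. Locked (deterministic) tables are never updated. With
#' complete data the E-step degenerates to counting and the fit converges in
#' one iteration to the [ml_estimate()] solution.
#'
#' @param net A `bbn` network; its current unlocked CPTs are the starting
#'   point unless `init` is given.
#' @param data Data frame of records, one column per node; `NA` (or an
#'   absent column) marks a missing value.
#' @param prior_count Symmetric pseudo-count used in every M-step
#'   (default 1, Laplace smoothing, which keeps large sparse tables away
#'   from zero cells).
#' @param tol Relative log-likelihood gain below which the fit stops.
#' @param max_iter Maximum number of EM iterations.
#' @param init Optional re-initialization before fitting: `"asis"` (default)
#'   keeps the network's current parameters, `"uniform"`/`"random"` call
#'   [initialize_cpts()] first.
#' @param seed Seed for `init = "random"`.
#' @return An object of class `sibbn_fit`: list with `network` (the fitted
#'   `bbn`), `loglik` (trace, one value per iteration, evaluated at the
#'   parameters entering that iteration), `iterations` and `converged`.
#' @export
em_fit <- function(net, data, prior_count = 1, tol = 1e-6, max_iter = 200,
                   init = c("asis", "uniform", "random"), seed = NULL) {
  init <- match.arg(init)
  stopifnot(inherits(net, "bbn"), prior_count >= 0, tol > 0, max_iter >= 1)
  if (init != "asis") net <- initialize_cpts(net, mode = init, seed = seed)
  comp <- .compile_net(net)
  m <- .encode_table(data, comp)
  if (!nrow(m)) stop_sibbn("no records to fit", "sibbn_missing_data")
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    e <- .estep(comp, m)
    trace[it] <- e$loglik
    comp <- .mstep(comp, e$counts, prior_count)
    if (it >= 2L &&
        (trace[it] - trace[it - 1L]) < tol * (abs(trace[it - 1L]) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  structure(list(network = .comp_to_net(comp, net), loglik = trace,
                 iterations = it, converged = converged),
            class = "sibbn_fit")
}

#' @export
print.sibbn_fit <- function(x, ...) {
  cat(sprintf("EM fit: %d iteration(s), %sconverged; final log-likelihood %.4f\n",
              x$iterations, if (x$converged) "" else "NOT ",
              x$loglik[length(x$loglik)]))
  invisible(x)
}

#' Recovery error between a fitted and a truth network
#'
#' Mean absolute difference between unlocked CPT entries of two networks
#' sharing a structure. By default each CPT row is weighted by the
#' probability of its parent configuration under the truth network: rows
#' that the data-generating process never visits are unidentifiable from
#' data, so an expected error under the data distribution is the meaningful
#' recovery measure. `weights = "uniform"` averages all entries equally.
#'
#' @param truth,fitted `bbn` networks with identical structure.
#' @param weights `"parent_prob"` (default) or `"uniform"`.
#' @return List with `per_node` (named vector of per-node errors) and
#'   `overall` (their mean).
#' @export
cpt_recovery_error <- function(truth, fitted, weights = c("parent_prob", "uniform")) {
  weights <- match.arg(weights)
  stopifnot(inherits(truth, "bbn"), inherits(fitted, "bbn"))
  if (!setequal(names(truth$nodes), names(fitted$nodes)))
    stop_sibbn("networks have different node sets", "sibbn_invalid_network")
  unlocked <- names(truth$cpts)[!vapply(truth$cpts, `[[`, logical(1), "locked")]
  per <- vapply(unlocked, function(v) {
    tp <- truth$cpts[[v]]$prob
    fp <- fitted$cpts[[v]]$prob
    if (!identical(dim(tp), dim(fp)))
      stop_sibbn(sprintf("CPT dimensions differ for node '%s'", v),
                 "sibbn_invalid_network")
    rowerr <- rowMeans(abs(tp - fp))
    if (weights == "uniform" || !length(truth$cpts[[v]]$parents)) {
      mean(rowerr)
    } else {
      pa <- truth$cpts[[v]]$parents
      jw <- .ve(truth, keep = pa, ev = stats::setNames(character(0), character(0)))
      w <- as.vector(jw$factor) / jw$total
      sum(w * rowerr)
    }
  }, numeric(1))
  list(per_node = per, overall = mean(per))
}
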