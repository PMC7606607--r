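# Cross-validated assessment of a model variant on survey records.

#' Seeded k-fold partition plan
#'
#' Shuffles record indices with the seed, then cuts the permutation into k
#' contiguous blocks; fold sizes differ by at most one. Deterministic per
#' seed.
#'
#' @param n Number of records.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Shuffle seed.
#' @return An object of class `fold_plan`: list with `k`, `n`, `seed` and
#'   `assignment` (fold id per record index).
#' @export
kfold_split <- function(n, k, seed = 1) {
  if (k < 2 || k > n)
    stop_sibbn(sprintf("need 2 <= k <= n (got k = %d, n = %d)", k, n),
               "sibbn_invalid_folds")
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  assignment <- integer(n)
  assignment[perm] <- rep(seq_len(k), times = sizes)
  structure(list(k = as.integer(k), n = as.integer(n), seed = seed,
                 assignment = assignment), class = "fold_plan")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive record outscores a
#' randomly chosen negative one, ties counted half: computed from midranks,
#' which is exactly the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Logical or 0/1 vector of true classes.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop_sibbn("AUC needs both classes present", "sibbn_single_class")
  r <- rank(scores)                      # midranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Points of the empirical ROC curve
#'
#' @inheritParams auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1); thresholds are the distinct score values (records
#'   scoring `>= threshold` are called positive), with `Inf` for the empty
#'   call set.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop_sibbn("ROC needs both classes present", "sibbn_single_class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)   # last index of each distinct score
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, cumsum(!y)[keep] / n0),
             tpr = c(0, cumsum(y)[keep] / n1))
}

#' Qualitative accuracy class of an AUC value
#'
#' Greiner's banding: values at or below 0.5 are "poor", (0.5, 0.7] "less
#' accurate", (0.7, 0.9] "moderately accurate", (0.9, 1) "highly accurate",
#' and exactly 1 "perfect".
#'
#' @param a AUC value in \[0, 1\].
#' @return The class label.
#' @export
classify_auc <- function(a) {
  stopifnot(length(a) == 1, is.finite(a))
  if (a < 0 || a > 1)
    stop_sibbn("AUC must lie in [0, 1]", "sibbn_invalid_value")
  if (a == 1) "perfect"
  else if (a > 0.9) "highly accurate"
  else if (a > 0.7) "moderately accurate"
  else if (a > 0.5) "less accurate"
  else "poor"
}

#' Cross-validated AUC of a model variant on survey records
#'
#' For each fold, fits the variant's unlocked CPTs by [em_fit()] on the
#' remaining folds (from a fresh uniform initialization) and scores the
#' held-out records with [predict_outcome()], the outcome excluded from the
#' evidence and missing fields marginalized. Pooled held-out scores against
#' observed outcomes give the AUC and its accuracy class.
#'
#' @param variant Variant tag, [model_variant()], or a `bbn` network used as
#'   the structural template.
#' @param data Data frame of survey records; the outcome column must be
#'   observed in every record.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold shuffle.
#' @param outcome Outcome node name.
#' @param designated Outcome state treated as the positive class for ROC
#'   scoring (default `"detected"`).
#' @param em List of arguments passed on to [em_fit()] (e.g. `prior_count`,
#'   `tol`, `max_iter`).
#' @param folds Optional pre-built [kfold_split()] plan (overrides `k` and
#'   `seed`).
#' @param semantics Index-rule direction mapping (used when `variant` is a
#'   tag).
#' @return An object of class `sibbn_validation`: list with `auc`, `class`,
#'   `roc`, `scores`, `labels`, `fold` (fold id per record) and `k`.
#' @export
cross_validate <- function(variant, data, k = 10, seed = 1,
                           outcome = "ecoli_pou", designated = "detected",
                           em = list(), folds = NULL,
                           semantics = c("contamination_risk", "literal")) {
  template <- if (inherits(variant, "bbn")) variant
              else build_model(variant, semantics = match.arg(semantics))
  if (!(outcome %in% names(data)) || anyNA(data[[outcome]]))
    stop_sibbn("the outcome must be observed in every record", "sibbn_missing_data")
  n <- nrow(data)
  plan <- folds %||% kfold_split(n, k, seed)
  if (!inherits(plan, "fold_plan") || plan$n != n)
    stop_sibbn("folds must be a fold_plan built for this data", "sibbn_invalid_folds")
  scores <- numeric(n)
  for (f in seq_len(plan$k)) {
    test <- which(plan$assignment == f)
    train <- data[-test, , drop = FALSE]
    never <- names(train)[vapply(train, function(col) all(is.na(col)), logical(1))]
    never <- intersect(never, names(template$nodes))
    if (length(never))
      warning(sprintf(
        "fold %d: node(s) %s never observed in training; estimates follow the smoothing prior",
        f, paste(never, collapse = ", ")), call. = FALSE)
    fit <- do.call(em_fit, c(list(net = initialize_cpts(template, "uniform"),
                                  data = train), em))
    for (i in test)
      scores[i] <- predict_outcome(fit$network, data[i, , drop = FALSE],
                                   outcome = outcome, state = designated)
  }
  labels <- data[[outcome]] == designated
  a <- auc(scores, labels)
  structure(list(auc = a, class = classify_auc(a),
                 roc = roc_points(scores, labels),
                 scores = scores, labels = labels,
                 fold = plan$assignment, k = plan$k, seed = plan$seed),
            class = "sibbn_validation")
}

#' @export
print.sibbn_validation <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: AUC = %.3f (\"%s\"), %d records (%d positive)\n",
              x$k, x$auc, x$class, length(x$labels), sum(x$labels)))
  invisible(x)
}
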