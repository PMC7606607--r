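# Brute-force oracles and fixture builders, independent of the package's
# variable-elimination and counting code paths.

# full joint table by enumeration of every assignment
enum_grid <- function(net) {
  st <- lapply(net$nodes, `[[`, "states")
  grid <- do.call(expand.grid, c(st, KEEP.OUT.ATTRS = FALSE,
                                 stringsAsFactors = FALSE))
  grid$.p <- apply(grid[, names(st), drop = FALSE], 1,
                   function(r) joint_probability(net, r))
  grid
}

enum_filter <- function(grid, ev) {
  keep <- rep(TRUE, nrow(grid))
  for (v in names(ev)) keep <- keep & grid[[v]] == ev[[v]]
  grid[keep, , drop = FALSE]
}

enum_posterior <- function(net, query, ev = list()) {
  grid <- enum_filter(enum_grid(net), ev)
  st <- net$nodes[[query]]$states
  p <- tapply(grid$.p, factor(grid[[query]], levels = st), sum)
  p[is.na(p)] <- 0
  as.vector(p) / sum(grid$.p)
}

enum_evidence_probability <- function(net, ev = list()) {
  sum(enum_filter(enum_grid(net), ev)$.p)
}

# trapezoidal area under the ROC polygon, an implementation independent of
# the midrank statistic used by auc()
auc_trapezoid <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

# O(n^2) pairwise Mann-Whitney oracle
auc_pairwise <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# random DAG network over mixed binary/ternary nodes, reproducible per seed
random_network <- function(seed, n_nodes = NULL, max_parents = 2) {
  set.seed(seed)
  nn <- n_nodes %||% sample(4:8, 1)
  nms <- sprintf("n%02d", seq_len(nn))
  nodes <- list(); cpts <- list()
  for (j in seq_len(nn)) {
    k <- sample(2:3, 1)
    nodes[[j]] <- bbn_node(nms[j], paste0("s", seq_len(k)))
    pa <- if (j > 1) sample(nms[seq_len(j - 1)],
                            sample(0:min(max_parents, j - 1), 1)) else character(0)
    nr <- if (length(pa))
      prod(vapply(pa, function(p) length(nodes[[match(p, nms)]]$states), 1L))
    else 1L
    pr <- matrix(rgamma(nr * k, shape = 1), nr, k)
    cpts[[j]] <- bbn_cpt(nms[j], pa, pr / rowSums(pr))
  }
  build_network(nodes, cpts)
}

random_evidence <- function(net, n_ev, seed) {
  set.seed(seed)
  evn <- sample(names(net$nodes), n_ev)
  vapply(evn, function(v) sample(net$nodes[[v]]$states, 1), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seeded evaluation that leaves the ambient RNG stream alone
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# two-node deterministic chain a -> b (identity CPT)
chain_net <- function() {
  build_network(
    list(bbn_node("a", c("a1", "a2")), bbn_node("b", c("b1", "b2"))),
    list(bbn_cpt("a", prob = c(0.3, 0.7)),
         bbn_cpt("b", "a", rbind(c(1, 0), c(0, 1)))))
}
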