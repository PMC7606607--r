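#' Define a categorical network node
#'
#' A node is a categorical variable with a fixed, ordered list of states. The
#' declared state order is canonical throughout the package: it fixes CPT
#' column order, the row order of parent-state combinations, serialization,
#' and the order of posterior vectors.
#'
#' @param name Node name (single non-empty string, unique within a network).
#' @param states Character vector of at least two distinct state labels.
#' @param role One of `"external"`, `"outer_SI"`, `"intermediate"`,
#'   `"water_quality"`, `"treatment"`. Roles are descriptive metadata used by
#'   the sanitary-inspection model builders; they do not affect inference.
#' @return An object of class `bbn_node`.
#' @examples
#' bbn_node("household_water_treatment", c("yes_treat", "no"), role = "treatment")
#' @export
bbn_node <- function(name, states,
                     role = c("external", "outer_SI", "intermediate",
                              "water_quality", "treatment")) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_sibbn("node name must be a single non-empty string", "sibbn_invalid_node")
  states <- as.character(states)
  if (length(states) < 2L)
    stop_sibbn(sprintf("node '%s' needs at least two states", name),
               "sibbn_invalid_node")
  if (anyDuplicated(states))
    stop_sibbn(sprintf("node '%s' has duplicated state labels", name),
               "sibbn_invalid_node")
  structure(list(name = name, states = states, role = role),
            class = "bbn_node")
}

#' Define a conditional probability table
#'
#' The table rows enumerate every combination of parent states in canonical
#' order (first parent varying fastest, exactly the order of
#' `expand.grid(parent_states)`); columns follow the child's declared state
#' order. A root node has a single row, its prior. Tables flagged `locked`
#' (deterministic index tables of intermediate nodes) are never modified by
#' parameter learning.
#'
#' @param child Child node name.
#' @param parents Character vector of parent node names (may be empty).
#' @param prob Numeric matrix, one row per parent-state combination, one
#'   column per child state; rows must be non-negative and sum to 1.
#'   A single row may be given as a plain vector for a root node.
#' @param locked Logical; `TRUE` marks the table as fixed during learning.
#' @return An object of class `bbn_cpt`.
#' @examples
#' bbn_cpt("hwt", prob = c(0.56, 0.44))
#' @export
bbn_cpt <- function(child, parents = character(), prob, locked = FALSE) {
  if (!is.character(child) || length(child) != 1L || !nzchar(child))
    stop_sibbn("CPT child must be a single non-empty string", "sibbn_invalid_cpt")
  parents <- as.character(parents)
  if (anyDuplicated(parents))
    stop_sibbn(sprintf("CPT for '%s' lists a parent twice", child),
               "sibbn_invalid_cpt")
  if (child %in% parents)
    stop_sibbn(sprintf("node '%s' cannot be its own parent", child),
               "sibbn_invalid_cpt")
  if (is.null(dim(prob))) prob <- matrix(as.numeric(prob), nrow = 1L)
  prob <- as.matrix(prob)
  storage.mode(prob) <- "double"
  if (!all(is.finite(prob)))
    stop_sibbn(sprintf("CPT for '%s' contains non-finite entries", child),
               "sibbn_invalid_cpt")
  structure(list(child = child, parents = parents, prob = prob,
                 locked = isTRUE(locked)),
            class = "bbn_cpt")
}

.net_states <- function(net) lapply(net$nodes, `[[`, "states")

#' Assemble and validate a Bayesian belief network
#'
#' Checks that node names are unique, that exactly one CPT is supplied per
#' node, that every parent is a declared node, that each CPT has one row per
#' parent-state combination with rows summing to 1 (within 1e-9), and that
#' the implied edge set is acyclic.
#'
#' @param nodes List of [bbn_node()] objects.
#' @param cpts List of [bbn_cpt()] objects, one per node.
#' @return An object of class `bbn`: a validated network specification.
#' @examples
#' a <- bbn_node("a", c("a1", "a2"))
#' b <- bbn_node("b", c("b1", "b2"))
#' net <- build_network(list(a, b), list(
#'   bbn_cpt("a", prob = c(0.3, 0.7)),
#'   bbn_cpt("b", "a", rbind(c(0.9, 0.1), c(0.2, 0.8)))))
#' @export
build_network <- function(nodes, cpts) {
  if (!length(nodes) || !length(cpts))
    stop_sibbn("nodes and cpts must be non-empty", "sibbn_invalid_network")
  if (inherits(nodes, "bbn_node")) nodes <- list(nodes)
  if (inherits(cpts, "bbn_cpt")) cpts <- list(cpts)
  ok <- vapply(nodes, inherits, logical(1), "bbn_node")
  if (!all(ok)) stop_sibbn("all nodes must be bbn_node objects", "sibbn_invalid_network")
  nm <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop_sibbn(sprintf("duplicate node name: %s", nm[duplicated(nm)][1]),
               "sibbn_duplicate_node")
  names(nodes) <- nm

  ok <- vapply(cpts, inherits, logical(1), "bbn_cpt")
  if (!all(ok)) stop_sibbn("all cpts must be bbn_cpt objects", "sibbn_invalid_network")
  ch <- vapply(cpts, `[[`, character(1), "child")
  if (anyDuplicated(ch))
    stop_sibbn(sprintf("more than one CPT for node '%s'", ch[duplicated(ch)][1]),
               "sibbn_invalid_network")
  if (!setequal(ch, nm)) {
    miss <- setdiff(nm, ch)
    extra <- setdiff(ch, nm)
    if (length(miss))
      stop_sibbn(sprintf("no CPT supplied for node(s): %s",
                         paste(miss, collapse = ", ")), "sibbn_invalid_network")
    stop_sibbn(sprintf("CPT supplied for unknown node(s): %s",
                       paste(extra, collapse = ", ")), "sibbn_invalid_network")
  }
  names(cpts) <- ch
  cpts <- cpts[nm]

  states <- lapply(nodes, `[[`, "states")
  for (v in nm) {
    cpt <- cpts[[v]]
    bad <- setdiff(cpt$parents, nm)
    if (length(bad))
      stop_sibbn(sprintf("CPT for '%s' names unknown parent(s): %s",
                         v, paste(bad, collapse = ", ")), "sibbn_unknown_parent")
    want_rows <- prod(vapply(states[cpt$parents], length, integer(1)))
    k <- length(states[[v]])
    if (ncol(cpt$prob) != k)
      stop_sibbn(sprintf("CPT for '%s': %d columns, but the node has %d states",
                         v, ncol(cpt$prob), k), "sibbn_invalid_cpt")
    if (nrow(cpt$prob) != want_rows)
      stop_sibbn(sprintf(
        "CPT for '%s': %d rows supplied, %d required (one per parent-state combination)",
        v, nrow(cpt$prob), want_rows), "sibbn_cpt_rows")
    if (any(cpt$prob < 0))
      stop_sibbn(sprintf("CPT for '%s' has negative entries", v), "sibbn_invalid_cpt")
    sums <- rowSums(cpt$prob)
    if (any(abs(sums - 1) > 1e-9))
      stop_sibbn(sprintf("CPT for '%s': row %d sums to %.12g, not 1",
                         v, which(abs(sums - 1) > 1e-9)[1],
                         sums[which(abs(sums - 1) > 1e-9)[1]]), "sibbn_cpt_rowsum")
    if (!is.null(colnames(cpt$prob)) && !identical(colnames(cpt$prob), states[[v]]))
      stop_sibbn(sprintf("CPT for '%s': column names do not match the declared state order", v),
                 "sibbn_invalid_cpt")
    colnames(cpt$prob) <- states[[v]]
    rownames(cpt$prob) <- combo_keys(parent_grid(states[cpt$parents]))
    cpts[[v]]$prob <- cpt$prob
  }

  net <- structure(list(nodes = nodes, cpts = cpts), class = "bbn")
  net$order <- topological_order(net)   # also proves acyclicity
  net
}

#' Topological ordering of a network's nodes
#'
#' Kahn's algorithm with a deterministic tie-break: among nodes whose parents
#' are all placed, the lexicographically smallest name goes next. Raises an
#' error naming the nodes involved if the edge set contains a cycle.
#'
#' @param net A `bbn` network (or a partially built one during validation).
#' @return Character vector of node names, parents always before children.
#' @export
topological_order <- function(net) {
  nm <- names(net$nodes)
  parents <- lapply(net$cpts, `[[`, "parents")
  placed <- character(0)
  remaining <- sort(nm)
  while (length(remaining)) {
    ready <- remaining[vapply(parents[remaining],
                              function(p) all(p %in% placed), logical(1))]
    if (!length(ready))
      stop_sibbn(sprintf("cycle detected among nodes: %s",
                         paste(remaining, collapse = ", ")), "sibbn_cycle")
    placed <- c(placed, ready[1])
    remaining <- setdiff(remaining, ready[1])
  }
  placed
}

#' Joint probability of a full assignment
#'
#' Chain-rule factorization: the product over nodes of the CPT entry selected
#' by the assignment.
#'
#' @param net A `bbn` network.
#' @param assignment Named character vector or list giving one legal state for
#'   every node in the network.
#' @return A probability in \[0, 1\].
#' @export
joint_probability <- function(net, assignment) {
  assignment <- unlist(assignment)
  nm <- names(net$nodes)
  if (!setequal(names(assignment), nm))
    stop_sibbn("assignment must cover every node exactly once", "sibbn_bad_assignment")
  states <- .net_states(net)
  for (v in nm) {
    if (!(assignment[[v]] %in% states[[v]]))
      stop_sibbn(sprintf("unknown state '%s' for node '%s'", assignment[[v]], v),
                 "sibbn_unknown_state")
  }
  p <- 1
  for (v in nm) {
    cpt <- net$cpts[[v]]
    key <- if (length(cpt$parents))
      paste(assignment[cpt$parents], collapse = "\x1f") else "(root)"
    p <- p * cpt$prob[key, assignment[[v]]]
    if (p == 0) return(0)
  }
  unname(p)
}

#' CPT rows as an auditable data frame
#'
#' Returns the table of one node keyed by explicit parent-state tuples, one
#' row per combination, with the probability of each child state in named
#' columns.
#'
#' @param net A `bbn` network.
#' @param node Node name.
#' @return A data frame: parent columns followed by `p_<state>` columns.
#' @export
cpt_rows <- function(net, node) {
  if (!(node %in% names(net$nodes)))
    stop_sibbn(sprintf("unknown node '%s'", node), "sibbn_unknown_node")
  cpt <- net$cpts[[node]]
  grid <- parent_grid(.net_states(net)[cpt$parents])
  pr <- as.data.frame(cpt$prob)
  names(pr) <- paste0("p_", colnames(cpt$prob))
  rownames(pr) <- NULL
  if (ncol(grid)) {
    names(grid) <- cpt$parents
    cbind(grid, pr)
  } else pr
}

#' @export
print.bbn <- function(x, ...) {
  roles <- vapply(x$nodes, `[[`, character(1), "role")
  nlock <- sum(vapply(x$cpts, `[[`, logical(1), "locked"))
  nedge <- sum(lengths(lapply(x$cpts, `[[`, "parents")))
  cat(sprintf("Discrete Bayesian belief network: %d nodes, %d edges (%d locked CPTs)\n",
              length(x$nodes), nedge, nlock))
  if (!is.null(x$variant)) cat(sprintf("  model variant: %s\n", x$variant))
  for (v in x$order) {
    p <- x$cpts[[v]]$parents
    cat(sprintf("  %s [%s] {%s}%s\n", v, roles[[v]],
                paste(x$nodes[[v]]$states, collapse = ", "),
                if (length(p)) paste0(" <- ", paste(p, collapse = ", ")) else ""))
  }
  invisible(x)
}
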