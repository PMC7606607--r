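# JSON interchange for network specifications.
#
# Layout (format "sibbn-network", version 1):
#   {
#     "format": "sibbn-network", "version": 1, "variant": "1B",   # variant optional
#     "nodes": [ {"name": ..., "states": [...], "role": ...}, ... ],
#     "cpts":  [ {"child": ..., "parents": [...], "locked": false,
#                 "rows": [ {"given": {"parent": "state", ...},
#                            "p": [ ... ]}, ... ]}, ... ]
#   }
# Rows appear in canonical order (first parent fastest); "given" keys make
# every row auditable without knowing that convention. Probabilities are
# written with 17 significant digits so a round trip reproduces the doubles
# bit-for-bit.

#' Write a network to the documented JSON layout
#'
#' @param net A `bbn` network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_network()]
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "bbn"))
  states <- .net_states(net)
  nodes <- lapply(net$nodes, function(nd)
    list(name = nd$name, states = nd$states, role = nd$role))
  cpts <- lapply(names(net$cpts), function(v) {
    cpt <- net$cpts[[v]]
    grid <- parent_grid(states[cpt$parents])
    rows <- lapply(seq_len(nrow(cpt$prob)), function(i) {
      given <- if (ncol(grid)) as.list(vapply(grid[i, , drop = FALSE],
                                              as.character, character(1)))
               else structure(list(), names = character(0))
      if (length(given)) names(given) <- cpt$parents
      list(given = given, p = unname(cpt$prob[i, ]))
    })
    list(child = v, parents = cpt$parents, locked = cpt$locked, rows = rows)
  })
  doc <- list(format = "sibbn-network", version = 1L)
  if (!is.null(net$variant)) doc$variant <- net$variant
  doc$nodes <- unname(nodes)
  doc$cpts <- unname(cpts)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a network from the documented JSON layout
#'
#' Validates the loaded structure with [build_network()], so a malformed file
#' fails with the same diagnostics as an in-code construction error.
#'
#' @param path Path to a file written by [write_network()].
#' @return A `bbn` network.
#' @export
read_network <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(doc$format, "sibbn-network"))
    stop_sibbn(sprintf("'%s' is not a sibbn network file", path), "sibbn_bad_file")
  nodes <- lapply(doc$nodes, function(nd)
    bbn_node(nd$name, unlist(nd$states), role = nd$role))
  cpts <- lapply(doc$cpts, function(cp) {
    prob <- do.call(rbind, lapply(cp$rows, function(r) unlist(r$p)))
    bbn_cpt(cp$child, parents = unlist(cp$parents) %||% character(0),
            prob = prob, locked = isTRUE(cp$locked))
  })
  net <- build_network(nodes, cpts)
  if (!is.null(doc$variant)) net$variant <- doc$variant
  net
}
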