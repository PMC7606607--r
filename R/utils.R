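# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched so package randomness never leaks into scripts.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_sibbn <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "sibbn_error")))
}

# canonical enumeration of parent-state combinations: first parent varies
# fastest, matching column-major fill of the CPT factor arrays
parent_grid <- function(parent_states) {
  if (!length(parent_states)) {
    return(as.data.frame(matrix(nrow = 1L, ncol = 0L)))
  }
  do.call(expand.grid,
          c(parent_states, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
}

combo_keys <- function(grid) {
  if (!ncol(grid)) return("(root)")
  do.call(paste, c(grid, sep = "\x1f"))
}
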