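#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so library internals never perturb user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a root seed
#'
#' Counter-based splitting: every pipeline stage draws its own seed from the
#' root seed and a stage index, so stages can be rerun independently yet
#' reproducibly. Result stays inside the 32-bit integer range R requires.
#'
#' @param seed root integer seed.
#' @param stage non-negative integer stage counter.
#' @return An integer seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stage) * 16807) %% 2147483629L)
}

sigmoid <- function(x) stats::plogis(x)

#' Signal a validation error
#' @keywords internal
#' @noRd
stop_validation <- function(msg, class = "drfuse_validation_error") {
  stop(structure(
    class = c(class, "drfuse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_binary_matrix <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}
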