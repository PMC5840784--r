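# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so seeded package functions
#' never disturb the caller's random stream.
#' @noRd
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
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# derive a sub-seed for a named stream; kept below 2^31 - 1
sub_seed <- function(seed, slot) {
  (as.numeric(seed) * 48271 + slot * 16807) %% 2147483629
}

stop_ntriss <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "ntriss_error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
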