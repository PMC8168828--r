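#' Evaluate code with a temporary RNG state
#'
#' Sets the seed, evaluates `code`, and restores whatever `.Random.seed` was
#' in place before, so seeded package functions never disturb the caller's
#' random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("rctscreen_validation_error",
                                             "rctscreen_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("rctscreen_format_error",
                                             "rctscreen_error")))
}

stop_undefined_metric <- function(...) {
  stop(errorCondition(paste0(...), class = c("rctscreen_undefined_metric",
                                             "rctscreen_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
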