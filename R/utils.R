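#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic functions in the package accept an integer seed; compound
#' pipelines derive per-stage seeds with fixed small offsets so stages can be
#' re-run independently. Kept strictly below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param offset fixed stage offset (small non-negative integer)
#' @return an integer seed
#' @export
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  as.integer((as.double(seed) * 101L + offset) %% 2147483587)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a single number strictly between 0 and 1", name),
         call. = FALSE)
  }
  invisible(x)
}
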