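`%||%` <- function(x, y) if (is.null(x)) y else x

clip01 <- function(x) pmin(1, pmax(0, x))

#' Derive a reproducible child seed
#'
#' Mixes a base seed with integer tags (subject index, condition index,
#' purpose) into a new seed in `[1, 2^31 - 2]`, so that every source of
#' randomness in a run flows deterministically from one named seed.
#'
#' @param seed Base integer seed.
#' @param ... Integer tags distinguishing the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in tags) {
    # multiplier kept small enough that x * 69069 + k stays exact in doubles
    x <- (x * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(x + 1)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_invalid(sprintf("`%s` must be a single finite number in [%s, %s]",
                         name, format(lower), format(upper)))
  }
  invisible(x)
}
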