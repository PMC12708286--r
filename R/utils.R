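#' Derive a reproducible child seed from a master seed and a string tag
#'
#' Stage and per-model seeds are derived deterministically from one master
#' seed so that any stage can be rerun in isolation with identical results.
#' The tag is folded into the seed by a small polynomial string hash; the
#' result always fits in a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param tag character scalar naming the consumer (stage or model label).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  h <- as.double(master %% 2147483647)
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Round half up to a fixed number of decimals
#'
#' Report rates use conventional half-up rounding (97.45 -> 97.5) rather
#' than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}
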