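#' Q16.16 fixed-point arithmetic
#'
#' The codec evaluates every prediction in signed Q16.16 fixed point: a value
#' is stored as a 32-bit signed integer `raw` interpreted as `raw / 2^16`.
#' Integer-only evaluation makes encoder and decoder bit-identical on any
#' platform, which is the whole lossless-decodability contract — a floating
#' point unit that rounds differently on the decoding machine would corrupt
#' every sample after the first mismatch.
#'
#' Representable range is \[-32768, 32767 + 65535/65536\]; conversion
#' integer -> Q16.16 -> integer is the identity on \[-32768, 32767\].
#'
#' @param x numeric vector of real coefficient values, each with |x| < 32768.
#' @return `q16_quantize()` returns the raw Q16.16 representation as a double
#'   vector holding exact integers (R has no native int64; doubles are exact
#'   for |v| < 2^53 which covers every quantity used here).
#' @examples
#' q16_quantize(1.0)    # 65536
#' q16_quantize(-1.5)   # -98304
#' q16_to_real(q16_quantize(0.25))
#' @export
q16_quantize <- function(x) {
  stopifnot(is.numeric(x))
  if (any(!is.finite(x))) stop("non-finite coefficient")
  if (any(x < -32768 | x >= 32768)) {
    stop("value outside Q16.16 representable range [-32768, 32768)")
  }
  # round half away from zero: symmetric treatment of +/- coefficients
  scaled <- x * 65536
  raw <- sign(scaled) * floor(abs(scaled) + 0.5)
  if (any(raw > 2147483647 | raw < -2147483648)) {
    stop("value outside Q16.16 representable range [-32768, 32768)")
  }
  raw
}

#' @rdname q16_quantize
#' @param raw raw Q16.16 values (as produced by `q16_quantize()`).
#' @export
q16_to_real <- function(raw) raw / 65536

#' Fixed-point multiply-accumulate prediction
#'
#' Computes `floor(sum(coeffs_raw * samples) / 2^16)`, i.e. an exact
#' wide-integer dot product of Q16.16 coefficients with integer samples
#' followed by an arithmetic right shift of 16 bits (truncation toward
#' -Inf). This is the single arithmetic primitive behind every predictor:
#' the integer prediction of the current sample from the `p` most recent
#' samples. The accumulation is exact for history lengths p <= 64 with
#' 16-bit samples (|acc| < 2^53), so identical inputs give identical
#' outputs on every platform.
#'
#' For integer-valued coefficients (e.g. the exact-fit binomial predictors)
#' the result equals the plain integer dot product with no rounding at all.
#'
#' @param coeffs_raw raw Q16.16 coefficient vector, most-recent-first.
#' @param samples integer samples `x[n-1], ..., x[n-p]`, most-recent-first.
#' @return the integer prediction.
#' @examples
#' q16_fma_dot(q16_quantize(c(2, -1)), c(10, 7))  # 13
#' q16_fma_dot(q16_quantize(0.5), 3)              # floor(1.5) = 1
#' @export
q16_fma_dot <- function(coeffs_raw, samples) {
  if (length(coeffs_raw) != length(samples)) {
    stop("coefficient / sample length mismatch")
  }
  acc <- sum(coeffs_raw * as.numeric(samples))
  floor(acc / 65536)
}
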