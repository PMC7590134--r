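#' @title Predictive models for IMU channels
#' @description
#' Seven causal, zero-delay autoregressive predictors, all reduced to a fixed
#' linear filter over the `p` most recent samples and evaluated in Q16.16
#' fixed point:
#'
#' * `delta` — order-0: predict the previous sample (filter `(1)`).
#' * `linear` — order-1 extrapolation from the last two samples (`(2, -1)`).
#' * `poly2`..`poly5` — least-squares polynomial regression of order d over
#'   the p most recent samples, extrapolated one step; with the default
#'   exact fit p = d+1 the filter is the alternating binomial vector.
#' * `spline` — natural cubic spline through the p most recent samples,
#'   with the last cubic piece evaluated one step beyond its interval.
#'
#' @name predictors
NULL

KC_METHODS <- c("delta", "linear", "poly2", "poly3", "poly4", "poly5", "spline")

#' One-step-ahead polynomial regression filter
#'
#' Derives the weight vector `w` such that `sum(w * c(x[n-1], ..., x[n-p]))`
#' equals the value at step `n` of the degree-`d` polynomial fitted by least
#' squares to the `p` most recent samples at unit spacing (past positions
#' -1, ..., -p; prediction at position 0). Algebraically this is the row
#' vector `e_d (C'C)^{-1} C'` of the normal equations, so any polynomial
#' signal of degree <= d is predicted exactly. For the exact-fit case
#' p = d+1 the weights are the signed binomial coefficients
#' `(-1)^(i+1) * choose(d+1, i)` — e.g. d=1 gives (2, -1), the familiar
#' linear extrapolator — computed directly so they are exact integers.
#'
#' @param d polynomial order, `d >= 0`.
#' @param p history length (number of past samples), `d < p <= 64`.
#' @return numeric weight vector of length `p`, most-recent-first; sums to 1
#'   (every polynomial predictor reproduces constants).
#' @examples
#' derive_poly_coeffs(1, 2)  # c(2, -1)
#' derive_poly_coeffs(2, 3)  # c(3, -3, 1)
#' @export
derive_poly_coeffs <- function(d, p = d + 1) {
  stopifnot(length(d) == 1, length(p) == 1, d >= 0, p > d, p <= 64)
  d <- as.integer(d); p <- as.integer(p)
  if (p == d + 1L) {
    i <- seq_len(p)
    return((-1)^(i + 1) * choose(d + 1L, i))
  }
  # overdetermined regression: monomial design at positions -1..-p
  C <- outer(-seq_len(p), d:0, `^`)
  G <- crossprod(C)
  if (rcond(G) < 1e-14) stop("rank-deficient polynomial design")  # cannot occur
  drop(solve(G, t(C))[d + 1L, ])
}

#' One-step-ahead natural cubic spline filter
#'
#' Weight vector of the predictor that passes a natural cubic spline through
#' the `p` most recent samples (unit knot spacing, zero second derivative at
#' both end knots) and evaluates the last cubic piece one step beyond its
#' interval. Because the prediction is linear in the samples, the weights
#' are obtained by running the spline on each unit impulse: solve the
#' tridiagonal second-derivative system and evaluate the end piece.
#'
#' A consequence of the natural boundary condition is worth knowing: the end
#' knot's second derivative is pinned to zero, and the one-step value of the
#' last piece simplifies to `2 x[n-1] - x[n-2] + M_p` where `M_p` is that
#' second derivative — so the natural-spline extrapolator reduces exactly to
#' the linear extrapolation filter `(2, -1, 0, ..., 0)` for every `p`. The
#' derivation below is kept generic (it is the definition of the method and
#' would yield non-trivial weights under any other boundary condition); see
#' the methods vignette for the algebra.
#'
#' @param p number of knots, `3 <= p <= 64` (p = 2 would degenerate to
#'   linear extrapolation).
#' @return numeric weight vector of length `p`, most-recent-first;
#'   sums to 1.
#' @export
derive_spline_coeffs <- function(p = 5) {
  stopifnot(length(p) == 1, p >= 3, p <= 64)
  p <- as.integer(p)
  predict_one <- function(x) {
    # second derivatives M: natural boundary M[1] = M[p] = 0
    A <- diag(p)
    b <- numeric(p)
    for (i in 2:(p - 1)) {
      A[i, i - 1L] <- 1; A[i, i] <- 4; A[i, i + 1L] <- 1
      b[i] <- 6 * (x[i + 1L] - 2 * x[i] + x[i - 1L])
    }
    M <- solve(A, b)
    i <- p - 1L; t0 <- p + 1L  # last piece f_{p-1}, one step beyond knot p
    M[i] * (p - t0)^3 / 6 + M[p] * (t0 - i)^3 / 6 +
      (x[i] - M[i] / 6) * (p - t0) + (x[p] - M[p] / 6) * (t0 - i)
  }
  w_oldest_first <- vapply(seq_len(p), function(i) {
    predict_one(replace(numeric(p), i, 1))
  }, numeric(1))
  rev(w_oldest_first)
}

#' Predictor specification
#'
#' Binds a method name to its order `d`, history length `p` and quantized
#' Q16.16 filter coefficients (most-recent-first). The spec is fully
#' determined by `(method, d, p)`, so the decoder re-derives it from the
#' container header; coefficients are never stored in the stream.
#'
#' @param method one of `"delta"`, `"linear"`, `"poly2"`..`"poly5"`,
#'   `"spline"`.
#' @param p history length; defaults to the exact fit `d + 1` for the
#'   polynomial methods and 5 knots for the spline.
#' @return an object of class `predictor_spec`: a list with fields `method`,
#'   `d`, `p`, `coeffs` (real weights) and `coeffs_raw` (Q16.16).
#' @examples
#' predictor_spec("linear")
#' predictor_spec("poly3", p = 6)  # overdetermined regression
#' @export
predictor_spec <- function(method = KC_METHODS, p = NULL) {
  method <- match.arg(method)
  d <- switch(method,
    delta = 0L, linear = 1L, poly2 = 2L, poly3 = 3L, poly4 = 4L, poly5 = 5L,
    spline = 3L)  # cubic
  if (method == "spline") {
    if (is.null(p)) p <- 5L
    w <- derive_spline_coeffs(p)
  } else {
    if (is.null(p)) p <- d + 1L
    w <- derive_poly_coeffs(d, p)
  }
  structure(
    list(method = method, d = d, p = as.integer(p),
         coeffs = w, coeffs_raw = q16_quantize(w)),
    class = "predictor_spec")
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat(sprintf("predictor_spec: %s (d = %d, p = %d)\n", x$method, x$d, x$p))
  cat("  weights:", paste(format(x$coeffs, digits = 6), collapse = " "), "\n")
  invisible(x)
}

#' Predict-and-encode a channel into residuals
#'
#' Runs the causal predictor over one channel: the first `p` samples are
#' stored verbatim as warm-up (the decoder needs history before the filter
#' can run), and for every later sample the integer residual
#' `e[n] = x[n] - floor(sum(coeffs * past) / 2^16)` is emitted. A signal
#' shorter than `p` is stored entirely as warm-up with no residuals —
#' degenerate but decodable.
#'
#' @param samples integer vector of 16-bit signed samples.
#' @param spec a [predictor_spec()].
#' @return a list of class `residual_stream`: `warmup` (first
#'   `min(p, length)` samples), `residuals` (integer vector), `p`.
#' @seealso [predict_decode()] for the exact inverse.
#' @export
predict_encode <- function(samples, spec) {
  stopifnot(inherits(spec, "predictor_spec"))
  check_int16(samples)
  samples <- as.numeric(samples)
  n <- length(samples)
  p <- spec$p
  if (n <= p) {
    return(structure(list(warmup = samples, residuals = numeric(0), p = p),
                     class = "residual_stream"))
  }
  # lag matrix: row t has x[t], x[t-1], ..., x[t-p] for t = p+1..n
  lagged <- stats::embed(samples, p + 1L)
  pred <- floor((lagged[, -1L, drop = FALSE] %*% spec$coeffs_raw) / 65536)
  structure(
    list(warmup = samples[seq_len(p)],
         residuals = as.numeric(lagged[, 1L] - pred),
         p = p),
    class = "residual_stream")
}

#' Decode residuals back into samples
#'
#' Exact inverse of [predict_encode()]: replays the identical fixed-point
#' predictor over the reconstructed history and adds each residual back.
#' Any reconstructed sample outside the 16-bit range signals a corrupt
#' stream (wrong spec or damaged payload) and is an error, never silent.
#'
#' @param stream a `residual_stream`.
#' @param spec the same [predictor_spec()] used to encode.
#' @return integer vector of reconstructed samples.
#' @export
predict_decode <- function(stream, spec) {
  stopifnot(inherits(spec, "predictor_spec"))
  p <- spec$p
  if (stream$p != p) stop("residual stream was produced with a different history length")
  x <- c(stream$warmup, numeric(length(stream$residuals)))
  craw <- spec$coeffs_raw
  nres <- length(stream$residuals)
  if (nres > 0) {
    for (k in seq_len(nres)) {
      t0 <- p + k
      pred <- floor(sum(craw * x[(t0 - 1):(t0 - p)]) / 65536)
      x[t0] <- pred + stream$residuals[k]
    }
  }
  if (length(x) && (max(x) > 32767 || min(x) < -32768)) {
    stop("reconstructed sample outside int16 range: corrupt stream or wrong spec")
  }
  as.integer(x)
}

# int16 validation shared by predictors / io / container
check_int16 <- function(x, what = "sample") {
  if (length(x) < 1) stop("empty channel")
  if (anyNA(x)) stop(sprintf("missing %s value", what))
  if (any(x != floor(x))) stop(sprintf("non-integer %s value", what))
  bad <- which(x < -32768 | x > 32767)
  if (length(bad)) {
    stop(sprintf("%s value %g at position %d outside 16-bit signed range",
                 what, x[bad[1]], bad[1]))
  }
  invisible(x)
}
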