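#' @title A-posteriori optimal L1 autoregressive reference models
#' @description
#' The proposed codecs use fixed filters. To know how much a *better* linear
#' model could gain, these routines compute, offline and with full knowledge
#' of the signal, the coefficient vector minimizing the L1 criterion
#'
#' \deqn{\min_a \|x - Xa\|_1 + \lambda \|a\|_1}
#'
#' where `X` holds the lagged samples. The L1 residual norm is the right
#' objective because the Golomb-Rice codeword length is (up to rounding) an
#' affine function of the residual magnitude, so total compressed size is
#' proportional to total absolute error — not squared error; the L1 penalty
#' encourages sparse coefficients, which quantize with less error. The fit
#' lower-bounds what any fixed linear predictor (including delta) can
#' achieve on that signal; it is non-causal and expensive, so it is a
#' reference point, never a shipped codec.
#'
#' The convex program is solved by cyclic coordinate descent: with all other
#' coefficients held fixed, the 1-D problem
#' \eqn{\min_a \sum_i |r_i - x_i a| + \lambda |a|} is piecewise linear and
#' its exact minimizer is a weighted median of the breakpoints
#' \eqn{r_i / x_i} with weights \eqn{|x_i|} (the penalty contributes a
#' breakpoint at 0 with weight \eqn{\lambda}). Descent starts from the delta
#' filter (1, 0, ..., 0), so the achieved objective can never exceed
#' delta's total absolute residual; each sweep is monotone.
#' @name optimal
NULL

# exact minimizer of sum(w * |b - a|): lower weighted median of breakpoints b
weighted_median <- function(b, w) {
  keep <- w > 0
  b <- b[keep]; w <- w[keep]
  if (!length(b)) return(0)
  o <- order(b)
  b <- b[o]; w <- w[o]
  cw <- cumsum(w)
  b[which(cw >= sum(w) / 2)[1]]
}

l1_objective <- function(y, X, a, lambda) {
  sum(abs(y - drop(X %*% a))) + lambda * sum(abs(a))
}

# cyclic coordinate descent for min ||y - X a||_1 + lambda ||a||_1
l1_coord_descent <- function(y, X, a0, lambda, tol = 1e-8, max_sweeps = 200L) {
  a <- a0
  r <- y - drop(X %*% a)
  obj <- sum(abs(r)) + lambda * sum(abs(a))
  for (sweep in seq_len(max_sweeps)) {
    prev <- obj
    for (k in seq_along(a)) {
      xk <- X[, k]
      r <- r + xk * a[k]                       # partial residual
      nz <- xk != 0
      bk <- r[nz] / xk[nz]
      wk <- abs(xk[nz])
      if (lambda > 0) { bk <- c(bk, 0); wk <- c(wk, lambda) }
      a[k] <- weighted_median(bk, wk)
      r <- r - xk * a[k]
    }
    obj <- sum(abs(r)) + lambda * sum(abs(a))
    if (prev - obj <= tol * (1 + abs(prev))) {
      return(list(a = a, objective = obj, sweeps = sweep, converged = TRUE))
    }
  }
  list(a = a, objective = obj, sweeps = max_sweeps, converged = FALSE)
}

# iteratively reweighted least squares: smooth companion to the coordinate
# descent. CD alone can stall at a coordinate-wise (non-global) minimum of
# the piecewise-linear objective; IRLS, seeded from ordinary least squares
# with a decreasing smoothing floor, lands near the global L1 optimum and
# CD then polishes it exactly.
l1_irls <- function(y, X, lambda, iters = 40L) {
  a <- tryCatch(qr.solve(X, y), error = function(e) numeric(ncol(X)))
  eps <- max(1, stats::median(abs(y)))
  for (it in seq_len(iters)) {
    r <- y - drop(X %*% a)
    eps <- max(eps / 4, 1e-9)
    w <- 1 / pmax(abs(r), eps)
    XtW <- t(X * w)
    A <- XtW %*% X
    if (lambda > 0) diag(A) <- diag(A) + lambda / pmax(abs(a), eps)
    a_new <- tryCatch(solve(A, XtW %*% y),
                      error = function(e) a)
    a <- drop(a_new)
  }
  a
}

# best of two starts: exact CD polish from the given warm start and from the
# IRLS solution. Taking the minimum keeps the warm start's feasibility bound.
l1_solve <- function(y, X, a0, lambda, tol, max_sweeps) {
  cand1 <- l1_coord_descent(y, X, a0, lambda, tol, max_sweeps)
  cand2 <- l1_coord_descent(y, X, l1_irls(y, X, lambda), lambda, tol,
                            max_sweeps)
  if (cand2$objective < cand1$objective) cand2 else cand1
}

lag_design <- function(x, p) {
  emb <- stats::embed(as.numeric(x), p + 1L)
  list(y = emb[, 1L], X = emb[, -1L, drop = FALSE])
}

#' Fit the L1-optimal autoregressive model to one channel
#'
#' @param x integer (or numeric) channel samples, length >= p + 10.
#' @param p model order (number of lags); default 8.
#' @param lambda L1 coefficient penalty weight, >= 0; default 0 (pure
#'   residual cost). A small grid such as `c(0, 0.1, 1, 10)` is the usual
#'   exploration range when sparsity matters.
#' @param tol relative objective-decrease tolerance; default 1e-8.
#' @param max_sweeps coordinate-descent sweep cap.
#' @return an object of class `kc_l1fit` with fields `coefficients` (lag
#'   1..p, most-recent-first), `objective` (achieved L1 criterion),
#'   `residuals`, `lambda`, `p`, `kind = "AR"`, `converged`, `sweeps`.
#' @examples
#' set.seed(1)
#' x <- cumsum(sample(c(-1L, 1L), 400, TRUE))
#' fit <- fit_l1_ar(x, p = 4)
#' coef(fit)  # close to (1, 0, 0, 0): delta is L1-optimal for a random walk
#' @export
fit_l1_ar <- function(x, p = 8, lambda = 0, tol = 1e-8, max_sweeps = 200L) {
  stopifnot(lambda >= 0, p >= 1)
  p <- as.integer(p)
  if (length(x) < p + 10) stop("signal too short for a meaningful fit (need length >= p + 10)")
  d <- lag_design(x, p)
  a0 <- c(1, numeric(p - 1L))   # delta filter: feasible warm start
  res <- l1_solve(d$y, d$X, a0, lambda, tol = tol, max_sweeps = max_sweeps)
  if (!res$converged) {
    warning("L1 coordinate descent reached the sweep cap before the tolerance")
  }
  structure(
    list(kind = "AR", p = p, lambda = lambda,
         coefficients = res$a,
         objective = res$objective,
         residuals = d$y - drop(d$X %*% res$a),
         delta_objective = sum(abs(d$y - d$X[, 1L])),
         converged = res$converged, sweeps = res$sweeps,
         n = length(d$y)),
    class = "kc_l1fit")
}

#' Fit the L1-optimal multivariate autoregressive model
#'
#' One L1 problem per target stream, with the design expanded to the past
#' `p` samples of *all* `s` co-located streams (`s*p` regressors). Each
#' target is warm-started from its own fitted AR solution — a feasible
#' point of the MVAR problem — so the MVAR objective never exceeds the AR
#' objective beyond the descent tolerance.
#'
#' @param channels list of equal-length channels (e.g. the six streams of
#'   one IMU node).
#' @inheritParams fit_l1_ar
#' @return an object of class `kc_l1fit` with `kind = "MVAR"`:
#'   `coefficients` is an `s x s x p` array (target, source, lag),
#'   `objective` the summed criterion, plus per-target fields.
#' @export
fit_l1_mvar <- function(channels, p = 8, lambda = 0, tol = 1e-8,
                        max_sweeps = 200L) {
  stopifnot(is.list(channels), length(channels) >= 2, lambda >= 0)
  if (length(unique(lengths(channels))) != 1) stop("channels must have equal length")
  s <- length(channels)
  p <- as.integer(p)
  n <- lengths(channels)[1]
  if (n < p + 10) stop("signal too short for a meaningful fit (need length >= p + 10)")
  # shared design: columns grouped by source stream, lag 1..p within group
  designs <- lapply(channels, lag_design, p = p)
  X <- do.call(cbind, lapply(designs, `[[`, "X"))
  coefs <- array(0, dim = c(s, s, p))
  objective <- 0
  per_target <- numeric(s)
  ar_objs <- numeric(s)
  converged <- TRUE
  for (i in seq_len(s)) {
    ar <- fit_l1_ar(channels[[i]], p = p, lambda = lambda, tol = tol,
                    max_sweeps = max_sweeps)
    ar_objs[i] <- ar$objective
    a0 <- numeric(s * p)
    a0[(i - 1L) * p + seq_len(p)] <- ar$coefficients
    res <- l1_solve(designs[[i]]$y, X, a0, lambda, tol = tol,
                    max_sweeps = max_sweeps)
    converged <- converged && res$converged
    coefs[i, , ] <- matrix(res$a, nrow = s, byrow = TRUE)
    per_target[i] <- res$objective
    objective <- objective + res$objective
  }
  structure(
    list(kind = "MVAR", p = p, lambda = lambda, s = s,
         coefficients = coefs,
         objective = objective, per_target = per_target,
         ar_objective = sum(ar_objs), ar_per_target = ar_objs,
         converged = converged, n = n - p),
    class = "kc_l1fit")
}

#' @export
print.kc_l1fit <- function(x, ...) {
  cat(sprintf("L1-optimal %s model (p = %d, lambda = %g)\n",
              x$kind, x$p, x$lambda))
  cat(sprintf("  objective (sum |e| + lambda sum |a|): %.4f over %d samples\n",
              x$objective, x$n))
  if (x$kind == "AR") {
    cat("  coefficients (lag 1..p):",
        paste(format(x$coefficients, digits = 4), collapse = " "), "\n")
    cat(sprintf("  delta-filter objective on same data: %.4f\n",
                x$delta_objective))
  } else {
    cat(sprintf("  %d targets; summed AR objective %.4f\n", x$s, x$ar_objective))
  }
  invisible(x)
}

#' @export
coef.kc_l1fit <- function(object, ...) object$coefficients

#' @export
residuals.kc_l1fit <- function(object, ...) {
  if (object$kind != "AR") stop("per-stream residuals are kept only for AR fits")
  object$residuals
}

#' Approximate Golomb-Rice encoded size (relaxed model)
#'
#' The affine surrogate `l + l*m + 2^-m * sum(u)` for the encoded size of
#' `l` residuals at Rice order `m`, with `u` the zigzag-mapped residuals.
#' This is the objective the L1 fit minimizes, not the exact bitstream
#' length: dropping the floor in the quotient overestimates each codeword
#' by less than one bit, so it is within `l` bits of the true size when no
#' escape fires.
#'
#' @param residuals signed integer residuals.
#' @param m Rice order.
#' @param l number of residuals (defaults to `length(residuals)`).
#' @return approximate size in bits (real-valued).
#' @export
approx_encoded_size <- function(residuals, m, l = length(residuals)) {
  stopifnot(m >= 0)
  l + l * m + 2^(-m) * sum(zigzag(residuals))
}

#' Quantize a fitted AR model into a usable predictor
#'
#' Rounds the real AR coefficients to Q16.16, producing a `predictor_spec`
#' that the codec primitives ([predict_encode()], [predict_decode()], Rice
#' coding) evaluate deterministically, and reports how much the
#' quantization costs: the exact Rice-coded payload size of the channel
#' under real-coefficient prediction (rounded to the nearest integer
#' prediction) versus fixed-point prediction.
#'
#' @param fit an AR `kc_l1fit`.
#' @param x optionally, the channel to evaluate the quantization cost on.
#' @return a list with `spec` (class `predictor_spec`, method `"ar"`) and,
#'   when `x` is given, `bits_real`, `bits_quantized` and `cr_ratio`
#'   (quantized/real compressed-size ratio).
#' @export
quantize_model <- function(fit, x = NULL) {
  stopifnot(inherits(fit, "kc_l1fit"))
  if (fit$kind != "AR") stop("only AR models can be quantized into a causal predictor")
  a <- fit$coefficients
  if (any(abs(a) >= 32768)) stop("coefficient magnitude exceeds the Q16.16 range")
  spec <- structure(
    list(method = "ar", d = NA_integer_, p = fit$p,
         coeffs = a, coeffs_raw = q16_quantize(a)),
    class = "predictor_spec")
  out <- list(spec = spec)
  if (!is.null(x)) {
    check_int16(x)
    d <- lag_design(x, fit$p)
    e_real <- d$y - round(drop(d$X %*% a))
    e_q <- predict_encode(x, spec)$residuals
    bits_for <- function(e) {
      m <- select_rice_order(e)
      sum(rice_encode(zigzag(e), m)$lengths)
    }
    out$bits_real <- bits_for(e_real)
    out$bits_quantized <- bits_for(e_q)
    out$cr_ratio <- out$bits_real / out$bits_quantized
  }
  out
}
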