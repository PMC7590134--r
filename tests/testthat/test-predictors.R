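# Lagrange one-step-extrapolation weights: independent oracle for the
# exact-fit (p = d+1) polynomial predictor. Weight of x[n-i] is
# prod_{j != i} j / (j - i) over past positions -1..-p evaluated at 0.
lagrange_weights <- function(p) {
  vapply(seq_len(p), function(i) {
    j <- setdiff(seq_len(p), i)
    prod(j / (j - i))
  }, numeric(1))
}

test_that("polynomial filters match the printed linear case and the Lagrange oracle", {
  expect_identical(derive_poly_coeffs(0, 1), 1)
  expect_identical(derive_poly_coeffs(1, 2), c(2, -1))
  expect_identical(derive_poly_coeffs(2, 3), c(3, -3, 1))
  for (d in 2:5) {
    expect_equal(derive_poly_coeffs(d, d + 1), lagrange_weights(d + 1),
                 tolerance = 1e-12)
    # signed binomial closed form
    i <- seq_len(d + 1)
    expect_identical(derive_poly_coeffs(d, d + 1), (-1)^(i + 1) * choose(d + 1, i))
  }
})

test_that("overdetermined regression weights match an lm() least-squares oracle", {
  for (case in list(c(1, 4), c(2, 5), c(3, 5), c(2, 8))) {
    d <- case[1]; p <- case[2]
    w <- derive_poly_coeffs(d, p)
    expect_equal(sum(w), 1, tolerance = 1e-9)  # constants reproduced
    # oracle: per unit impulse, fit the degree-d polynomial by QR least
    # squares and extrapolate to position 0
    C <- outer(-seq_len(p), d:0, `^`)
    w_oracle <- vapply(seq_len(p), function(i) {
      fit <- stats::lm.fit(C, replace(numeric(p), i, 1))
      unname(fit$coefficients[d + 1])
    }, numeric(1))
    expect_equal(w, w_oracle, tolerance = 1e-9)
  }
  expect_error(derive_poly_coeffs(2, 2))
})

test_that("every polynomial predictor is exact on polynomials of its degree", {
  set.seed(4)
  for (d in 0:5) {
    spec <- predictor_spec(c("delta", "linear", "poly2", "poly3", "poly4",
                             "poly5")[d + 1])
    # binomial-coefficient basis keeps degree-d integer polynomials in int16
    b <- sample(-2:2, d + 1, replace = TRUE)
    n <- 0:17
    x <- as.integer(vapply(n, function(t) sum(b * choose(t, 0:d)), numeric(1)))
    stream <- predict_encode(x, spec)
    expect_identical(stream$residuals, rep(0, length(x) - spec$p))
  }
})

test_that("natural-spline extrapolation weights collapse to the linear filter", {
  # hand algebra: last-piece value = 2 x[p] - x[p-1] + M[p], and the natural
  # boundary pins M[p] = 0
  for (p in c(3, 4, 5, 8, 16)) {
    expect_equal(derive_spline_coeffs(p), c(2, -1, rep(0, p - 2)),
                 tolerance = 1e-9)
  }
  expect_error(derive_spline_coeffs(2))
  # impulse case, hand-solved tridiagonal system: x = (0,0,0,1) -> 2
  w <- derive_spline_coeffs(4)
  expect_equal(sum(w * rev(c(0, 0, 0, 1))), 2, tolerance = 1e-9)
})

test_that("spline and polynomial predictors reproduce constants and ramps", {
  for (method in c("linear", "poly2", "poly3", "spline")) {
    spec <- predictor_spec(method)
    const <- rep(7L, 20)
    expect_identical(predict_encode(const, spec)$residuals, rep(0, 20 - spec$p))
    ramp <- as.integer(1:20)
    expect_identical(predict_encode(ramp, spec)$residuals, rep(0, 20 - spec$p))
  }
  # delta on constants; worked first-difference example
  expect_identical(predict_encode(c(5L, 5L, 5L, 5L), predictor_spec("delta"))$residuals,
                   c(0, 0, 0))
  expect_identical(predict_encode(c(1L, 3L, 6L), predictor_spec("delta"))$residuals,
                   c(2, 3))
})

test_that("encode/decode are exact inverses for every method", {
  spec <- predictor_spec("linear")
  stream <- structure(list(warmup = c(1, 2), residuals = c(0, 0), p = 2L),
                      class = "residual_stream")
  expect_identical(predict_decode(stream, spec), as.integer(1:4))
  set.seed(9)
  for (i in 1:60) {
    x <- as.integer(rand_int16(sample(10:60, 1)))
    method <- sample(all_methods, 1)
    spec <- predictor_spec(method)
    expect_identical(predict_decode(predict_encode(x, spec), spec), x)
  }
  # signals shorter than p become pure warm-up and still round-trip
  spec <- predictor_spec("poly5")
  short <- as.integer(c(4, -4, 9))
  st <- predict_encode(short, spec)
  expect_identical(st$warmup, as.numeric(short))
  expect_identical(length(st$residuals), 0L)
  expect_identical(predict_decode(st, spec), short)
})

test_that("corrupt residuals that push samples out of int16 are detected", {
  spec <- predictor_spec("delta")
  stream <- predict_encode(c(32000L, 32500L), spec)
  stream$residuals <- stream$residuals + 5000
  expect_error(predict_decode(stream, spec), "int16")
})
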