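# closed-form oracle for p = 1: min_a sum |x[n] - a x[n-1]| is attained at a
# weighted median of the ratios x[n]/x[n-1] with weights |x[n-1]|
l1_ar1_oracle <- function(x) {
  y <- x[-1]; z <- x[-length(x)]
  keep <- z != 0
  b <- y[keep] / z[keep]; w <- abs(z[keep])
  o <- order(b); b <- b[o]; w <- w[o]
  b[which(cumsum(w) >= sum(w) / 2)[1]]
}

test_that("the L1 fit matches closed-form and grid-search oracles", {
  set.seed(31)
  for (i in 1:5) {
    x <- rand_walk_int16(400, sd = 15)
    fit <- fit_l1_ar(x, p = 1)
    oracle_a <- l1_ar1_oracle(as.numeric(x))
    obj <- function(a) sum(abs(x[-1] - a * x[-length(x)]))
    expect_lte(fit$objective, obj(oracle_a) + 1e-6)
    expect_equal(fit$objective, obj(coef(fit)), tolerance = 1e-9)
  }
  # p = 2: dense grid oracle
  set.seed(32)
  x <- as.numeric(rand_walk_int16(200, sd = 30))
  fit <- fit_l1_ar(x, p = 2)
  grid <- expand.grid(a1 = seq(0.5, 1.5, by = 0.01),
                      a2 = seq(-0.5, 0.5, by = 0.01))
  gobj <- apply(grid, 1, function(a) {
    sum(abs(x[3:200] - a[1] * x[2:199] - a[2] * x[1:198]))
  })
  expect_lte(fit$objective, min(gobj) + 1e-6)
})

test_that("ramps are predicted with zero objective and big penalties kill coefficients", {
  x <- as.integer(1:120)
  fit <- fit_l1_ar(x, p = 2)
  expect_lt(fit$objective, 1e-6)  # (2,-1) attains 0; solution may differ
  set.seed(33)
  x <- rand_walk_int16(200, sd = 10)
  fit <- suppressWarnings(fit_l1_ar(x, p = 3, lambda = 1e6))
  expect_lt(max(abs(coef(fit))), 1e-6)
  expect_equal(fit$objective, sum(abs(x[-(1:3)])), tolerance = 1e-6)
})

test_that("random-walk channels are near-optimally predicted by the delta filter", {
  set.seed(34)
  for (i in 1:3) {
    x <- rand_walk_int16(2000, sd = 20)
    fit <- fit_l1_ar(x, p = 4)
    expect_lte(fit$objective, fit$delta_objective + 1e-9)  # feasibility bound
    gap <- (fit$delta_objective - fit$objective) / fit$delta_objective
    expect_lt(gap, 0.02)
    expect_lt(max(abs(coef(fit) - c(1, 0, 0, 0))), 0.1)
  }
})

test_that("a sparse AR generating process is recovered at n = 5000", {
  set.seed(35)
  a_true <- c(0.5, 0, 0.25)
  for (noise in c(0, 5)) {
    innov <- round(stats::rnorm(5100, sd = 60))
    x <- numeric(5100)
    for (t in 4:5100) {
      x[t] <- round(sum(a_true * x[(t - 1):(t - 3)]) + innov[t] +
                      stats::rnorm(1, sd = noise))
    }
    x <- as.integer(x[101:5100])
    fit <- suppressWarnings(fit_l1_ar(x, p = 5))
    expect_lt(max(abs(coef(fit)[1:3] - a_true)), 0.05)
    expect_lt(max(abs(coef(fit)[4:5])), 0.05)
  }
})

test_that("MVAR finds cross-stream structure and never does worse than AR", {
  set.seed(36)
  base <- rand_walk_int16(600, sd = 25)
  delayed <- c(base[1], base[-length(base)])  # stream 2 = stream 1 lagged once
  fit <- suppressWarnings(fit_l1_mvar(list(base, delayed), p = 2))
  expect_lt(abs(fit$coefficients[2, 1, 1] - 1), 0.02)
  expect_lt(fit$per_target[2], 0.01 * sum(abs(delayed)))
  expect_lte(fit$objective, fit$ar_objective + 1e-6)
  # independent noise: MVAR still bounded by AR from the warm start
  chans <- replicate(3, as.integer(sample(-500:500, 300, TRUE)), simplify = FALSE)
  fit <- suppressWarnings(fit_l1_mvar(chans, p = 2))
  expect_lte(fit$objective, fit$ar_objective + 1e-6)
})

test_that("the relaxed size model tracks the exact Rice length within l bits", {
  expect_equal(approx_encoded_size(rep(0, 100), 0), 100)
  e <- c(5, -3, 2)
  expect_equal(approx_encoded_size(2 * e, 3), 3 + 9 + 2^-3 * sum(zigzag(2 * e)))
  set.seed(37)
  for (i in 1:10) {
    e <- unzigzag(stats::rgeom(500, prob = stats::runif(1, 0.005, 0.2)))
    m <- select_rice_order(e)
    exact <- sum(rice_encode(zigzag(e), m)$lengths)
    expect_lte(abs(exact - approx_encoded_size(e, m)), length(e))
  }
})

test_that("quantized optimal models reduce to the named specs and cost little", {
  set.seed(38)
  x <- rand_walk_int16(1500, sd = 20)
  fit <- fit_l1_ar(x, p = 3)
  fit$coefficients <- c(1, 0, 0)
  q <- quantize_model(fit, x)
  expect_identical(q$spec$coeffs_raw, q16_quantize(c(1, 0, 0)))
  # same residuals as the delta codec once the warm-up offset is aligned
  expect_identical(predict_encode(x, q$spec)$residuals[1:10],
                   predict_encode(x, predictor_spec("delta"))$residuals[3:12])
  fit$coefficients <- c(2, -1)
  fit$p <- 2L
  expect_identical(quantize_model(fit)$spec$coeffs_raw,
                   predictor_spec("linear")$coeffs_raw)
  # real random-walk fit: quantization changes the compressed size < 1%
  fit <- fit_l1_ar(x, p = 3)
  q <- quantize_model(fit, x)
  expect_lt(abs(1 - q$cr_ratio), 0.01)
  fit$coefficients <- c(40000, 0, 0)
  expect_error(quantize_model(fit), "range")
})
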