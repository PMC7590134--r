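#' @title Benchmarking harness: compression ratios and method comparison
#' @description
#' Runs every codec over every test case of a corpus, reports compression
#' ratios against the fixed-width CSV baseline, and applies the standard
#' machinery for comparing algorithms across many datasets: the Friedman
#' rank test with the Nemenyi post-hoc procedure across methods, and
#' one-way ANOVA with Tukey's HSD across data classes.
#' @name evaluate
NULL

#' First-order (Shannon) entropy
#'
#' `H = -sum(p * log2(p))` in bits per symbol, the coding-side lower bound
#' for a memoryless source. Accepts either symbol counts or probabilities;
#' `0 * log2(0)` is taken as 0.
#'
#' @param x non-negative counts, or probabilities summing to 1 (within
#'   1e-9).
#' @return entropy in bits.
#' @examples
#' first_order_entropy(c(0.5, 0.5))        # 1
#' first_order_entropy(table(c(1, 1, 2, 3)))
#' @export
first_order_entropy <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("negative count or probability")
  s <- sum(x)
  if (s <= 0) stop("all-zero input")
  p <- if (abs(s - 1) <= 1e-9) x else x / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy of a sample sequence
#'
#' Convenience wrapper: empirical first-order entropy of the symbols in a
#' signal (e.g. of delta residuals, as a pre-coding diagnostic).
#'
#' @param samples integer vector.
#' @return bits per symbol.
#' @export
signal_entropy <- function(samples) {
  first_order_entropy(table(samples))
}

#' Compression ratio
#'
#' `CR = original bytes / compressed bytes`, the paper-standard figure of
#' merit with the fixed-width CSV as the size-1 baseline.
#'
#' @param original_bytes,compressed_bytes positive sizes in bytes.
#' @return the ratio.
#' @export
compression_ratio <- function(original_bytes, compressed_bytes) {
  if (any(original_bytes <= 0) || any(compressed_bytes <= 0)) {
    stop("sizes must be positive")
  }
  original_bytes / compressed_bytes
}

#' Raw streaming bandwidth of a full-body kinematic setup
#'
#' The back-of-the-envelope bandwidth of uncompressed full-body motion
#' capture: `rate * segments * axes * bits` bits per second, reported in
#' Mbps. The defaults — 500 Hz, 15 body segments, 9 axes, 32-bit samples —
#' give 2.16 Mbps, about the bandwidth of an HD video stream and more than
#' Bluetooth or Zigbee can carry, which is the case for compressing these
#' signals at all.
#'
#' @param rate_hz sampling rate per axis.
#' @param segments number of instrumented body segments.
#' @param axes axes per segment.
#' @param bits bits per sample.
#' @return bandwidth in Mbps (1e6 bits/s).
#' @export
raw_stream_bandwidth <- function(rate_hz = 500, segments = 15, axes = 9,
                                 bits = 32) {
  rate_hz * segments * axes * bits / 1e6
}

#' Friedman rank test across methods
#'
#' Ranks the methods within every test case (rank 1 = highest CR, average
#' ranks on ties) and computes the classic Friedman statistic
#' `chi2_F = 12 / (N k (k+1)) * sum(Rj^2) - 3 N (k+1)` on the column rank
#' sums `Rj`, referred to a chi-squared distribution with k-1 degrees of
#' freedom. A matrix with every row fully tied yields statistic 0, p = 1.
#'
#' @param cr matrix of compression ratios, N test cases x k methods.
#' @return list with `statistic`, `p_value`, `mean_ranks` (named), `N`,
#'   `k`.
#' @export
friedman_rank_test <- function(cr) {
  cr <- as.matrix(cr)
  N <- nrow(cr); k <- ncol(cr)
  if (N < 2 || k < 2) stop("need at least 2 test cases and 2 methods")
  ranks <- t(apply(cr, 1, function(row) rank(-row, ties.method = "average")))
  Rj <- colSums(ranks)
  stat <- 12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
  stat <- max(stat, 0)  # guard tiny negative round-off on all-tied input
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       mean_ranks = Rj / N, N = N, k = k)
}

#' Nemenyi post-hoc comparison
#'
#' After a rejected Friedman test, two methods differ significantly when
#' their mean ranks differ by at least the critical difference
#' `CD = q_alpha(k) * sqrt(k (k+1) / (6 N))`, with `q_alpha(k)` the
#' studentized-range quantile at infinite df divided by sqrt(2).
#'
#' @param mean_ranks named vector of mean ranks (from
#'   [friedman_rank_test()]).
#' @param N number of test cases.
#' @param alpha significance level (default 0.05).
#' @return list with `cd` (critical difference), `diff` (pairwise
#'   mean-rank differences) and `significant` (logical matrix).
#' @export
nemenyi_posthoc <- function(mean_ranks, N, alpha = 0.05) {
  k <- length(mean_ranks)
  stopifnot(k >= 2, N >= 1)
  q <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2)
  cd <- q * sqrt(k * (k + 1) / (6 * N))
  d <- abs(outer(mean_ranks, mean_ranks, `-`))
  list(cd = cd, q = q, diff = d, significant = d >= cd)
}

#' One-way ANOVA with Tukey HSD across data classes
#'
#' Tests whether a codec's compression ratios differ across data classes
#' (movement activities), then locates the differing pairs with Tukey's
#' honest significant difference. Delegates to `stats::aov()` and
#' `stats::TukeyHSD()`.
#'
#' @param cr numeric vector of compression ratios.
#' @param class factor (or coercible) of the same length: the data class
#'   of each observation; every class needs >= 2 observations.
#' @param alpha significance level (default 0.05).
#' @return list with `F`, `p_value`, `tukey` (the Tukey table) and
#'   `significant_pairs` (character vector of pairs below `alpha`).
#' @export
anova_tukey <- function(cr, class, alpha = 0.05) {
  class <- factor(class)
  if (nlevels(class) < 2) stop("need at least two data classes")
  if (any(table(class) < 2)) stop("every class needs at least two observations")
  df <- data.frame(cr = cr, class = class)
  fit <- stats::aov(cr ~ class, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$class
  list(F = an[["F value"]][1],
       p_value = an[["Pr(>F)"]][1],
       tukey = tk,
       significant_pairs = rownames(tk)[tk[, "p adj"] < alpha])
}

#' Run the full compression benchmark over a corpus
#'
#' Compresses every test case with every method, computes per-case
#' compression ratios against the fixed-width CSV baseline (binary and
#' DEFLATE baselines are reported alongside), and runs the method-level
#' Friedman/Nemenyi comparison plus, for the best-ranked method, the
#' activity-level ANOVA/Tukey comparison. Failures on individual cases are
#' recorded and skipped, never fatal.
#'
#' @param corpus list of test cases (see [synth_corpus()] /
#'   [build_corpus()]).
#' @param methods character vector of codec names (default all seven).
#' @param rice_mode passed to [kc_compress()].
#' @return object of class `kc_benchmark`: `cases` (long data frame of
#'   per-case sizes and CRs), `summary` (mean CR per method), `by_activity`
#'   (mean CR of the best method per activity), `friedman`, `nemenyi`,
#'   `anova` (NULL when the corpus is too small), `failures`.
#' @export
run_benchmark <- function(corpus, methods = KC_METHODS,
                          rice_mode = "exhaustive") {
  stopifnot(length(corpus) >= 1)
  rows <- list(); failures <- list()
  for (i in seq_along(corpus)) {
    case <- corpus[[i]]
    channels <- case$channels
    csv_b <- length(write_fixed_csv(channels))
    bin_b <- length(write_binary_int16(channels))
    zip_b <- deflate_size(write_fixed_csv(channels))
    for (method in methods) {
      comp_b <- tryCatch(length(kc_compress(channels, method = method,
                                            rice_mode = rice_mode)),
                         error = function(e) {
                           failures[[length(failures) + 1L]] <<-
                             list(case = i, method = method,
                                  message = conditionMessage(e))
                           NA_integer_
                         })
      rows[[length(rows) + 1L]] <- data.frame(
        case = i,
        activity = case$meta$activity %||% NA_character_,
        segment = case$meta$segment %||% NA_character_,
        method = method,
        csv_bytes = csv_b, binary_bytes = bin_b, deflate_bytes = zip_b,
        compressed_bytes = comp_b,
        cr = if (is.na(comp_b)) NA_real_ else compression_ratio(csv_b, comp_b),
        stringsAsFactors = FALSE)
    }
  }
  cases <- do.call(rbind, rows)
  ok <- !is.na(cases$cr)
  mean_cr <- tapply(cases$cr[ok], cases$method[ok], mean)[methods]
  # wide CR matrix for the rank tests
  crmat <- matrix(cases$cr, ncol = length(methods), byrow = TRUE,
                  dimnames = list(NULL, methods))
  fr <- nem <- an <- by_activity <- NULL
  if (nrow(crmat) >= 2 && ncol(crmat) >= 2 && !anyNA(crmat)) {
    fr <- friedman_rank_test(crmat)
    if (fr$p_value < 0.05) nem <- nemenyi_posthoc(fr$mean_ranks, fr$N)
  } else if (nrow(crmat) < 2) {
    warning("corpus has a single test case: rank statistics not computed")
  }
  best <- methods[which.max(mean_cr)]
  sub <- cases[cases$method == best & ok, ]
  if (length(unique(sub$activity)) >= 2 && all(table(sub$activity) >= 2)) {
    an <- anova_tukey(sub$cr, sub$activity)
  }
  by_activity <- tapply(sub$cr, sub$activity, mean)
  structure(
    list(cases = cases, summary = mean_cr, best_method = best,
         by_activity = by_activity, friedman = fr, nemenyi = nem,
         anova = an, failures = failures),
    class = "kc_benchmark")
}

#' @export
print.kc_benchmark <- function(x, ...) {
  cat("IMU compression benchmark over",
      length(unique(x$cases$case)), "test cases\n\n")
  cat("Mean compression ratio per method (CSV baseline = 1):\n")
  print(round(x$summary, 3))
  if (!is.null(x$friedman)) {
    cat(sprintf("\nFriedman chi^2 = %.2f (p = %.3g); mean ranks:\n",
                x$friedman$statistic, x$friedman$p_value))
    print(round(x$friedman$mean_ranks, 2))
  }
  if (!is.null(x$by_activity)) {
    cat(sprintf("\nMean CR of %s by activity:\n", x$best_method))
    print(round(x$by_activity, 2))
  }
  if (length(x$failures)) {
    cat("\n", length(x$failures), "case failures recorded\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
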