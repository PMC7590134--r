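# Signal builders shared across tests. All draw from the session RNG, so
# callers set a seed first.

all_methods <- c("delta", "linear", "poly2", "poly3", "poly4", "poly5",
                 "spline")

rand_int16 <- function(n) sample(-32768:32767, n, replace = TRUE)

# integer random walk with rounded-Gaussian steps, reflected into int16
rand_walk_int16 <- function(n, sd = 20) {
  x <- cumsum(round(stats::rnorm(n, sd = sd)))
  x <- x - round(mean(x))
  # fold back any excursion beyond the representable range
  while (any(x > 32767 | x < -32768)) {
    x <- ifelse(x > 32767, 65534 - x, x)
    x <- ifelse(x < -32768, -65536 - x, x)
  }
  as.integer(x)
}

# a small mixed bag of channels exercising all signal shapes
random_test_channels <- function() {
  kind <- sample(3, 1)
  n <- sample(30:80, 1)
  s <- sample(1:3, 1)
  lapply(seq_len(s), function(i) {
    switch(kind,
           as.integer(rand_int16(n)),
           rand_walk_int16(n, sd = sample(c(1, 20, 400), 1)),
           as.integer(round(3000 * sin(seq_len(n) / sample(3:15, 1)) +
                              stats::rnorm(n, sd = 30))))
  })
}
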