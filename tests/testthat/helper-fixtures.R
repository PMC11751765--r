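# Shared small fixtures, built in code.

# tiny but valid grid world: 3 x 3 cells, n_years years
tiny_config <- function(n_years = 4L, seed = 11L, ...) {
  synthetic_config(n_lat = 3L, n_lon = 3L, n_years = n_years, seed = seed,
                   ...)
}

# deterministic daily date axis
daily_dates <- function(n_years = 3L, start = "2003-01-01") {
  start <- as.Date(start)
  end <- seq(start, by = paste(n_years, "years"), length.out = 2)[2] - 1
  seq(start, end, by = "day")
}

# independent residual-correlation oracle for the partial correlation:
# Pearson correlation of the least-squares residuals of x on z and y on z
pcor_residual_oracle <- function(x, y, z) {
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  cor(rx, ry)
}

# brute-force Theil-Sen: explicit double loop over all pairs
theil_sen_bruteforce <- function(x, y) {
  n <- length(x)
  slopes <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
    }
  }
  median(slopes)
}

# brute-force Benjamini-Hochberg step-up: sort, compare to i*q/m, reject all
# p-values up to the largest index passing
bh_bruteforce <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  pass <- which(ps <= (seq_len(m) / m) * q)
  reject <- logical(m)
  if (length(pass)) reject[ord[seq_len(max(pass))]] <- TRUE
  reject
}

# naive local linear regression with tricube weights (LOWESS, iter = 0)
lowess_naive <- function(x, y, frac) {
  n <- length(x)
  k <- max(2, ceiling(frac * n))
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d, partial = k)[k]
    w <- (1 - pmin(1, d / h)^3)^3
    keep <- w > 0
    fit <- lm(y ~ x, weights = w, subset = keep)
    unname(predict(fit, data.frame(x = x[i])))
  }, numeric(1))
}
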