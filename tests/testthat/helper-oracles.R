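# Independent brute-force multi-tau estimator (pure R, direct O(N^2) sums)
# used as the oracle for the compiled correlator.
brute_multitau <- function(x, bin_width, max_lag, m = 16) {
  x <- as.numeric(x)
  binw <- bin_width
  lags <- numeric(0)
  g <- numeric(0)
  stage <- 0
  repeat {
    n <- length(x)
    if (n < 2 * m) break
    mu <- mean(x)
    if (mu <= 0) break
    klo <- if (stage == 0) 1 else m / 2 + 1
    done <- FALSE
    for (k in klo:m) {
      lag <- k * binw
      if (lag > max_lag) {
        done <- TRUE
        break
      }
      nk <- n - k
      lags <- c(lags, lag)
      g <- c(g, sum(x[1:nk] * x[(k + 1):n]) / (nk * mu^2))
    }
    if (done) break
    n2 <- floor(n / 2)
    x <- x[seq(1, 2 * n2, by = 2)] + x[seq(2, 2 * n2, by = 2)]
    binw <- binw * 2
    stage <- stage + 1
  }
  data.frame(lag = lags, g = g)
}

# Evaluate the FCS diffusion models on a log-spaced lag grid (for noiseless
# fit round trips).
model_curve_2d <- function(g0, tau, lags) {
  structure(data.frame(lag = lags, g = 1 + g0 / (1 + lags / tau)),
            class = c("correlation_curve", "data.frame"))
}

model_curve_2d1r <- function(g0, tau, A, tR, lags) {
  g <- 1 + g0 / (1 + lags / tau) * (1 + A * exp(-lags / tR))
  structure(data.frame(lag = lags, g = g),
            class = c("correlation_curve", "data.frame"))
}

log_lags <- function(from = 2e-6, to = 1, n = 120) {
  exp(seq(log(from), log(to), length.out = n))
}
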