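test_that("autocorrelation of a constant trace is 1 at all lags", {
  cur <- autocorrelate(rep(5, 4096), max_lag = 0.1, bin_width = 1e-3)
  expect_true(all(abs(cur$g - 1) < 1e-12))
  expect_true(all(diff(cur$lag) > 0))
})

test_that("Poisson shot noise is uncorrelated at every positive lag", {
  set.seed(13)
  x <- rpois(2e5, 1)
  cur <- autocorrelate(x, max_lag = 0.05, bin_width = 1e-3)
  # the estimator s.e. is < 0.005 at every stage here; 0.02 is > 4 sigma
  expect_true(all(abs(cur$g - 1) < 0.02))
  expect_lt(abs(mean(cur$g) - 1), 0.005)
})

test_that("multi-tau correlator equals the brute-force estimator", {
  set.seed(17)
  for (n in c(1000, 10000)) {
    x <- rpois(n, 2) + rep(c(0L, 3L), length.out = n)
    cur <- autocorrelate(x, max_lag = (n / 4) * 1e-3, bin_width = 1e-3)
    oracle <- brute_multitau(x, 1e-3, (n / 4) * 1e-3)
    expect_equal(nrow(cur), nrow(oracle))
    expect_equal(cur$lag, oracle$lag, tolerance = 1e-12)
    expect_equal(cur$g, oracle$g, tolerance = 1e-10)
  }
})

test_that("degenerate traces are rejected", {
  expect_error(autocorrelate(rep(0, 100), max_lag = 0.01, bin_width = 1e-3),
               "degenerate")
  expect_error(autocorrelate(rep(1, 100), max_lag = 1, bin_width = 1e-3),
               "max_lag")
})

test_that("noiseless 2D and 2D1R model curves round-trip through the fit", {
  lags <- log_lags()
  f2 <- fit_fcs_model(model_curve_2d(0.1, 150e-6, lags), "2D")
  expect_equal(f2$g0, 0.1, tolerance = 1e-6)
  expect_equal(f2$tau_app, 150e-6, tolerance = 1e-6)
  expect_null(f2$A)

  f3 <- fit_fcs_model(model_curve_2d1r(0.05, 400e-6, 0.3, 5e-6, lags), "2D1R")
  expect_equal(f3$g0, 0.05, tolerance = 1e-6)
  expect_equal(f3$tau_app, 400e-6, tolerance = 1e-6)
  expect_equal(f3$A, 0.3, tolerance = 1e-5)
  expect_equal(f3$t_R, 5e-6, tolerance = 1e-5)
})

test_that("2D-model bias on a 3D Gaussian focus shrinks with aspect ratio", {
  # closed-form check behind the simulator's default wz/wxy = 10: fitting
  # the 2D model to the exact 3D-focus correlation biases tau by ~-7% at
  # aspect ratio 5 but only ~-2% at ratio 10
  tau <- 150e-6
  bias_at <- function(S) {
    lags <- log_lags(1e-5, 1, 200)
    g <- 1 + 0.1 / (1 + lags / tau) / sqrt(1 + lags / (S^2 * tau))
    curve <- structure(data.frame(lag = lags, g = g),
                       class = c("correlation_curve", "data.frame"))
    (fit_fcs_model(curve, "2D")$tau_app - tau) / tau
  }
  expect_lt(abs(bias_at(5) - (-0.072)), 0.005)
  expect_lt(abs(bias_at(10) - (-0.021)), 0.005)
})

test_that("quadratic threshold extrapolation recovers an exact intercept", {
  x <- c(4, 8, 12, 16, 20)
  tau <- 151e-6 + 2.5e-7 * x^2
  sweep <- unbiased_tau(x, tau)
  expect_equal(sweep$tau, 151e-6, tolerance = 1e-9)
  expect_equal(sweep$curvature, 2.5e-7, tolerance = 1e-6)
  expect_error(unbiased_tau(c(5, 5, 5), rep(1e-4, 3)), "distinct")
  expect_error(unbiased_tau(x[1:2], tau[1:2]), "distinct|length")
  # negative intercept is a fit failure, not a silent answer
  expect_error(unbiased_tau(x, 1e-6 * x^2 - 1e-5), "non-positive")
})

test_that("simulated single-species trace yields tau near truth by plain FCS", {
  sim <- single_species_sim()
  fit <- fit_fcs_model(autocorrelate(sim$trace, max_lag = 1), "2D")
  expect_lt(abs(fit$tau_app - 150e-6) / 150e-6, 0.15)
  # G0 should reflect the mean focal occupancy within Monte-Carlo error;
  # background photons dilute the amplitude, so compare after correction
  trace <- sim$trace
  total_rate <- mean(trace$donor + trace$acceptor)
  bg_rate <- 0.002
  signal_frac <- (total_rate - bg_rate) / total_rate
  occupancy <- 6 * pi^1.5 * 0.25e-6^2 * 2.5e-6 / 6e-6^3
  expect_lt(abs(fit$g0 / signal_frac^2 - 1 / occupancy) * occupancy, 0.25)
})

test_that("pscfcs_apparent_tau on an everything-selection matches plain FCS", {
  sim <- single_species_sim()
  trace <- sim$trace
  conv <- fit_fcs_model(autocorrelate(trace, max_lag = 1), "2D")
  all_win <- data.frame(start_bin = 1L, end_bin = length(trace))
  bg <- background_model(0.001, 0.001)
  psc <- pscfcs_apparent_tau(trace, all_win, bg, threshold_used = 0, seed = 9)
  expect_lt(abs(psc$tau_app - conv$tau_app) / conv$tau_app, 0.1)
  expect_error(
    pscfcs_apparent_tau(trace, data.frame(start_bin = integer(),
                                          end_bin = integer()),
                        bg, 0, seed = 1),
    "empty selection")
})
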