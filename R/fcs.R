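#' Multi-tau autocorrelation of an intensity trace
#'
#' Computes the normalized intensity autocorrelation
#' `G(t) = <I(0) I(t)> / <I>^2` on a quasi-logarithmic lag grid: `m` linearly
#' spaced lags per stage with x2 rebinning between stages (the standard
#' multi-tau cascade).  Within each stage the estimator equals the direct
#' sum `sum_i I(i) I(i+k) / ((N-k) <I>^2)` evaluated on the stage's rebinned
#' series.
#'
#' For FRET-labelled species the donor and acceptor channels should be summed
#' before correlating, which cancels the donor/acceptor anti-correlation from
#' FRET dynamics; `channel = "sum"` (default) does this.
#'
#' @param trace A [binned_trace()] or a numeric intensity vector.
#' @param max_lag Largest lag time, seconds; must be below the trace duration.
#' @param bin_width Bin width in seconds (required when `trace` is a plain
#'   vector).
#' @param m Lags per stage of the multi-tau cascade (default 16).
#' @param channel `"sum"`, `"donor"` or `"acceptor"` when `trace` is a
#'   `binned_trace`.
#' @return A data frame of class `correlation_curve` with columns `lag`
#'   (seconds, increasing) and `g`.
#' @export
autocorrelate <- function(trace, max_lag, bin_width = NULL, m = 16L,
                          channel = c("sum", "donor", "acceptor")) {
  if (inherits(trace, "binned_trace")) {
    channel <- match.arg(channel)
    x <- switch(channel,
                sum = as.numeric(trace$donor) + as.numeric(trace$acceptor),
                donor = as.numeric(trace$donor),
                acceptor = as.numeric(trace$acceptor))
    bin_width <- trace$bin_width
  } else {
    if (is.null(bin_width)) stop("`bin_width` required for a plain vector")
    x <- as.numeric(trace)
  }
  if (length(x) < 2L || mean(x) <= 0) {
    stop("degenerate trace: need >= 2 bins with positive mean intensity")
  }
  if (max_lag >= length(x) * bin_width) {
    stop("`max_lag` must be smaller than the trace duration")
  }
  res <- cpp_multitau(x, bin_width, max_lag, as.integer(m))
  structure(data.frame(lag = res$lag, g = res$g),
            class = c("correlation_curve", "data.frame"),
            bin_width = bin_width, m = as.integer(m))
}

#' Fit a diffusion model to an FCS curve
#'
#' Models: `"2D"` is `G(t) = 1 + G0 / (1 + t/tau)`, the two-dimensional free
#' diffusion form used throughout the pipeline; `"2D1R"` multiplies it by one
#' exponential relaxation term `(1 + A exp(-t/t_R))` for fast photophysics.
#' Unweighted least squares over the lag window.
#'
#' @param curve A `correlation_curve`.
#' @param model `"2D"` or `"2D1R"`.
#' @param fit_window Lag window `(t_min, t_max)` in seconds; default
#'   `c(1e-5, 1)`.
#' @param start Optional named list of starting values.
#' @return A list of class `fcs_fit`: `g0`, `tau_app` (seconds), optional
#'   `A`, `t_R`, plus `model`, `fit_window`, `residual_norm` and the fitted
#'   `curve` subset.
#' @export
fit_fcs_model <- function(curve, model = c("2D", "2D1R"),
                          fit_window = c(1e-5, 1), start = NULL) {
  model <- match.arg(model)
  sel <- curve$lag >= fit_window[1] & curve$lag <= fit_window[2]
  if (sum(sel) < if (model == "2D") 3L else 5L) {
    stop("correlation curve does not cover the fit window")
  }
  t <- curve$lag[sel]
  g <- curve$g[sel]
  if (is.null(start)) {
    g0_0 <- max(max(g) - 1, 1e-4)
    half <- 1 + g0_0 / 2
    tau_0 <- t[which.min(abs(g - half))]
    tau_0 <- max(tau_0, t[1])
    start <- list(g0 = g0_0, tau = tau_0)
    if (model == "2D1R") start <- c(start, list(A = 0.1, tR = tau_0 / 20))
  }
  dat <- data.frame(t = t, g = g)
  fit <- tryCatch({
    if (model == "2D") {
      minpack.lm::nlsLM(g ~ 1 + g0 / (1 + t / tau), data = dat,
                        start = list(g0 = start$g0, tau = start$tau),
                        lower = c(1e-12, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(g ~ 1 + g0 / (1 + t / tau) * (1 + A * exp(-t / tR)),
                        data = dat,
                        start = list(g0 = start$g0, tau = start$tau,
                                     A = start$A, tR = start$tR),
                        lower = c(1e-12, 1e-12, 0, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) stop("FCS fit failed: ", conditionMessage(e)))
  p <- coef(fit)
  out <- list(g0 = unname(p["g0"]), tau_app = unname(p["tau"]),
              A = if (model == "2D1R") unname(p["A"]) else NULL,
              t_R = if (model == "2D1R") unname(p["tR"]) else NULL,
              model = model, fit_window = fit_window,
              residual_norm = sqrt(sum(stats::residuals(fit)^2)),
              curve = dat)
  class(out) <- "fcs_fit"
  out
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("<fcs_fit %s> G0 = %.4g, tau_app = %.4g s", x$model, x$g0,
              x$tau_app))
  if (!is.null(x$A)) cat(sprintf(", A = %.3g, t_R = %.3g s", x$A, x$t_R))
  cat(sprintf("  (residual norm %.3g)\n", x$residual_norm))
  invisible(x)
}

#' Apparent diffusion time of a selected subpopulation at one threshold
#'
#' The core of subpopulation-selective FCS at a single peak threshold: mask
#' the fine trace (keep the selected burst windows, replace everything else
#' by Poisson background), sum the channels, autocorrelate, and fit the 2D
#' diffusion model.
#'
#' @param trace_fine The [binned_trace()] at acquisition binning.
#' @param windows Fine-bin keep windows (`start_bin`/`end_bin`, 1-based
#'   inclusive), e.g. from [map_windows()]; must be non-empty.
#' @param background A [background_model()] at the fine binning.
#' @param threshold_used The peak threshold that produced `windows`
#'   (recorded in the result).
#' @param seed Seed for the Poisson replacement noise.
#' @param fit_window Lag window for the model fit, seconds.
#' @param max_lag Largest correlation lag, seconds.
#' @return An `fcs_fit` with an extra `threshold` element.
#' @export
pscfcs_apparent_tau <- function(trace_fine, windows, background,
                                threshold_used, seed,
                                fit_window = c(1e-5, 1), max_lag = 1) {
  if (nrow(windows) == 0L) {
    stop("empty selection: no burst windows to correlate")
  }
  masked <- poisson_masked_trace(trace_fine, windows, background, seed)
  curve <- autocorrelate(masked, max_lag = max_lag)
  fit <- fit_fcs_model(curve, model = "2D", fit_window = fit_window)
  fit$threshold <- threshold_used
  fit
}

#' Threshold sweep of the subpopulation-selective FCS pipeline
#'
#' Runs the whole per-threshold pipeline over a set of peak thresholds:
#' rebin the fine trace to the burst-analysis binning, detect bursts at each
#' threshold, background-correct their FRET efficiencies, select the
#' efficiency window, map the kept bursts back to fine-trace windows, mask,
#' correlate and fit.  Finish with [unbiased_tau()] to extrapolate the
#' threshold bias away.
#'
#' @param trace_fine The [binned_trace()] at acquisition binning.
#' @param e_min,e_max Apparent-efficiency selection window (closed interval).
#' @param thresholds Peak thresholds in counts per burst-analysis bin.  The
#'   default starts above the Poisson tail of the expected background (a few
#'   counts per ms), where detected bursts are molecular transits rather
#'   than background excursions.
#' @param burst_bin_width Burst-analysis bin width, seconds (default 1 ms).
#' @param guard_bins Number of burst-analysis bins kept on each side of a
#'   selected burst.  The margin keeps the gate length approximately
#'   threshold-independent, so the rectangular selection gate does not
#'   truncate the correlation tail more at high thresholds.
#' @param seed Seed for the Poisson replacement noise (one stream per
#'   threshold, derived deterministically).
#' @param fit_window,max_lag Passed to [pscfcs_apparent_tau()].
#' @return A data frame of class `pscfcs_sweep_result` with columns
#'   `threshold`, `tau_app`, `g0`, `n_bursts`.
#' @export
pscfcs_sweep <- function(trace_fine, e_min, e_max,
                         thresholds = c(8, 11, 14, 17, 20),
                         burst_bin_width = 1e-3, guard_bins = 1L, seed = 1L,
                         fit_window = c(1e-5, 1), max_lag = 1) {
  stopifnot(inherits(trace_fine, "binned_trace"))
  thresholds <- sort(unique(thresholds))
  factor <- max(1L, round(burst_bin_width / trace_fine$bin_width))
  coarse <- if (factor > 1L) rebin(trace_fine, factor) else trace_fine
  rows <- lapply(seq_along(thresholds), function(i) {
    th <- thresholds[i]
    bursts <- detect_bursts(coarse, th)
    if (nrow(bursts) == 0L) return(NULL)
    bg_coarse <- estimate_background(coarse, bursts)
    bursts <- background_correct_bursts(bursts, bg_coarse)
    sel <- select_by_efficiency(bursts, e_min, e_max)
    if (nrow(sel) == 0L) return(NULL)
    if (guard_bins > 0L) {
      sel$start_bin <- pmax(1L, sel$start_bin - as.integer(guard_bins))
      sel$end_bin <- pmin(length(coarse), sel$end_bin + as.integer(guard_bins))
    }
    win <- map_windows(sel, coarse$bin_width, trace_fine$bin_width,
                       length(trace_fine))
    scale <- coarse$bin_width / trace_fine$bin_width
    bg_fine <- background_model(bg_coarse$donor_rate / scale,
                                bg_coarse$acceptor_rate / scale)
    fit <- pscfcs_apparent_tau(trace_fine, win, bg_fine, th,
                               seed = seed + i, fit_window = fit_window,
                               max_lag = max_lag)
    data.frame(threshold = th, tau_app = fit$tau_app, g0 = fit$g0,
               n_bursts = nrow(sel))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop("no threshold produced a non-empty selection")
  }
  structure(out, class = c("pscfcs_sweep_result", "data.frame"), seed = seed)
}

#' Extrapolate the apparent diffusion time to zero threshold
#'
#' The peak threshold biases the apparent diffusion time of the
#' subpopulation-selective correlation upward; empirically the bias is
#' quadratic in the threshold, `tau_app = tau + a x^2`.  An unweighted
#' least-squares fit of that relation yields the unbiased diffusion time
#' `tau` as the intercept.
#'
#' @param thresholds Peak thresholds `x` (counts per bin), or a
#'   `pscfcs_sweep_result`.
#' @param tau_apps Apparent diffusion times, seconds (omit when passing a
#'   sweep result).
#' @return A list of class `threshold_sweep`: `thresholds`, `tau_apps`,
#'   `tau` (intercept, seconds), `tau_se`, `curvature`, `residuals`.
#' @export
unbiased_tau <- function(thresholds, tau_apps = NULL) {
  if (inherits(thresholds, "pscfcs_sweep_result")) {
    tau_apps <- thresholds$tau_app
    thresholds <- thresholds$threshold
  }
  if (length(thresholds) != length(tau_apps)) {
    stop("`thresholds` and `tau_apps` must have equal length")
  }
  if (length(unique(thresholds)) < 3L) {
    stop("need >= 3 distinct thresholds to extrapolate")
  }
  if (any(tau_apps <= 0)) stop("apparent diffusion times must be positive")
  x2 <- thresholds^2
  fit <- lm(tau_apps ~ x2)
  tau <- unname(coef(fit)[1])
  if (tau <= 0) stop("extrapolated diffusion time is non-positive")
  structure(list(thresholds = thresholds, tau_apps = tau_apps, tau = tau,
                 tau_se = suppressWarnings(summary(fit)$coefficients[1, 2]),
                 curvature = unname(coef(fit)[2]),
                 residuals = unname(stats::residuals(fit))),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf(
    "<threshold_sweep> tau = %.4g +/- %.2g s over %d thresholds (a = %.3g)\n",
    x$tau, x$tau_se, length(x$thresholds), x$curvature))
  invisible(x)
}

#' Write a correlation curve as delimited text
#'
#' @param curve A `correlation_curve`.
#' @param path File path.
#' @export
write_correlation <- function(curve, path) {
  write.table(data.frame(lag_s = curve$lag, g = curve$g), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
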