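#' Apparent FRET efficiency from channel photon sums
#'
#' `E = acceptor / (donor + acceptor)`, the ratiometric proximity observable
#' of burst-wise single-molecule FRET.
#'
#' @param donor_sum,acceptor_sum Photon counts (vectors recycle).
#' @return Efficiencies; errors if any total is zero or negative.
#' @examples
#' fret_efficiency(30, 70) # 0.7
#' @export
fret_efficiency <- function(donor_sum, acceptor_sum) {
  total <- donor_sum + acceptor_sum
  if (any(total <= 0)) {
    stop("undefined efficiency: donor + acceptor must be positive")
  }
  acceptor_sum / total
}

#' Histogram of burst FRET efficiencies with Gaussian decomposition
#'
#' Builds a (normalized) histogram of burst-wise apparent efficiencies and
#' fits a sum of `n_components` Gaussians by unweighted least squares on the
#' bin densities.  Also usable on arbitrary scalar samples (e.g. acceptor
#' photon counts under direct excitation) by passing a numeric vector and an
#' explicit `range`.
#'
#' @param x A `burst_table` (its `e_app` column is used) or a numeric vector.
#' @param bin_width Histogram bin width; default 0.02 efficiency units.
#' @param n_components Number of Gaussian components (>= 1).
#' @param range Histogram support; default `c(-0.2, 1.2)` spans the
#'   background-corrected efficiency scale including the donor-only peak.
#' @param start Optional list of starting values (`mean`, `sigma`,
#'   `amplitude` vectors) for the decomposition.
#' @return A list of class `fret_histogram`: `breaks`, `counts`, `density`,
#'   `mids`, `n`, and `peaks` — a data frame (`mean`, `sigma`, `amplitude`,
#'   `area`) sorted by mean.
#' @export
fret_histogram <- function(x, bin_width = 0.02, n_components = 1L,
                           range = c(-0.2, 1.2), start = NULL) {
  values <- if (inherits(x, "burst_table") || is.data.frame(x)) x$e_app else x
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("need at least one burst / value")
  if (n_components < 1L) stop("`n_components` must be >= 1")
  if (is.null(range)) range <- grDevices::extendrange(values, f = 0.05)
  breaks <- seq(range[1], range[2] + bin_width / 2, by = bin_width)
  values <- pmin(pmax(values, range[1]), max(breaks) - 1e-12)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  peaks <- fit_gaussian_mixture(h$mids, h$density, values,
                                n_components, start)
  structure(list(breaks = h$breaks, counts = h$counts, density = h$density,
                 mids = h$mids, n = length(values), peaks = peaks),
            class = "fret_histogram")
}

# Least-squares decomposition of a histogram density into Gaussian peaks.
# Starting values come from k-means clustering of the raw sample.
fit_gaussian_mixture <- function(mids, density, values, k, start = NULL) {
  if (is.null(start)) {
    if (k == 1L) {
      mu0 <- mean(values)
      s0 <- max(sd(values), 1e-3)
      if (is.na(s0)) s0 <- 1e-2
      a0 <- 1 / (s0 * sqrt(2 * pi))
    } else {
      km <- kmeans(values, centers = k, nstart = 5)
      o <- order(km$centers)
      mu0 <- as.numeric(km$centers)[o]
      s0 <- vapply(seq_len(k), function(j) {
        s <- sd(values[km$cluster == j])
        if (is.na(s) || s < 1e-3) 1e-2 else s
      }, numeric(1))[o]
      w <- (km$size / length(values))[o]
      a0 <- w / (s0 * sqrt(2 * pi))
    }
    start <- list(mean = mu0, sigma = s0, amplitude = a0)
  }
  k <- length(start$mean)
  par0 <- c(start$mean, log(start$sigma), log(pmax(start$amplitude, 1e-12)))
  model <- function(p, x) {
    mu <- p[1:k]
    s <- exp(p[(k + 1):(2 * k)])
    a <- exp(p[(2 * k + 1):(3 * k)])
    rowSums(vapply(seq_len(k), function(j) {
      a[j] * exp(-(x - mu[j])^2 / (2 * s[j]^2))
    }, numeric(length(x))))
  }
  resid_fun <- function(p) density - model(p, mids)
  fit <- minpack.lm::nls.lm(par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 5)) {
    stop(sprintf("Gaussian decomposition did not converge (residual norm %.3g)",
                 sqrt(sum(resid_fun(fit$par)^2))))
  }
  p <- fit$par
  peaks <- data.frame(mean = p[1:k], sigma = exp(p[(k + 1):(2 * k)]),
                      amplitude = exp(p[(2 * k + 1):(3 * k)]))
  peaks$area <- peaks$amplitude * peaks$sigma * sqrt(2 * pi)
  peaks[order(peaks$mean), , drop = FALSE]
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat(sprintf("<fret_histogram> %d values in %d bins\n", x$n,
              length(x$counts)))
  print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Select bursts by apparent FRET efficiency window
#'
#' Retains the bursts whose `e_app` lies in the closed interval
#' `[e_min, e_max]`; order is preserved.  This is the subpopulation-selection
#' step: the kept bursts define the trace segments retained for
#' subpopulation-selective FCS.
#'
#' @param bursts A `burst_table`.
#' @param e_min,e_max Window bounds, `e_min < e_max`.
#' @return The filtered `burst_table` (possibly empty).
#' @export
select_by_efficiency <- function(bursts, e_min, e_max) {
  if (e_min >= e_max) stop("`e_min` must be < `e_max`")
  keep <- !is.na(bursts$e_app) & bursts$e_app >= e_min & bursts$e_app <= e_max
  bursts[keep, , drop = FALSE]
}

#' Subpopulation fractions from fitted peak areas
#'
#' Divides each labelled peak's area by the total labelled area, e.g. to turn
#' bound/unbound histogram peaks into a bound fraction.  The donor-only
#' (zero-efficiency) peak should not be labelled: it reports on acceptor
#' photophysics, not on the equilibrium.
#'
#' @param peaks The `peaks` data frame of a [fret_histogram()].
#' @param labels Character vector, one entry per peak row; `NA` entries are
#'   excluded from the denominator.
#' @return Named numeric vector of fractions summing to 1.
#' @export
subpopulation_fractions <- function(peaks, labels) {
  stopifnot(length(labels) == nrow(peaks))
  keep <- !is.na(labels)
  if (!any(keep)) stop("need at least one labelled peak")
  areas <- tapply(peaks$area[keep], labels[keep], sum)
  total <- sum(areas)
  if (total <= 0) stop("all labelled peak areas are zero")
  setNames(as.numeric(areas) / total, names(areas))
}
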