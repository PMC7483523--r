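#' Specification of a simulated fluorescent species
#'
#' @param e_true Acceptor branching probability (the noise-free FRET
#'   efficiency), in \[0, 1\].
#' @param count Number of molecules of this species in the box.
#' @param diffusion Diffusion coefficient, m^2/s; alternatively give `tau`.
#' @param tau Diffusion time through the focus, seconds (converted to a
#'   diffusion coefficient via `D = wxy^2 / (4 tau)` using `focus`).
#' @param brightness Mean photons per time bin emitted at the focus centre.
#'   The default 0.1 per 0.96-us bin corresponds to a ~100 kHz peak count
#'   rate, a typical bright single-dye level.
#' @param focus A [focus_geometry()], needed when `tau` is given.
#' @return An object of class `molecule_spec`.
#' @export
molecule_spec <- function(e_true, count = 1L, diffusion = NULL, tau = NULL,
                          brightness = 0.1, focus = focus_geometry()) {
  if (e_true < 0 || e_true > 1) stop("`e_true` must be in [0, 1]")
  if (count < 1) stop("`count` must be >= 1")
  if (brightness <= 0) stop("`brightness` must be positive")
  if (is.null(diffusion) == is.null(tau)) {
    stop("give exactly one of `diffusion` or `tau`")
  }
  if (is.null(diffusion)) {
    if (tau <= 0) stop("`tau` must be positive")
    diffusion <- focus$wxy^2 / (4 * tau)
  }
  if (diffusion <= 0) stop("`diffusion` must be positive")
  structure(list(e_true = e_true, count = as.integer(count),
                 diffusion = diffusion, brightness = brightness),
            class = "molecule_spec")
}

#' Configuration of the Brownian confocal simulation
#'
#' @param box_edge Edge of the periodic cubic simulation box, meters.  Must
#'   comfortably exceed the focus dimensions; default 6 um.
#' @param focus A [focus_geometry()].
#' @param time_step Time bin of the simulation (= fine trace bin width),
#'   seconds; default 0.96 us, the acquisition binning used for
#'   subpopulation-selective FCS.
#' @param duration Simulated time, seconds.
#' @param background A [background_model()] with rates in counts per
#'   `time_step` bin.  The default 0.001/bin per channel is ~1 kHz, a typical
#'   confocal background.
#' @param seed Integer seed; the simulation is bit-reproducible given it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(box_edge = 6e-6, focus = focus_geometry(),
                              time_step = 0.96e-6, duration = 60,
                              background = background_model(0.001, 0.001),
                              seed = 1L) {
  if (box_edge < 4 * focus$wxy) stop("`box_edge` must be several waists wide")
  if (time_step <= 0) stop("`time_step` must be positive")
  if (duration < time_step) stop("`duration` must cover at least one bin")
  structure(list(box_edge = box_edge, focus = focus, time_step = time_step,
                 duration = duration, background = background,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a confocal single-molecule photon trace
#'
#' Brownian dynamics of point emitters in a periodic box: per time bin each
#' molecule takes Gaussian steps of variance `2 D dt` per axis, emits Poisson
#' photons with mean `brightness * exp(-2 (x^2+y^2)/wxy^2 - 2 z^2/wz^2)`,
#' and the photons are split donor/acceptor by a binomial draw at the
#' acceptor probability `e_true`.  Poisson background is added per channel.
#'
#' The ground-truth log records, per molecule, the transit windows through
#' the effective focus (the `1/e^2` ellipsoid) with the photons emitted
#' during each transit — the oracle against which burst detection and
#' diffusion-time recovery are validated.
#'
#' @param molecules A [molecule_spec()] or list of them.
#' @param config A [simulation_config()].
#' @param transit_gap Seconds; consecutive focus entries of the same
#'   molecule closer than this are merged into one transit, so diffusive
#'   re-crossings of the focus boundary do not fragment a single passage.
#' @return A list with `trace` (a [binned_trace()]) and `log`, a data frame
#'   with `molecule`, `species` (index into `molecules`), `e_true`,
#'   `start_bin`, `end_bin` (1-based, end exclusive), `start_s`, `end_s`,
#'   `photons`.
#' @export
simulate_confocal_smd <- function(molecules, config, transit_gap = 100e-6) {
  stopifnot(inherits(config, "simulation_config"))
  if (inherits(molecules, "molecule_spec")) molecules <- list(molecules)
  D <- unlist(lapply(molecules, function(s) rep(s$diffusion, s$count)))
  bright <- unlist(lapply(molecules, function(s) rep(s$brightness, s$count)))
  e_true <- unlist(lapply(molecules, function(s) rep(s$e_true, s$count)))
  species <- unlist(lapply(seq_along(molecules), function(i) {
    rep(i, molecules[[i]]$count)
  }))
  n_bins <- floor(config$duration / config$time_step)
  res <- with_seed(config$seed, {
    cpp_simulate_confocal(D, bright, e_true, config$box_edge,
                          config$focus$wxy, config$focus$wz,
                          config$time_step, n_bins,
                          config$background$donor_rate,
                          config$background$acceptor_rate)
  })
  trace <- binned_trace(res$donor, res$acceptor, config$time_step)
  log <- data.frame(molecule = res$transit_molecule,
                    start_bin = res$transit_start_bin + 1,
                    end_bin = res$transit_end_bin + 1,
                    photons = res$transit_photons)
  log <- merge_transits(log, gap_bins = ceiling(transit_gap /
                                                  config$time_step))
  log$species <- species[log$molecule]
  log$e_true <- e_true[log$molecule]
  log$start_s <- (log$start_bin - 1) * config$time_step
  log$end_s <- (log$end_bin - 1) * config$time_step
  log <- log[order(log$start_bin),
             c("molecule", "species", "e_true", "start_bin", "end_bin",
               "start_s", "end_s", "photons")]
  rownames(log) <- NULL
  list(trace = trace, log = log)
}

# Merge per-molecule transit windows separated by fewer than `gap_bins`
# bins; photon sums accumulate.
merge_transits <- function(log, gap_bins) {
  if (nrow(log) < 2L) return(log)
  pieces <- lapply(split(log, log$molecule), function(d) {
    d <- d[order(d$start_bin), , drop = FALSE]
    grp <- cumsum(c(1, as.integer(d$start_bin[-1L] - d$end_bin[-nrow(d)] >
                                    gap_bins)))
    data.frame(molecule = d$molecule[1L],
               start_bin = tapply(d$start_bin, grp, min),
               end_bin = tapply(d$end_bin, grp, max),
               photons = tapply(d$photons, grp, sum))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Synthetic titration / binding-curve tables
#'
#' Evaluates one of the equilibrium models on a concentration grid and adds
#' independent Gaussian noise, emitting replicate tables for parameter
#' recovery studies.
#'
#' @param kind `"trimer_titration"` (observable: effective stoichiometric
#'   number `n = 1 + 2 f`, concentrations in nM), `"hill"` (observable:
#'   bound fraction, concentrations in pM) or `"second_trimer"` (observable:
#'   doubly-bound fraction, concentrations in uM).
#' @param true_params The generating model: a [trimer_equilibrium()],
#'   [hill_binding()] or [second_trimer_binding()] matching `kind`.
#' @param concentrations Concentration grid (units per `kind`).
#' @param sigma Gaussian noise standard deviation on the observable.
#' @param replicates Number of replicate curves.
#' @param seed Integer seed.
#' @return A data frame with `replicate`, `concentration`, `observable`.
#' @export
synth_equilibrium_data <- function(kind = c("trimer_titration", "hill",
                                            "second_trimer"),
                                   true_params, concentrations, sigma = 0,
                                   replicates = 1L, seed = 1L) {
  kind <- match.arg(kind)
  curve <- switch(kind,
    trimer_titration = {
      stopifnot(inherits(true_params, "trimer_equilibrium"))
      1 + 2 * trimer_species(true_params, concentrations)$fraction
    },
    hill = {
      stopifnot(inherits(true_params, "hill_binding"))
      hill_fraction(true_params, concentrations)
    },
    second_trimer = {
      stopifnot(inherits(true_params, "second_trimer_binding"))
      second_trimer_fraction(true_params, concentrations)
    })
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      data.frame(replicate = r, concentration = concentrations,
                 observable = curve + rnorm(length(curve), sd = sigma))
    }))
  })
}
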