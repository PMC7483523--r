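# Simulated fixtures are expensive; build each once per test run and share.
.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Single Cy3B-like species (tau = 150 us) at acquisition binning; the
# workhorse for correlation, burst-detection and pipeline checks.
single_species_sim <- function() {
  cached_fixture("single_species", {
    cfg <- simulation_config(duration = 20, time_step = 0.96e-6, seed = 101)
    simulate_confocal_smd(
      molecule_spec(e_true = 0.33, count = 6, tau = 150e-6), cfg)
  })
}

# Full-pipeline validation run: one bright species with a known diffusion
# time, threshold sweep at the default grid, quadratic extrapolation.
validation_sweep <- function() {
  cached_fixture("validation_sweep", {
    cfg <- simulation_config(duration = 60, time_step = 0.96e-6, seed = 301)
    sim <- simulate_confocal_smd(
      molecule_spec(e_true = 0.33, count = 10, tau = 150e-6), cfg)
    sweep <- pscfcs_sweep(sim$trace, e_min = 0.2, e_max = 0.5, seed = 302)
    list(sweep = sweep, extrapolation = unbiased_tau(sweep),
         tau_true = 150e-6)
  })
}

# The six-molecule two-efficiency scenario (4 molecules at E = 0.11, 2 at
# E = 0.33) at a 10-us step, rebinned to 1 ms for burst analysis.
two_species_sim <- function() {
  cached_fixture("two_species", {
    cfg <- simulation_config(duration = 120, time_step = 10e-6, seed = 202,
                             background = background_model(0.01, 0.01))
    # brightness 5 per 10-us bin (~500 kHz peak): bright enough that bursts
    # carry ~100 photons, so the two efficiency peaks are shot-noise
    # resolved as in the reference histograms
    sim <- simulate_confocal_smd(
      list(molecule_spec(e_true = 0.11, count = 4, tau = 150e-6,
                         brightness = 5),
           molecule_spec(e_true = 0.33, count = 2, tau = 150e-6,
                         brightness = 5)), cfg)
    sim$coarse <- rebin(sim$trace, 100)
    sim
  })
}
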