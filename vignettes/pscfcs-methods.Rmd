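---
title: "Methods: subpopulation-selective FCS and coupled chaperone equilibria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subpopulation-selective FCS and coupled chaperone equilibria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pscfcs)
```

## The problem

A solution of an unfolded outer-membrane-protein client and its periplasmic
holdase chaperone contains several species at once: free collapsed client,
client bound by one chaperone trimer, client bound by two, free monomer and
free trimer of the chaperone itself.  Conventional fluorescence correlation
spectroscopy (FCS) measures a number-weighted average diffusion time over
all fluorescent species and therefore cannot assign a molecular weight to
any one of them.  Burst-wise single-molecule FRET (smFRET), on the other
hand, distinguishes the species by conformation — each subpopulation is a
peak in the apparent-efficiency histogram — but carries no direct size
information.

This package combines the two: bursts are classified by apparent FRET
efficiency, the trace segments belonging to one efficiency window are kept,
every other segment is replaced by synthetic Poisson background, and the
autocorrelation of the resulting trace reports the diffusion time of that
subpopulation alone.  We refer to the procedure as subpopulation-selective
(portion-selectively-chosen) FCS.

## Pipeline and models

1. **Burst analysis.** The two-channel photon trace, acquired at
   sub-microsecond binning, is rebinned to 1 ms.  A burst is a maximal run
   of bins with summed donor + acceptor counts at or above a peak
   threshold $x$.  The apparent efficiency of a burst is
   $E_\mathrm{app} = I_\mathrm{Ac}/(I_\mathrm{Dr}+I_\mathrm{Ac})$; for
   histogramming and selection the per-channel background (rate × burst
   length) is subtracted first, so donor-only species appear near zero and
   can legitimately scatter below it.

2. **Masking.** Bursts inside the chosen efficiency window are mapped back
   to the acquisition binning by time interval and retained verbatim;
   every other fine bin is redrawn from a Poisson law at the measured
   per-channel background rate.  Donor and acceptor are then summed —
   summation cancels the donor/acceptor anti-correlation produced by FRET
   dynamics — and the sum is autocorrelated with a multi-tau estimator
   (16 lags per stage, ×2 rebinning).

3. **FCS fit.** The correlation is fitted by the two-dimensional free
   diffusion model
   $G(t) = 1 + G_0\,(1+t/\tau_\mathrm{app})^{-1}$
   over lags from 10 µs to 1 s, unweighted.  A variant with one
   exponential relaxation factor $(1 + A e^{-t/t_R})$ is available for
   traces with fast photophysics.

4. **Threshold extrapolation.** The peak threshold biases
   $\tau_\mathrm{app}$ upward: a higher threshold keeps only transits that
   pass close to the focus axis, and those dwell longer.  Empirically the
   bias is quadratic, $\tau_\mathrm{app} = \tau + a x^2$, so the sweep of
   thresholds is fitted by that relation and the intercept $\tau$ is the
   unbiased diffusion time.

5. **Size and stoichiometry.** With the Stokes–Einstein relation
   $D = k_B T / 6\pi\eta R$, the focal relation $\tau = \omega_{xy}^2/4D$,
   and the equal-density spherical approximation, masses scale as the cube
   of diffusion times, $M_1/M_2 = (\tau_1/\tau_2)^3$, with first-order
   error propagation
   $\sigma^2(M_1)/M_1^2 = 9(\sigma^2(\tau_1)/\tau_1^2 +
   \sigma^2(\tau_2)/\tau_2^2)$.  The chaperone:client stoichiometric ratio
   follows as $r = ((\tau_\mathrm{bound}/\tau_\mathrm{apo})^3 - 1)\,
   M_\mathrm{client}/M_\mathrm{chaperone}$.

6. **Coupled equilibria.** Three mass-action models are provided and
   fitted by unweighted nonlinear least squares:

   * self-trimerization $3S \rightleftharpoons S_3$ with
     $K = [S]^3/[S_3]$ (nM²), conservation $[S] + 3[S_3] = c_\mathrm{tot}$,
     half-trimerization at $C_{1/2} = \sqrt{4K/3}$, and titration
     observable $n(c_\mathrm{tot}) = 1 + 2f$ (a labelled tracer diffuses as
     mass 1 free and mass 3 in a trimer);
   * cooperative client binding, Hill form
     $p = c^{n}/(K_D^{n} + c^{n})$;
   * second-trimer binding, a Langmuir isotherm in the free-trimer
     concentration, $f = [S_3]/(K_D' + [S_3])$, with $[S_3]$ supplied by
     the trimerization model at each total concentration.

   The titration and isotherm forms are reconstructions from mass action
   and the stated reactions; only their parameter values are taken from
   measurements.  Free energies use $\Delta G = RT\ln K_D$ at the 1 M
   standard state, and diffusion-limited association rates use the
   Smoluchowski form $k^+ = 4\pi(D_A + D_B)(R_A + R_B)$.

## The simulator

`simulate_confocal_smd()` is the ground-truth engine behind every pipeline
test: point emitters random-walk through a periodic cubic box (Gaussian
steps of variance $2D\Delta t$ per axis), emit Poisson photons with mean
`brightness` × the Gaussian detection profile
$\exp(-2(x^2{+}y^2)/\omega_{xy}^2 - 2z^2/\omega_z^2)$, and the photons are
split donor/acceptor by a binomial draw at the branching probability
`e_true`.  Poisson background is added per channel.  The log records every
focus transit (the $1/e^2$ ellipsoid) with its photon sum, so burst
detection and subpopulation selection can be scored against the molecule
that actually caused each burst.

Defaults, chosen once as a realistic single-molecule condition and used by
all validation runs:

| parameter | default | why |
|---|---|---|
| $\omega_{xy}$ | 0.25 µm | typical confocal waist; with the default $D$ it gives $\tau = 150$ µs, a free-dye scale |
| $\omega_z/\omega_{xy}$ | 10 | the fit model is two-dimensional; a closed-form check shows aspect ratio 5 biases the fitted $\tau$ by −7.2%, ratio 10 by −2.1%, so the default geometry is made consistent with the 2D model |
| box edge | 6 µm | > 2$\omega_z$, so a molecule genuinely leaves the focus before wrapping |
| time step | 0.96 µs | the acquisition binning correlated by the pipeline |
| brightness | 0.1 photons/bin | ≈100 kHz peak rate, a bright single dye |
| background | 0.001/bin/channel | ≈1 kHz per channel |

The six-molecule two-efficiency scenario (four molecules at branching
probability 0.11, two at 0.33) uses a higher peak rate of ≈500 kHz and a
burst threshold of 100 counts/ms: resolving efficiency peaks 0.22 apart in
a burst histogram requires the binomial shot-noise width
$\sqrt{E(1-E)/N}$ to be well below the separation, i.e. on the order of
100 photons per burst — the burst statistics visible in reference smFRET
histograms of this kind.  At the 100 kHz FCS brightness a 150 µs transit
delivers only ~15–30 photons and the two peaks blur into each other.

What the simulator deliberately omits: photobleaching and blinking (an
optional relaxation term exists only in the fit model, not the emitter),
spectral crosstalk and direct acceptor excitation (available as zero-default
leakage parameters would be in a microscope, but off), detector afterpulsing
and dead time, and any conformational dynamics — `e_true` is fixed per
molecule.  Passing tests therefore demonstrate correctness of the
estimators under ideal photophysics, not robustness to every artefact of
real recordings.

## Numerical choices

* **Threshold grid.** The default sweep is 8, 11, 14, 17, 20 counts per
  1 ms bin.  The lower end is set by the background: with ~2 counts/ms of
  summed background, thresholds inside the Poisson tail
  ($P(\mathrm{bg} \ge x)$ not ≪ 1) let background excursions chain into
  spurious "bursts", and the kept windows stop corresponding to molecular
  transits.  At $x = 8$ the per-bin false rate is ~10⁻³.
* **Guard margin.** Selected bursts are padded by one burst-analysis bin on
  each side before masking (`guard_bins = 1`).  Without the margin the kept
  gate shrinks to a single 1 ms bin at high thresholds, and the rectangular
  gate truncates the correlation tail progressively more as the threshold
  rises — a bias in the opposite direction of the selection bias the
  quadratic extrapolation is designed to remove.  With the margin the gate
  length is approximately threshold-independent.
* **Efficiency histogram.** Bin width 0.02 over [−0.2, 1.2]; wide enough to
  include the background-corrected donor-only peak, fine enough to resolve
  peaks 0.2 apart.  The number of Gaussian components is user-specified per
  experiment; starting values come from k-means on the burst efficiencies,
  and widths/amplitudes are fitted on a log scale to keep them positive.
* **Root finding.** The trimerization cubic is solved by bracketed
  bisection on [0, total] polished with Newton steps to 10⁻¹² relative;
  conservation holds to 10⁻¹⁰ relative across 10⁻² – 10⁵ nM.
* **Fit parameterizations.** All dissociation constants are fitted on a log
  scale (positivity without constraints); standard errors are mapped back
  by the delta method.  Flat titrations and all-zero binding curves are
  reported as unbounded-estimate errors rather than silently returning the
  bound.
* **Seeds.** Every stochastic step (simulation, Poisson replacement,
  synthetic noise) takes an explicit integer seed and restores the caller's
  RNG state, so whole workflows are bit-reproducible.

## Validation scale

The validation runs bundled with the package use 60 s of simulated trace at
0.96 µs binning with 10 molecules for the threshold-extrapolation check
(three replicates in the acceptance script, one in the test suite), and
60 s at 10 µs binning for the six-molecule two-efficiency scenario.  At
this scale the per-replicate statistical error of a fitted diffusion time
is a few percent — comparable to, and partly larger than, the ~2% residual
model bias of the 2D fit — which is why the extrapolation check is stated
as a bound on the relative error rather than an equality.

## Known limitations

* The quadratic threshold law is empirical; it is used as a fitting device
  for extrapolation, and no mechanistic claim is made.
* The 2D diffusion model ignores the axial dimension entirely; with the
  default geometry this contributes about −2% to fitted diffusion times.
* Mass inference assumes spherical, equal-density species; shape and
  hydration corrections are out of scope, so ratios of similar species are
  more trustworthy than absolute masses.
* The effective-stoichiometry titration treats the labelled tracer as
  chemically identical to the unlabelled monomer.
* Whether bursts should be re-detected per threshold or reused from one
  detection pass is a genuine design choice; this package re-detects per
  threshold, which keeps each sweep point a self-contained analysis.
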