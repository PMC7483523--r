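# pscfcs

Subpopulation-selective fluorescence correlation spectroscopy (pscFCS) in R:
measure the diffusion time — and from it the molecular weight and binding
stoichiometry — of one molecular subpopulation picked out of a mixed
single-molecule FRET recording, and fit the coupled mass-action equilibria
of a chaperone–client system (self-trimerization, cooperative client
binding, second-trimer binding).

## Who this is for

Single-molecule biophysicists analysing two-channel (donor/acceptor)
confocal photon traces of freely diffusing, FRET-labelled molecules.
Conventional FCS averages over every fluorescent species in solution;
burst-wise smFRET separates the species but carries no size information.
pscFCS combines them:

1. detect fluorescence bursts at a peak threshold `x` on 1 ms bins and
   classify them by apparent FRET efficiency
   `E = I_acceptor / (I_donor + I_acceptor)`;
2. keep the acquisition-binned (0.96 µs) trace segments of one efficiency
   window, replace everything else by synthetic Poisson background;
3. autocorrelate the masked donor+acceptor sum (multi-tau estimator) and
   fit the 2D diffusion model `G(t) = 1 + G0 / (1 + t/τ_app)` over
   10 µs – 1 s;
4. sweep the threshold and extrapolate the empirical bias law
   `τ_app = τ + a·x²` to `x = 0`, giving the unbiased diffusion time of
   that subpopulation alone;
5. convert diffusion times to masses by the Stokes–Einstein cubic law
   `M1/M2 = (τ1/τ2)³` and to chaperone:client stoichiometries
   `r = ((τ_bound/τ_apo)³ − 1)·M_client/M_chaperone`.

A Brownian-dynamics confocal simulator (`simulate_confocal_smd()`) with a
ground-truth transit log generates all validation data, and an
`equilibria` module fits the monomer–trimer equilibrium
(`3S ⇌ S₃`, `K = [S]³/[S₃]`), the Hill isotherm
`p = c^n/(K_D^n + c^n)`, and second-trimer binding
`f = [S₃]/(K_D' + [S₃])`.

## Worked example

```r
library(pscfcs)

## chaperone self-trimerization: half concentration from the fitted K
skp <- trimer_equilibrium(K = 4.6e4)   # nM^2
trimer_c_half(skp)
#> [1] 247.6557                        # nM: trimerization midpoint ~2.5e2 nM

## coupling the apparent client-binding constant (550 pM) through the
## trimer equilibrium gives the effective trimer K_D and free energy
kd_eff <- (550e-12)^3 / (4.6e4 * 1e-18)   # M
kd_eff
#> [1] 3.616848e-15                    # a few femtomolar
binding_free_energy(kd_eff)
#> [1] -19.56984                       # kcal/mol at 296.15 K

## stoichiometry from bound/apo diffusion times and the labelled masses
stoichiometric_ratio(549e-6, 422e-6, m_client = 40.2e3, m_chaperone = 18.8e3)$r
#> [1] 2.569826                        # ~3 monomers per client

## full pscFCS pipeline on a simulated recording with known truth
cfg <- simulation_config(duration = 20, seed = 7)       # 0.96 us bins
sim <- simulate_confocal_smd(
  molecule_spec(e_true = 0.33, count = 10, tau = 150e-6), cfg)
report <- run_pscfcs_workflow(sim$trace, e_min = 0.2, e_max = 0.5, seed = 1,
                              reference = list(tau = 151e-6, mass = 560))
report
#> <pscfcs_report> selection [0.20, 0.50], 5 thresholds
#>   unbiased tau = 0.0001488 +/- 2.2e-06 s
#>   mass = 536.2 +/- 23 Da
report$sweep
#>   threshold      tau_app       g0 n_bursts
#> 1         8 0.0001567588 3.904716      750
#> 2        11 0.0001564834 3.562273      618
#> 3        14 0.0001633226 3.213837      488
#> 4        17 0.0001738544 2.784139      378
#> 5        20 0.0001822532 2.468012      307
```

The apparent diffusion time rises with the peak threshold (brighter bursts
come from longer, more central focus passages); the quadratic extrapolation
returns 148.8 µs against the simulated 150 µs, and the cubic mass law
converts it to a molecular weight relative to the supplied reference
species.

A thin command-line front end over the same functions is installed at
`inst/cli/pscfcs.R` (subcommands `simulate`, `bursts`, `hist`, `pscfcs`,
`fit-trimer`, `fit-hill`, `fit-second`, `hydro`).

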