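K_REFERENCE <- 4.6e4 # nM^2, reference scale of the chaperone trimerization constant

test_that("trimer equilibrium solves mass action with conservation", {
  m <- trimer_equilibrium(K_REFERENCE)
  sp <- trimer_species(m, 0)
  expect_equal(unlist(sp[c("monomer", "trimer", "fraction")]),
               c(monomer = 0, trimer = 0, fraction = 0))
  # half-trimerization at the closed-form total sqrt(4K/3)
  c_half <- trimer_c_half(m)
  expect_equal(trimer_species(m, c_half)$fraction, 0.5, tolerance = 1e-9)
  # no-trimer limit
  weak <- trimer_equilibrium(1e12)
  expect_lt(trimer_species(weak, 100)$fraction, 1e-5)
  # conservation across a wide grid
  totals <- 10^seq(-1, 5, length.out = 40)
  sp <- trimer_species(m, totals)
  expect_true(all(abs(sp$monomer + 3 * sp$trimer - totals) / totals < 1e-10))
  # fraction strictly increasing in total and in 1/K
  expect_true(all(diff(sp$fraction) > 0))
  expect_true(all(trimer_species(trimer_equilibrium(K_REFERENCE / 10),
                                 totals)$fraction > sp$fraction))
  expect_error(trimer_species(m, -1), "non-negative")
})

test_that("half concentration follows sqrt(4K/3)", {
  expect_equal(trimer_c_half(trimer_equilibrium(3 / 4)), 1)
  expect_equal(trimer_c_half(trimer_equilibrium(4.6e4)), 247.66, tolerance = 1e-4)
  # scales as sqrt(K)
  expect_equal(trimer_c_half(trimer_equilibrium(4e2)) /
                 trimer_c_half(trimer_equilibrium(1e2)), 2, tolerance = 1e-12)
})

test_that("trimer titration fit recovers K and flags flat data", {
  totals <- 10^seq(0, 4, length.out = 12)
  truth <- trimer_equilibrium(K_REFERENCE)
  n_clean <- 1 + 2 * trimer_species(truth, totals)$fraction
  fit <- fit_trimer_titration(totals, n_clean)
  expect_equal(fit$K, K_REFERENCE, tolerance = 1e-6)
  expect_error(fit_trimer_titration(totals, rep(1, 12)), "flat|unbounded")
})

test_that("Hill fraction has its defining properties and fits round-trip", {
  hb <- hill_binding(550, 1.6)
  expect_equal(hill_fraction(hb, 550), 0.5)
  expect_equal(hill_fraction(hb, 0), 0)
  expect_equal(hill_fraction(hill_binding(200, 1), 600), 0.75)
  # monotone and bounded
  p <- hill_fraction(hb, 10^seq(0, 5, length.out = 50))
  expect_true(all(p >= 0 & p <= 1) && all(diff(p) > 0))

  conc <- 10^seq(log10(100), log10(8000), length.out = 10)
  p_clean <- hill_fraction(hb, conc)
  fit <- fit_hill(conc, p_clean)
  expect_equal(fit$k_d, 550, tolerance = 1e-6)
  expect_equal(fit$n_hill, 1.6, tolerance = 1e-6)
  # fixing n = 1 on Langmuir data reduces to a Langmuir fit
  p1 <- hill_fraction(hill_binding(550, 1), conc)
  fit1 <- fit_hill(conc, p1, fix_n = 1)
  expect_equal(fit1$k_d, 550, tolerance = 1e-6)
})

test_that("second-trimer fraction couples to the trimer equilibrium", {
  tri <- trimer_equilibrium(K_REFERENCE)
  m <- second_trimer_binding(1.2, tri)
  expect_equal(second_trimer_fraction(m, 0), 0)
  # f = 1/2 when the free trimer concentration equals K':
  # [S3] = 1.2 uM needs total = (K*[S3])^(1/3) + 3[S3] (in nM)
  s3_nM <- 1200
  total_nM <- (K_REFERENCE * s3_nM)^(1 / 3) + 3 * s3_nM
  expect_equal(second_trimer_fraction(m, total_nM / 1e3), 0.5,
               tolerance = 1e-9)
  # monotone and bounded
  f <- second_trimer_fraction(m, 10^seq(-2, 2, length.out = 40))
  expect_true(all(f >= 0 & f <= 1) && all(diff(f) > 0))

  totals <- 10^seq(log10(0.2), log10(10), length.out = 8)
  f_clean <- second_trimer_fraction(m, totals)
  fit <- fit_second_trimer(totals, f_clean, tri)
  expect_equal(fit$k_d_prime, 1.2, tolerance = 1e-6)
  expect_error(fit_second_trimer(totals, rep(0, 8), tri), "unbounded")
})

test_that("binding free energy follows RT ln K with 1 M standard state", {
  expect_equal(binding_free_energy(1), 0)
  # composing an apparent picomolar K_D with the trimerization constant
  # lands in the femtomolar range and about -20 kcal/mol
  kd_eff <- (550e-12)^3 / (K_REFERENCE * (1e-9)^2)
  expect_gt(kd_eff, 1e-15)
  expect_lt(kd_eff, 1e-14)
  dg <- binding_free_energy(kd_eff)
  expect_equal(dg, -19.57, tolerance = 1e-3)
  # tenfold affinity change shifts dG by RT ln 10
  expect_equal(binding_free_energy(1e-9) - binding_free_energy(1e-10),
               1.98720425864083e-3 * 296.15 * log(10), tolerance = 1e-12)
  expect_error(binding_free_energy(0), "positive")
})

test_that("apparent monomer/trimer association rates cross over", {
  tri <- trimer_equilibrium(K_REFERENCE)
  # equal rate constants at the half concentration: [S]:[S3] = 3
  at_half <- apparent_rates(tri, 6.7e9, 6.7e9, trimer_c_half(tri))
  expect_equal(at_half$ratio, 3, tolerance = 1e-9)
  # ratio strictly decreasing with total (trimer pathway takes over)
  rates <- apparent_rates(tri, 6.7e9, 6.6e9, 10^seq(0, 4, length.out = 30))
  expect_true(all(diff(rates$ratio) < 0))
  expect_true(all(rates$monomer_rate >= 0 & rates$trimer_rate >= 0))
  expect_error(apparent_rates(tri, -1, 1, 10), "positive")
})

test_that("synthetic titration tables are exact at zero noise and seeded", {
  tri <- trimer_equilibrium(K_REFERENCE)
  conc <- 10^seq(0, 4, length.out = 12)
  tab <- synth_equilibrium_data("trimer_titration", tri, conc, sigma = 0)
  expect_equal(tab$observable, 1 + 2 * trimer_species(tri, conc)$fraction)

  hb <- hill_binding(550, 1.6)
  tab_h <- synth_equilibrium_data("hill", hb, c(100, 550, 2000), sigma = 0)
  expect_equal(tab_h$observable[2], 0.5)

  a <- synth_equilibrium_data("hill", hb, c(100, 550), sigma = 0.05,
                              replicates = 2, seed = 9)
  b <- synth_equilibrium_data("hill", hb, c(100, 550), sigma = 0.05,
                              replicates = 2, seed = 9)
  expect_identical(a, b)
})

test_that("noisy trimer titrations refit without bias across seeds", {
  tri <- trimer_equilibrium(K_REFERENCE)
  conc <- 10^seq(0, 4, length.out = 12)
  ks <- vapply(1:20, function(s) {
    tab <- synth_equilibrium_data("trimer_titration", tri, conc,
                                  sigma = 0.05, seed = s)
    fit_trimer_titration(tab$concentration, tab$observable)$K
  }, numeric(1))
  # mean recovery within 2 standard errors of the truth
  expect_lt(abs(mean(ks) - K_REFERENCE), 2 * sd(ks) / sqrt(length(ks)))
})
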