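#' Monomer-trimer self-association equilibrium
#'
#' The mass-action model `3 S <-> S3` with dissociation constant
#' `K = [S]^3 / [S3]` (nM^2) and conservation `total = [S] + 3 [S3]`.
#'
#' @param K Dissociation constant in nM^2 (> 0).
#' @return An object of class `trimer_equilibrium`.
#' @export
trimer_equilibrium <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K <= 0) stop("`K` must be > 0")
  structure(list(K = as.numeric(K)), class = "trimer_equilibrium")
}

#' Species concentrations of the monomer-trimer equilibrium
#'
#' Solves `[S] + 3 [S]^3 / K = total` for the unique non-negative monomer
#' concentration (bisection on the monotone cubic, polished by Newton steps
#' to 1e-12 relative), then reports the trimer concentration and the fraction
#' of monomers residing in trimers.
#'
#' @param model A [trimer_equilibrium()].
#' @param total Total monomer concentration(s), nM (>= 0); vectorized.
#' @return A data frame with columns `total`, `monomer`, `trimer` (all nM)
#'   and `fraction` (of monomers in trimers; 0 at `total = 0` by convention).
#' @export
trimer_species <- function(model, total) {
  stopifnot(inherits(model, "trimer_equilibrium"))
  if (any(total < 0)) stop("`total` must be non-negative")
  K <- model$K
  s <- vapply(total, function(ct) {
    if (ct == 0) return(0)
    f <- function(x) x + 3 * x^3 / K - ct
    root <- uniroot(f, c(0, ct), tol = .Machine$double.eps * max(ct, 1))$root
    # Newton polish
    for (i in 1:5) {
      root <- root - (root + 3 * root^3 / K - ct) / (1 + 9 * root^2 / K)
    }
    root
  }, numeric(1))
  trimer <- s^3 / K
  frac <- ifelse(total == 0, 0, 3 * trimer / total)
  data.frame(total = total, monomer = s, trimer = trimer, fraction = frac)
}

#' Half-trimerization concentration
#'
#' The total monomer concentration at which half of the monomers are in
#' trimers; analytically `sqrt(4 K / 3)` for the `3 S <-> S3` model.
#'
#' @param model A [trimer_equilibrium()].
#' @return The half concentration, nM.
#' @examples
#' trimer_c_half(trimer_equilibrium(K = 4.6e4)) # about 248 nM
#' @export
trimer_c_half <- function(model) {
  stopifnot(inherits(model, "trimer_equilibrium"))
  sqrt(4 * model$K / 3)
}

#' Fit the self-trimerization constant to an effective-stoichiometry titration
#'
#' The titration observable is the effective stoichiometric number of a
#' trace-labelled monomer, `n(total) = 1 + 2 f(total)`, where `f` is the
#' trimer fraction from [trimer_species()]: a labelled monomer diffuses as
#' mass 1 when free and as mass 3 when in a trimer.  `K` is estimated by
#' unweighted least squares on a log10 parameterization.
#'
#' @param total Total monomer concentrations, nM.
#' @param n_obs Observed effective stoichiometric numbers.
#' @return A list of class `trimer_fit`: `model` (a [trimer_equilibrium()]),
#'   `K`, `K_se`, `fitted`, `residuals`.
#' @export
fit_trimer_titration <- function(total, n_obs) {
  stopifnot(length(total) == length(n_obs))
  if (length(total) < 4L) stop("need >= 4 titration points")
  if (max(n_obs) - min(n_obs) < 0.05) {
    stop("titration is flat: trimerization constant is unbounded by the data")
  }
  predict_n <- function(log10K) {
    1 + 2 * trimer_species(trimer_equilibrium(10^log10K), total)$fraction
  }
  # initial guess: C_1/2 where n crosses midway between observed extremes
  mid <- (max(n_obs) + min(n_obs)) / 2
  c_half0 <- total[which.min(abs(n_obs - mid))]
  start <- log10(3 * max(c_half0, min(total[total > 0]))^2 / 4)
  fit <- minpack.lm::nls.lm(par = c(log10K = start),
                            fn = function(p) n_obs - predict_n(p[1]),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 5)) stop("trimer titration fit did not converge")
  log10K <- fit$par[[1]]
  if (log10K > 12) {
    stop("titration is flat: trimerization constant is unbounded by the data")
  }
  se_log <- tryCatch(sqrt(diag(vcov(fit)))[[1]], error = function(e) NA_real_)
  K <- 10^log10K
  structure(list(model = trimer_equilibrium(K), K = K,
                 K_se = K * log(10) * se_log,
                 fitted = predict_n(log10K),
                 residuals = n_obs - predict_n(log10K)),
            class = "trimer_fit")
}

#' Hill binding isotherm
#'
#' Cooperative client binding with apparent dissociation constant `k_d` (the
#' chaperone concentration at half saturation) and Hill coefficient `n_hill`.
#'
#' @param k_d Apparent dissociation constant, pM (> 0).
#' @param n_hill Hill coefficient (> 0).
#' @return An object of class `hill_binding`.
#' @export
hill_binding <- function(k_d, n_hill) {
  if (k_d <= 0 || n_hill <= 0) stop("`k_d` and `n_hill` must be > 0")
  structure(list(k_d = k_d, n_hill = n_hill), class = "hill_binding")
}

#' Bound fraction under the Hill isotherm
#'
#' `p = c^n / (K^n + c^n)`; `p = 1/2` at `c = K` by construction.
#'
#' @param model A [hill_binding()].
#' @param total Total chaperone concentration(s), same unit as `k_d`.
#' @return Bound fraction(s) in \[0, 1\].
#' @export
hill_fraction <- function(model, total) {
  stopifnot(inherits(model, "hill_binding"))
  if (any(total < 0)) stop("`total` must be non-negative")
  cn <- total^model$n_hill
  cn / (model$k_d^model$n_hill + cn)
}

#' Fit the Hill isotherm to a normalized binding curve
#'
#' Unweighted least squares for `(K_D, n)`; optionally with `n` fixed
#' (Langmuir when `fix_n = 1`).
#'
#' @param total Total chaperone concentrations (same unit as the desired
#'   `k_d`, e.g. pM).
#' @param p_obs Normalized bound fractions.
#' @param fix_n Optional fixed Hill coefficient.
#' @return A list of class `hill_fit`: `model`, `k_d`, `k_d_se`, `n_hill`,
#'   `n_se`, `fitted`, `residuals`.
#' @export
fit_hill <- function(total, p_obs, fix_n = NULL) {
  stopifnot(length(total) == length(p_obs))
  if (length(total) < 4L) stop("need >= 4 points")
  k0 <- total[which.min(abs(p_obs - 0.5))]
  if (k0 <= 0) k0 <- stats::median(total[total > 0])
  resid_fun <- function(p) {
    kd <- exp(p[1])
    n <- if (is.null(fix_n)) exp(p[2]) else fix_n
    p_obs - hill_fraction(hill_binding(kd, n), total)
  }
  par0 <- if (is.null(fix_n)) c(log(k0), log(1.5)) else c(log(k0))
  fit <- minpack.lm::nls.lm(par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 5)) stop("Hill fit did not converge")
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    rep(NA_real_, length(par0))
  })
  kd <- exp(fit$par[1])
  n <- if (is.null(fix_n)) exp(fit$par[2]) else fix_n
  model <- hill_binding(kd, n)
  structure(list(model = model, k_d = kd, k_d_se = kd * se[1], n_hill = n,
                 n_se = if (is.null(fix_n)) n * se[2] else 0,
                 fitted = hill_fraction(model, total),
                 residuals = resid_fun(fit$par)),
            class = "hill_fit")
}

#' Second-trimer binding model
#'
#' Binding of a second trimer to the client-trimer complex, with the free
#' trimer concentration supplied by the embedded self-trimerization
#' equilibrium.
#'
#' @param k_d_prime Dissociation constant of the second trimer, uM (> 0).
#' @param trimer A [trimer_equilibrium()] (K in nM^2).
#' @return An object of class `second_trimer_binding`.
#' @export
second_trimer_binding <- function(k_d_prime, trimer) {
  if (k_d_prime <= 0) stop("`k_d_prime` must be > 0")
  stopifnot(inherits(trimer, "trimer_equilibrium"))
  structure(list(k_d_prime = k_d_prime, trimer = trimer),
            class = "second_trimer_binding")
}

#' Fraction of doubly-bound client under the second-trimer model
#'
#' Computes the free trimer concentration `[S3]` at the given total monomer
#' concentration from the embedded trimer equilibrium, then the Langmuir
#' fraction `f = [S3] / (K' + [S3])` of client carrying a second trimer.
#'
#' @param model A [second_trimer_binding()].
#' @param total Total monomer concentration(s), uM.
#' @return Fraction(s) in \[0, 1\], monotone in `total`.
#' @export
second_trimer_fraction <- function(model, total) {
  stopifnot(inherits(model, "second_trimer_binding"))
  if (any(total < 0)) stop("`total` must be non-negative")
  s3_nM <- trimer_species(model$trimer, total * 1e3)$trimer
  s3 <- s3_nM / 1e3 # uM
  s3 / (model$k_d_prime + s3)
}

#' Fit the second-trimer dissociation constant
#'
#' Least-squares estimate of `K'` from a normalized doubly-bound-fraction
#' curve, with the self-trimerization constant supplied (not co-fitted).
#'
#' @param total Total monomer concentrations, uM.
#' @param f_obs Normalized fractions of the doubly-bound species.
#' @param trimer A [trimer_equilibrium()] fixing the free-trimer supply.
#' @return A list of class `second_trimer_fit`: `model`, `k_d_prime`,
#'   `k_d_prime_se`, `fitted`, `residuals`.
#' @export
fit_second_trimer <- function(total, f_obs, trimer) {
  stopifnot(length(total) == length(f_obs),
            inherits(trimer, "trimer_equilibrium"))
  if (length(total) < 4L) stop("need >= 4 points")
  if (max(f_obs) < 0.05) {
    stop("no doubly-bound signal: K' is unbounded by the data")
  }
  s3 <- trimer_species(trimer, total * 1e3)$trimer / 1e3
  resid_fun <- function(p) f_obs - s3 / (exp(p[1]) + s3)
  k0 <- s3[which.min(abs(f_obs - 0.5))]
  if (k0 <= 0) k0 <- stats::median(s3[s3 > 0])
  fit <- minpack.lm::nls.lm(c(log(k0)), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 5)) stop("second-trimer fit did not converge")
  se <- tryCatch(sqrt(diag(vcov(fit)))[[1]], error = function(e) NA_real_)
  kdp <- exp(fit$par[1])
  structure(list(model = second_trimer_binding(kdp, trimer),
                 k_d_prime = kdp, k_d_prime_se = kdp * se,
                 fitted = s3 / (kdp + s3), residuals = resid_fun(fit$par)),
            class = "second_trimer_fit")
}

#' Standard binding free energy from a dissociation constant
#'
#' `dG = R T ln(K_D / 1 M)` in kcal/mol (1 M standard state); negative for
#' sub-molar dissociation constants.
#'
#' @param k_d Dissociation constant in molar (> 0).
#' @param conditions A [solvent_conditions()] (temperature is used).
#' @return Free energy, kcal/mol.
#' @examples
#' # coupled constants: an apparent 550 pM client binding with cooperative
#' # trimer recruitment at K = 4.6e4 nM^2 implies a femtomolar trimer K_D
#' kd <- (550e-12)^3 / (4.6e4 * (1e-9)^2)
#' binding_free_energy(kd) # about -20 kcal/mol
#' @export
binding_free_energy <- function(k_d, conditions = solvent_conditions()) {
  if (any(k_d <= 0)) stop("`k_d` must be positive")
  r_kcal <- 1.98720425864083e-3 # kcal / (mol K)
  r_kcal * conditions$temperature * log(k_d)
}

#' Apparent pseudo-first-order association rates of the two pathways
#'
#' Given the self-trimerization equilibrium and the bimolecular rate
#' constants of monomer and trimer association, returns the apparent rates
#' `k+_mono [S]` and `k+_tri [S3]` at each total concentration, plus their
#' ratio.  The monomer pathway dominates at low totals (the trimer vanishes
#' as `[S]^3`) and the trimer pathway takes over with increasing
#' concentration.
#'
#' @param trimer A [trimer_equilibrium()].
#' @param k_plus_monomer,k_plus_trimer Association rate constants,
#'   M^-1 s^-1 (> 0).
#' @param total Total monomer concentration(s), nM.
#' @return A data frame with `total`, `monomer_rate`, `trimer_rate` (s^-1)
#'   and `ratio` (monomer/trimer).
#' @export
apparent_rates <- function(trimer, k_plus_monomer, k_plus_trimer, total) {
  if (k_plus_monomer <= 0 || k_plus_trimer <= 0) {
    stop("rate constants must be positive")
  }
  sp <- trimer_species(trimer, total)
  mono <- k_plus_monomer * sp$monomer * 1e-9
  tri <- k_plus_trimer * sp$trimer * 1e-9
  data.frame(total = total, monomer_rate = mono, trimer_rate = tri,
             ratio = mono / tri)
}
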