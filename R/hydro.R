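#' Solvent conditions for hydrodynamic conversions
#'
#' @param temperature Absolute temperature, kelvin.  Default 296.15 K (23 C,
#'   the usual room-temperature single-molecule condition).
#' @param viscosity Dynamic viscosity, Pa s.  Default 0.9321e-3 (water at
#'   23 C).
#' @return An object of class `solvent_conditions`.
#' @export
solvent_conditions <- function(temperature = 296.15, viscosity = 0.9321e-3) {
  if (temperature <= 0 || viscosity <= 0) {
    stop("temperature and viscosity must be positive")
  }
  structure(list(temperature = temperature, viscosity = viscosity),
            class = "solvent_conditions")
}

#' Confocal focus geometry
#'
#' @param wxy Lateral 1/e^2 waist of the detection volume, meters.
#' @param wz Axial 1/e^2 extent, meters.  The default 10x aspect ratio keeps
#'   axial diffusion negligible over the fit window, consistent with the 2D
#'   diffusion model used for fitting.
#' @return An object of class `focus_geometry`.
#' @export
focus_geometry <- function(wxy = 0.25e-6, wz = 2.5e-6) {
  if (wxy <= 0 || wz <= 0) stop("focus dimensions must be positive")
  structure(list(wxy = wxy, wz = wz), class = "focus_geometry")
}

#' Boltzmann constant, J/K
#' @keywords internal
.k_boltzmann <- 1.380649e-23

#' Stokes-Einstein conversions among D, R and the diffusion time
#'
#' Completes the triple (diffusion coefficient `D`, hydrodynamic radius `R`,
#' diffusion time `tau`) from exactly one given quantity, using
#' `D = k_B T / (6 pi eta R)` and `tau = wxy^2 / (4 D)`.
#'
#' @param conditions A [solvent_conditions()].
#' @param radius Hydrodynamic radius, meters.
#' @param diffusion Diffusion coefficient, m^2/s.
#' @param tau Diffusion time, seconds (requires `focus`).
#' @param focus A [focus_geometry()]; needed to link `tau` and `D`.
#' @return A list with `D` (m^2/s), `R` (m) and `tau` (seconds; `NA` when no
#'   focus is given).
#' @examples
#' # a 2.3 nm protein in water at 23 C diffuses at ~1.0e-10 m^2/s
#' stokes_einstein(solvent_conditions(), radius = 2.3e-9)$D
#' @export
stokes_einstein <- function(conditions = solvent_conditions(), radius = NULL,
                            diffusion = NULL, tau = NULL, focus = NULL) {
  given <- !c(is.null(radius), is.null(diffusion), is.null(tau))
  if (sum(given) != 1L) {
    stop("give exactly one of `radius`, `diffusion`, `tau`")
  }
  se_d_from_r <- function(r) {
    .k_boltzmann * conditions$temperature / (6 * pi * conditions$viscosity * r)
  }
  if (!is.null(radius)) {
    if (any(radius <= 0)) stop("`radius` must be positive")
    D <- se_d_from_r(radius)
    R <- radius
  } else if (!is.null(diffusion)) {
    if (any(diffusion <= 0)) stop("`diffusion` must be positive")
    D <- diffusion
    R <- se_d_from_r(diffusion) # relation is self-inverse in R <-> D
  } else {
    if (any(tau <= 0)) stop("`tau` must be positive")
    if (is.null(focus)) stop("`focus` required when `tau` is given")
    D <- focus$wxy^2 / (4 * tau)
    R <- se_d_from_r(D)
  }
  tau_out <- if (!is.null(focus)) focus$wxy^2 / (4 * D) else NA_real_
  list(D = D, R = R, tau = tau_out)
}

#' Molecular weight from the diffusion-time ratio to a reference
#'
#' Under the equal-density spherical approximation the mass scales as the
#' cube of the diffusion time, `M1 = M2 (tau1/tau2)^3`; the first-order
#' relative variance is `9 (s1^2/tau1^2 + s2^2/tau2^2)`.
#'
#' @param tau,tau_sd Diffusion time of the target species and its standard
#'   deviation, seconds.
#' @param tau_ref,tau_ref_sd Reference diffusion time and its standard
#'   deviation, seconds.
#' @param mass_ref Reference molecular weight, daltons.
#' @return A list with `mass` and `sd`, daltons.
#' @export
mass_from_tau <- function(tau, tau_ref, mass_ref, tau_sd = 0, tau_ref_sd = 0) {
  if (is.null(mass_ref) || !is.numeric(mass_ref) || mass_ref <= 0) {
    stop("`mass_ref` must be a positive mass in daltons")
  }
  if (tau <= 0 || tau_ref <= 0) stop("diffusion times must be positive")
  mass <- mass_ref * (tau / tau_ref)^3
  rel_var <- 9 * (tau_sd^2 / tau^2 + tau_ref_sd^2 / tau_ref^2)
  list(mass = mass, sd = mass * sqrt(rel_var))
}

#' Chaperone:client stoichiometric ratio from bound/apo diffusion times
#'
#' `r = ((tau_bound/tau_apo)^3 - 1) * m_client / m_chaperone`: the complex
#' mass in client units, converted to the number of bound chaperone monomers.
#' The uncertainty applies the first-order cubic-propagation scheme to the
#' diffusion-time ratio.
#'
#' @param tau_bound,tau_apo Diffusion times of bound and free client, seconds.
#' @param m_client,m_chaperone Molecular weights, daltons.
#' @param tau_bound_sd,tau_apo_sd Standard deviations of the diffusion times.
#' @return A list with `r` and `sd`.
#' @examples
#' stoichiometric_ratio(549e-6, 422e-6, 40.2e3, 18.8e3)$r # about 2.57
#' @export
stoichiometric_ratio <- function(tau_bound, tau_apo, m_client, m_chaperone,
                                 tau_bound_sd = 0, tau_apo_sd = 0) {
  if (m_client <= 0 || m_chaperone <= 0) stop("masses must be positive")
  if (tau_bound <= 0 || tau_apo <= 0) stop("diffusion times must be positive")
  if (tau_bound < tau_apo) {
    warning("tau_bound < tau_apo: complex apparently lighter than free client")
  }
  q3 <- (tau_bound / tau_apo)^3
  rho <- m_client / m_chaperone
  r <- (q3 - 1) * rho
  var_r <- (rho * q3)^2 * 9 *
    (tau_bound_sd^2 / tau_bound^2 + tau_apo_sd^2 / tau_apo^2)
  list(r = r, sd = sqrt(var_r))
}

#' Effective stoichiometric number from a dye-referenced diffusion time
#'
#' The observable of the self-trimerization titration: the apparent number of
#' monomer masses diffusing together, `n = (tau/tau_ref)^3 * m_ref /
#' m_monomer`, with a free dye as the reference species.
#'
#' @param tau Measured diffusion time of the labelled species, seconds.
#' @param tau_ref Reference (free dye) diffusion time, seconds.
#' @param m_ref Reference molecular weight, daltons.
#' @param m_monomer Monomer molecular weight, daltons.
#' @return The effective stoichiometric number `n`.
#' @export
effective_stoichiometry <- function(tau, tau_ref, m_ref, m_monomer) {
  if (any(c(tau, tau_ref, m_ref, m_monomer) <= 0)) {
    stop("all inputs must be positive")
  }
  (tau / tau_ref)^3 * m_ref / m_monomer
}

#' Diffusion-limited association rate constant
#'
#' Smoluchowski encounter rate `k+ = 4 pi (D_A + D_B)(R_A + R_B)`, converted
#' to per-molar per-second via Avogadro's number and the m^3 to litre factor.
#'
#' @param d_a,r_a Diffusion coefficient (m^2/s) and radius (m) of species A.
#' @param d_b,r_b Same for species B.
#' @return Rate constant in M^-1 s^-1.
#' @export
diffusion_limited_rate <- function(d_a, r_a, d_b, r_b) {
  if (any(c(d_a, r_a, d_b, r_b) <= 0)) stop("all inputs must be positive")
  avogadro <- 6.02214076e23
  4 * pi * (d_a + d_b) * (r_a + r_b) * avogadro * 1e3
}
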