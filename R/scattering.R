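#' Dielectric spectrum of a medium
#'
#' Complex relative permittivity (and optionally permeability) on a frequency
#' grid. Sign convention follows the susceptibility: `eps = eps' - 1i*eps''`
#' with loss `eps'' >= 0`, i.e. passive media have `Im(eps_rel) <= 0`.
#'
#' @param freq Strictly increasing frequency grid (Hz).
#' @param eps_rel Complex relative permittivity per frequency.
#' @param mu_rel Complex relative permeability per frequency (default 1,
#'   nonmagnetic tissue).
#' @return An object of class `dielectric_spectrum`.
#' @export
dielectric_spectrum <- function(freq, eps_rel, mu_rel = rep(1 + 0i, length(freq))) {
  if (any(diff(freq) <= 0)) stop("frequency grid must be strictly increasing")
  eps_rel <- rep_len(as.complex(eps_rel), length(freq))
  mu_rel <- rep_len(as.complex(mu_rel), length(freq))
  if (any(Im(eps_rel) > 1e-12))
    stop("passive convention violated: Im(eps_rel) must be <= 0 (eps = eps' - i*eps'')")
  structure(list(freq = freq, eps_rel = eps_rel, mu_rel = mu_rel),
            class = "dielectric_spectrum")
}

#' Single-pole Debye dielectric model
#'
#' `eps(f) = eps_inf + delta_eps/(1 + i*2*pi*f*tau) - 1i*sigma_s/(2*pi*f*eps0)`.
#' Used to generate approximate presets for the host medium (cream, emulating
#' fatty tissue) and the gelatin/water tumor-mimicking target.
#'
#' @param freq Frequency grid (Hz).
#' @param eps_inf High-frequency permittivity.
#' @param delta_eps Dispersion amplitude.
#' @param tau Relaxation time (s).
#' @param sigma_s Static conductivity (S/m).
#' @param constants A [physical_constants()] object.
#' @return A `dielectric_spectrum`.
#' @examples
#' cream <- debye_spectrum(seq(1e9, 4e9, length.out = 16))
#' @export
debye_spectrum <- function(freq, eps_inf = 5, delta_eps = 15, tau = 18e-12,
                           sigma_s = 0.3, constants = physical_constants()) {
  eps <- eps_inf + delta_eps / (1 + 1i * 2 * pi * freq * tau)
  cond <- ifelse(freq > 0, sigma_s / (2 * pi * freq * constants$eps0), 0)
  dielectric_spectrum(freq, eps - 1i * cond)
}

#' @rdname debye_spectrum
#' @export
target_debye_spectrum <- function(freq, eps_inf = 6, delta_eps = 40,
                                  tau = 12e-12, sigma_s = 0.7,
                                  constants = physical_constants()) {
  debye_spectrum(freq, eps_inf, delta_eps, tau, sigma_s, constants)
}

principal_impedance_sqrt <- function(z) {
  s <- sqrt(z)
  # passive impedance must have Re >= 0; flip branch if violated
  ifelse(Re(s) < 0, -s, s)
}

#' Wave impedance of a medium
#'
#' `Z(f) = Z0*sqrt(mu_rel/eps_rel)` with `Z0 = sqrt(mu0/eps0)`; principal
#' branch of the complex square root with `Re(Z) >= 0` enforced.
#'
#' @param spec A [dielectric_spectrum()].
#' @param constants A [physical_constants()] object.
#' @return Complex impedance per frequency (Ohm).
#' @examples
#' sp <- dielectric_spectrum(c(1e9, 2e9), c(1, 1))
#' impedance(sp)  # ~376.73 Ohm, free space
#' @export
impedance <- function(spec, constants = physical_constants()) {
  stopifnot(inherits(spec, "dielectric_spectrum"))
  if (any(spec$eps_rel == 0)) stop("zero permittivity: impedance undefined")
  constants$Z0 * principal_impedance_sqrt(spec$mu_rel / spec$eps_rel)
}

#' Field-dependent reflection coefficient at the tumor/host boundary
#'
#' Plane-wave, specular, normal-incidence reflection between the host medium
#' (permittivity `eps_1`, `mu_1 = 1`) and the MNP-loaded target
#' (`eps_2`, `mu_2(f, H) = 1 + chi(f, H)`):
#' `Gamma = (sqrt(mu_2*eps_1/eps_2) - 1) / (sqrt(mu_2*eps_1/eps_2) + 1)`,
#' algebraically equal to the impedance form `(Z2 - Z1)/(Z2 + Z1)`.
#'
#' @param host Host-medium [dielectric_spectrum()].
#' @param target Target [dielectric_spectrum()] (its `mu_rel` is replaced by
#'   `1 + chi(f, H)` when a susceptibility model is given).
#' @param chi_model A `susceptibility_model`, or `NULL` for a nonmagnetic
#'   target.
#' @param H Field intensity (A/m) at which the MNP susceptibility is taken.
#' @param env Carrier environment for closed-form chi.
#' @return An object of class `reflection_spectrum` with fields `freq`,
#'   `gamma` and `field`.
#' @export
reflection_coefficient <- function(host, target, chi_model = NULL, H = 0,
                                   env = medium_environment()) {
  stopifnot(inherits(host, "dielectric_spectrum"),
            inherits(target, "dielectric_spectrum"))
  if (length(host$freq) != length(target$freq) ||
      any(host$freq != target$freq))
    stop("host and target must share the same frequency grid")
  mu2 <- if (is.null(chi_model)) target$mu_rel else
    1 + susceptibility(chi_model, target$freq, H, env)
  s <- principal_impedance_sqrt(mu2 * host$eps_rel / target$eps_rel)
  structure(list(freq = host$freq, gamma = (s - 1) / (s + 1), field = H),
            class = "reflection_spectrum")
}

#' Differential reflection coefficient between two field states
#'
#' `dGamma(f) = Gamma(f, Hm) - Gamma(f, Hn)`; identically zero when the target
#' susceptibility does not depend on the field, which is what makes the
#' differential measurement blind to static (field-independent) scatterers.
#'
#' @inheritParams reflection_coefficient
#' @param Hm,Hn Field intensities of the two states (A/m).
#' @return A `reflection_spectrum` whose `gamma` holds the difference and
#'   whose `field` holds `c(Hm, Hn)`.
#' @export
differential_reflection <- function(host, target, chi_model, Hm, Hn,
                                    env = medium_environment()) {
  gm <- reflection_coefficient(host, target, chi_model, Hm, env)
  gn <- reflection_coefficient(host, target, chi_model, Hn, env)
  structure(list(freq = gm$freq, gamma = gm$gamma - gn$gamma,
                 field = c(Hm, Hn)),
            class = "reflection_spectrum")
}
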