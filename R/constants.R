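#' Physical constants
#'
#' Returns the set of physical constants used throughout the package, in SI
#' units. The gyromagnetic ratio is expressed per unit of magnetic field
#' *intensity* (rad s^-1 per A/m), i.e. the free-electron value in rad/s/T
#' multiplied by `mu0`, so that resonance frequencies can be computed directly
#' from field intensities H in A/m.
#'
#' @param kb Boltzmann constant (J/K).
#' @param mu0 Vacuum permeability (H/m).
#' @param eps0 Vacuum permittivity (F/m).
#' @param gamma Gyromagnetic ratio (rad s^-1 (A/m)^-1).
#' @return An object of class `physical_constants`.
#' @examples
#' pc <- physical_constants()
#' pc$mu0 * pc$eps0 * 299792458^2  # ~ 1
#' @export
physical_constants <- function(kb = 1.380649e-23,
                               mu0 = 4e-7 * pi,
                               eps0 = 8.8541878128e-12,
                               gamma = 1.760859630e11 * 4e-7 * pi) {
  stopifnot(kb > 0, mu0 > 0, eps0 > 0, gamma > 0)
  c_light <- 1 / sqrt(mu0 * eps0)
  if (abs(mu0 * eps0 * 299792458^2 - 1) > 1e-9)
    stop("mu0*eps0 inconsistent with the speed of light")
  structure(list(kb = kb, mu0 = mu0, eps0 = eps0, gamma = gamma,
                 c = c_light, Z0 = sqrt(mu0 / eps0)),
            class = "physical_constants")
}

#' Unit converters for magnetic quantities
#'
#' Magnetization quoted in gauss (CGS, as 4*pi*M) converts to A/m via
#' 1 G = 79.577 A/m; field intensities at user interfaces are accepted in kA/m
#' (the conventional unit in the MNP-imaging literature) and converted once to
#' A/m at the boundary.
#'
#' @param x Numeric vector.
#' @return Numeric vector in A/m.
#' @export
gauss_to_a_per_m <- function(x) x * 1e3 / (4 * pi)

#' @rdname gauss_to_a_per_m
#' @export
ka_per_m_to_a_per_m <- function(x) x * 1e3
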