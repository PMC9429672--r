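#' Physical constants and unit conventions
#'
#' The package uses one unit system throughout: energies in micro-eV,
#' momentum transfer q in inverse Angstrom, diffusion coefficients in
#' Angstrom^2 per nanosecond, times in nanoseconds, radii in nanometres
#' (hydrodynamics) or Angstrom (EISF geometry), viscosities in Pa s and
#' temperatures in Kelvin.  A diffusion coefficient D (A^2/ns) maps to a
#' Lorentzian half width at half maximum gamma = hbar * D * q^2 (micro-eV).
#'
#' @format `qens_constants` is a list with elements:
#' \describe{
#'   \item{hbar_uev_ns}{reduced Planck constant, 0.6582119569 micro-eV ns (CODATA)}
#'   \item{kB_J_per_K}{Boltzmann constant, 1.380649e-23 J/K (exact, SI)}
#'   \item{fwhm_over_sd}{Gaussian FWHM / standard deviation, 2 sqrt(2 ln 2)}
#' }
#' @export
qens_constants <- list(
  hbar_uev_ns = 0.6582119569,
  kB_J_per_K  = 1.380649e-23,
  fwhm_over_sd = 2 * sqrt(2 * log(2))
)

.hbar <- qens_constants$hbar_uev_ns
.kB   <- qens_constants$kB_J_per_K

#' Convert a Gaussian FWHM to its standard deviation
#'
#' @param fwhm full width at half maximum (any unit)
#' @return standard deviation in the same unit
#' @export
fwhm_to_sd <- function(fwhm) fwhm / qens_constants$fwhm_over_sd

#' Convert a Gaussian standard deviation to its FWHM
#'
#' @param sd standard deviation (any unit)
#' @return full width at half maximum in the same unit
#' @export
sd_to_fwhm <- function(sd) sd * qens_constants$fwhm_over_sd

#' Jump-diffusion linewidth
#'
#' Half width at half maximum of the quasi-elastic Lorentzian for jump
#' diffusion with diffusion coefficient `D_i` and residence time `tau`:
#' gamma(q) = hbar * D_i * q^2 / (1 + D_i * q^2 * tau).  The width grows as
#' hbar * D_i * q^2 at small q and saturates at hbar / tau at large q; with
#' `tau = 0` it reduces to the Fickian linewidth hbar * D * q^2.
#'
#' @param q momentum transfer (1/Angstrom), vectorised
#' @param D_i jump diffusion coefficient (Angstrom^2/ns), > 0
#' @param tau residence time between jumps (ns), >= 0
#' @return HWHM in micro-eV
#' @export
jump_diffusion_hwhm <- function(q, D_i, tau) {
  stopifnot(D_i > 0, tau >= 0)
  .hbar * D_i * q^2 / (1 + D_i * q^2 * tau)
}

#' Fickian linewidth
#'
#' gamma(q) = hbar * D * q^2 for simple (Fickian) diffusion.
#'
#' @param q momentum transfer (1/Angstrom)
#' @param D diffusion coefficient (Angstrom^2/ns)
#' @return HWHM in micro-eV
#' @export
fickian_hwhm <- function(q, D) .hbar * D * q^2
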