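#' Instrument profile
#'
#' Describes the measurement grids and nominal energy resolution of a
#' neutron spectrometer: a backscattering-like instrument (sub-micro-eV
#' resolution, narrow energy window, nanosecond motions) or a
#' time-of-flight-like instrument (tens of micro-eV resolution, wide
#' window, picosecond motions).
#'
#' @param name label, e.g. "backscattering"
#' @param kind "backscattering" or "tof"; selects which spectral model the
#'   simulator and fitting pipeline apply
#' @param q momentum-transfer grid (1/Angstrom), positive and increasing
#' @param omega energy-transfer grid (micro-eV), strictly increasing
#' @param fwhm energy resolution FWHM (micro-eV)
#' @return an `instrument_profile` object
#' @export
instrument_profile <- function(name, kind = c("backscattering", "tof"),
                               q, omega, fwhm) {
  kind <- match.arg(kind)
  stopifnot(all(q > 0), !is.unsorted(q, strictly = TRUE),
            !is.unsorted(omega, strictly = TRUE), fwhm > 0)
  window <- max(abs(range(omega)))
  if (window < 10 * fwhm)
    stop("energy window must be >= 10x the resolution FWHM")
  structure(list(name = name, kind = kind, q = as.numeric(q),
                 omega = as.numeric(omega), fwhm = fwhm, window = window),
            class = "instrument_profile")
}

#' Default instrument profiles
#'
#' Two instrument emulations: a backscattering-like spectrometer with
#' 0.75 micro-eV FWHM resolution, a +/- 30 micro-eV window and 16 q points
#' in 0.2-1.9 1/Angstrom; and a time-of-flight-like spectrometer with
#' 80 micro-eV FWHM, a +/- 3000 micro-eV window and 18 q points in
#' 0.3-2.0 1/Angstrom.
#'
#' @param n_omega_bs,n_omega_tof number of energy channels for each profile
#' @return named list with elements `backscattering` and `tof`
#' @export
default_profiles <- function(n_omega_bs = 256L, n_omega_tof = 512L) {
  list(
    backscattering = instrument_profile(
      "backscattering", "backscattering",
      q = seq(0.2, 1.9, length.out = 16L),
      omega = seq(-30, 30, length.out = n_omega_bs),
      fwhm = 0.75),
    tof = instrument_profile(
      "tof", "tof",
      q = seq(0.3, 2.0, length.out = 18L),
      omega = seq(-3000, 3000, length.out = n_omega_tof),
      fwhm = 80)
  )
}

#' Default resolution model for an instrument profile
#'
#' One centred Gaussian per q at the profile's nominal FWHM.
#'
#' @param profile an [instrument_profile()]
#' @return a [resolution_model()]
#' @export
profile_resolution <- function(profile) {
  stopifnot(inherits(profile, "instrument_profile"))
  gaussian_resolution(profile$q, profile$fwhm)
}

#' QENS spectrum set
#'
#' Container for S(q, omega) of one sample at one temperature: intensity
#' and pointwise uncertainty matrices (rows = q, columns = omega).
#'
#' @param profile an [instrument_profile()]
#' @param intensity,error numeric matrices, length(q) x length(omega);
#'   errors strictly positive wherever intensity is finite
#' @param sample one of "solvent", "apo", "liganded", "ligand-only"
#' @param temperature sample temperature (K)
#' @return a `spectrum_set` object
#' @export
spectrum_set <- function(profile, intensity, error,
                         sample = c("solvent", "apo", "liganded", "ligand-only"),
                         temperature = 295) {
  sample <- match.arg(sample)
  stopifnot(inherits(profile, "instrument_profile"),
            is.matrix(intensity), is.matrix(error),
            nrow(intensity) == length(profile$q),
            ncol(intensity) == length(profile$omega),
            all(dim(intensity) == dim(error)))
  bad <- is.finite(intensity) & !(error > 0)
  if (any(bad)) stop("errors must be > 0 wherever intensity is finite")
  structure(list(profile = profile, q = profile$q, omega = profile$omega,
                 intensity = intensity, error = error, sample = sample,
                 temperature = temperature),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("Spectrum set: %s sample on %s, %d q x %d channels, T = %g K\n",
              x$sample, x$profile$name, length(x$q), length(x$omega),
              x$temperature))
  invisible(x)
}

#' Ground truth for the synthetic-data generator
#'
#' Holds every parameter the simulators need, with defaults emulating the
#' study conditions: a crowded protein solution (volume fraction 0.09) in
#' D2O, apparent centre-of-mass diffusion near 3 Angstrom^2/ns, internal
#' jump diffusion with D_i ~ 50 Angstrom^2/ns and residence time ~ 0.01 ns,
#' and an EISF with immobile fraction ~ 0.4, methyl weight ~ 0.3, sphere
#' radius 8.5 Angstrom and the fixed methyl jump distance 1.715 Angstrom.
#' Default amplitudes reflect a concentrated liganded sample: the
#' hydrogen-rich protein + ligand signal well above the weak incoherent
#' D2O background, and only a small apparent-elastic container line.
#'
#' @param solvent list: `D_w` and `tau_w` (jump-diffusion parameters of the
#'   narrow D2O line, Angstrom^2/ns and ns), `sigma_broad` (HWHM of the
#'   broad solvent line, micro-eV), amplitudes `I1`, `I2`, `I_el`,
#'   background `slope` (1/micro-eV per micro-eV) and `offset`
#' @param protein list: `D` (centre-of-mass, Angstrom^2/ns), `D_i`, `tau`
#'   (internal jump diffusion), EISF parameters `a`, `b`, `R` (Angstrom),
#'   `d` (Angstrom), `beta` (per-q amplitude of the protein signal on the
#'   backscattering instrument), `beta_d2o` (solvent amplitude there),
#'   `gamma_fast` (HWHM of the fast internal line on the TOF instrument,
#'   micro-eV) and `tof_amplitudes`, a named list per sample label with
#'   elements `I_el`, `I_slow`, `I_fast`
#' @param phi dry protein volume fraction in [0, 1)
#' @param phi_ligand_only volume fraction used for the ligand-only sample
#' @param noise noise scale: the simulated point at (q, omega) receives
#'   additive Gaussian noise with sd = noise * sqrt(max(model, 1e-6 * peak))
#'   (counting statistics on reduced data); 0 = noiseless
#' @param seed integer seed; mandatory whenever `noise > 0`
#' @return a `ground_truth` list
#' @export
ground_truth <- function(solvent = list(), protein = list(), phi = 0.09,
                         phi_ligand_only = 0.03, noise = 0, seed = NULL) {
  sol <- utils::modifyList(list(
    D_w = 80, tau_w = 0.001, sigma_broad = 800,
    I1 = 0.08, I2 = 0.04, I_el = 0.005,
    slope = -2e-7, offset = 2e-5), solvent)
  pro <- utils::modifyList(list(
    D = 3.0, D_i = 50, tau = 0.01,
    a = 0.4, b = 0.3, R = 8.5, d = 1.715,
    beta = 0.2, beta_d2o = 0.05, gamma_fast = 300,
    tof_amplitudes = list(
      liganded      = c(I_el = 0.004, I_slow = 0.15, I_fast = 0.05),
      apo           = c(I_el = 0.001, I_slow = 0.05, I_fast = 0),
      `ligand-only` = c(I_el = 0.001, I_slow = 0.04, I_fast = 0.01))),
    protein)
  stopifnot(sol$I1 >= 0, sol$I2 >= 0, sol$I_el >= 0,
            pro$a >= 0, pro$a <= 1, pro$b >= 0, pro$b <= 1,
            pro$R > 0, phi >= 0, phi < 1, noise >= 0)
  structure(list(solvent = sol, protein = pro, phi = phi,
                 phi_ligand_only = phi_ligand_only, noise = noise,
                 seed = seed),
            class = "ground_truth")
}

#' Per-q solvent parameters implied by a ground truth
#'
#' @param truth a [ground_truth()]
#' @param q momentum-transfer grid (1/Angstrom)
#' @return data frame with columns q, I1, I2, I_el, sigma1, sigma2, slope,
#'   offset (the narrow width sigma1 from the solvent jump-diffusion law,
#'   sigma2 the broad constant)
#' @export
solvent_truth_params <- function(truth, q) {
  s <- truth$solvent
  data.frame(q = q,
             I1 = s$I1, I2 = s$I2, I_el = s$I_el,
             sigma1 = jump_diffusion_hwhm(q, s$D_w, s$tau_w),
             sigma2 = s$sigma_broad,
             slope = s$slope, offset = s$offset)
}

#' Per-q backscattering solvent parameters implied by a ground truth
#'
#' The D2O contribution inside the backscattering model: amplitude
#' beta_D2O(q) and Lorentzian width gamma_D2O(q) (the narrow water line).
#'
#' @inheritParams solvent_truth_params
#' @return data frame with columns q, beta_d2o, gamma_d2o
#' @export
bs_solvent_truth_params <- function(truth, q) {
  s <- truth$solvent
  data.frame(q = q, beta_d2o = truth$protein$beta_d2o,
             gamma_d2o = jump_diffusion_hwhm(q, s$D_w, s$tau_w))
}

.apply_counting_noise <- function(model_matrix, noise, seed) {
  peak <- max(model_matrix)
  floor_val <- 1e-6 * peak
  if (noise > 0) {
    if (is.null(seed)) stop("a seed is mandatory when noise > 0")
    set.seed(as.integer(seed))
    err <- noise * sqrt(pmax(model_matrix, floor_val))
    intensity <- model_matrix + matrix(
      stats::rnorm(length(model_matrix)), nrow = nrow(model_matrix)) * err
  } else {
    err <- matrix(1e-8 * max(peak, .Machine$double.xmin),
                  nrow = nrow(model_matrix), ncol = ncol(model_matrix))
    intensity <- model_matrix
  }
  list(intensity = intensity, error = err)
}

#' Noise scale for a target peak signal-to-noise ratio
#'
#' With counting-statistics noise sd = noise * sqrt(model), the
#' signal-to-noise at the peak is sqrt(peak)/noise.
#'
#' @param peak peak model intensity
#' @param snr desired signal-to-noise ratio at the peak
#' @return the noise scale to pass to [ground_truth()]
#' @export
noise_for_snr <- function(peak, snr) sqrt(peak) / snr

#' Simulate a pure-solvent spectrum set
#'
#' Noiseless model: resolution-convolved sum of two solvent Lorentzians
#' (widths ordered sigma1 < sigma2) plus an elastic container line and a
#' sloped background, per q; counting-statistics noise applied on top.
#' Uncertainties equal the applied noise standard deviation.
#'
#' @param profile an [instrument_profile()] (typically the tof profile)
#' @param truth a [ground_truth()]
#' @param temperature sample temperature (K)
#' @param seed overrides `truth$seed`
#' @return a [spectrum_set()] with sample = "solvent"
#' @export
simulate_solvent <- function(profile, truth, temperature = 295, seed = truth$seed) {
  stopifnot(inherits(profile, "instrument_profile"),
            inherits(truth, "ground_truth"))
  res <- profile_resolution(profile)
  sp <- solvent_truth_params(truth, profile$q)
  if (any(sp$sigma1 >= sp$sigma2))
    stop("solvent truth must have sigma1 < sigma2 at every q")
  model <- t(vapply(seq_along(profile$q), function(i) {
    solvent_model_eval(unlist(sp[i, c("I1", "I2", "I_el", "sigma1", "sigma2",
                                      "slope", "offset")]),
                       profile$omega, resolution_at(res, profile$q[i]))
  }, numeric(length(profile$omega))))
  noisy <- .apply_counting_noise(model, truth$noise, seed)
  spectrum_set(profile, noisy$intensity, noisy$error, "solvent", temperature)
}

#' Simulate a protein-solution spectrum set
#'
#' For a tof-like profile, emits the two-step model structure: apparent
#' elastic line + slow internal Lorentzian (jump-diffusion width at each q)
#' + fast broad Lorentzian + (1 - phi)-scaled solvent + background.  For a
#' backscattering-like profile, emits the global model: per-q amplitude
#' beta(q) times (A0(q) L(hbar D q^2) + (1 - A0(q)) L(hbar D q^2 +
#' Gamma(q))) plus the solvent water Lorentzian, all resolution-convolved,
#' with A0 from the EISF model and Gamma from jump diffusion.
#'
#' @param profile an [instrument_profile()]
#' @param truth a [ground_truth()]
#' @param sample "apo", "liganded" or "ligand-only" (for a pure-solvent
#'   spectrum use [simulate_solvent()])
#' @param temperature sample temperature (K)
#' @param seed overrides `truth$seed`
#' @param scale_solvent logical; scale the backscattering solvent amplitude
#'   by (1 - phi) as in the tof model (default TRUE)
#' @return a [spectrum_set()]
#' @export
simulate_protein <- function(profile, truth,
                             sample = c("liganded", "apo", "ligand-only"),
                             temperature = 295, seed = truth$seed,
                             scale_solvent = TRUE) {
  sample <- match.arg(sample)
  stopifnot(inherits(profile, "instrument_profile"),
            inherits(truth, "ground_truth"))
  res <- profile_resolution(profile)
  pro <- truth$protein
  phi <- if (sample == "ligand-only") truth$phi_ligand_only else truth$phi
  if (profile$kind == "tof") {
    sp <- solvent_truth_params(truth, profile$q)
    amps <- pro$tof_amplitudes[[sample]]
    model <- t(vapply(seq_along(profile$q), function(i) {
      q <- profile$q[i]
      free <- c(I_el = unname(amps["I_el"]),
                I_slow = unname(amps["I_slow"]),
                gamma_slow = jump_diffusion_hwhm(q, pro$D_i, pro$tau),
                I_fast = unname(amps["I_fast"]),
                gamma_fast = pro$gamma_fast)
      protein_tof_model_eval(free, profile$omega, resolution_at(res, q),
                             unlist(sp[i, c("I1", "I2", "sigma1", "sigma2",
                                            "slope", "offset")]), phi)
    }, numeric(length(profile$omega))))
  } else {
    bsol <- bs_solvent_truth_params(truth, profile$q)
    A0 <- eisf_model(profile$q, pro$a, pro$b, pro$R, pro$d)
    Gamma <- jump_diffusion_hwhm(profile$q, pro$D_i, pro$tau)
    sol_scale <- if (scale_solvent) 1 - phi else 1
    model <- t(vapply(seq_along(profile$q), function(i) {
      q <- profile$q[i]
      bs_model_eval(profile$omega, resolution_at(res, q),
                    D = pro$D, q = q, beta = pro$beta, A0 = A0[i],
                    Gamma = Gamma[i],
                    beta_d2o = sol_scale * bsol$beta_d2o[i],
                    gamma_d2o = bsol$gamma_d2o[i])
    }, numeric(length(profile$omega))))
  }
  noisy <- .apply_counting_noise(model, truth$noise, seed)
  spectrum_set(profile, noisy$intensity, noisy$error, sample, temperature)
}

#' Simulate dynamic light scattering correlograms
#'
#' Single-exponential Siegert correlograms g2(tau) = 1 + beta_c *
#' exp(-2 Gamma tau) with Gamma = D_t(c) q^2, D_t(c) = D_t (1 + k_D c),
#' and q from the scattering angle.  Lag-time grids are log-spaced around
#' the decay time at each angle.
#'
#' @param D_t translational diffusion coefficient at infinite dilution
#'   (Angstrom^2/ns)
#' @param angles scattering angles (degrees, in (0, 180))
#' @param concentrations protein concentrations (mg/mL)
#' @param k_D linear interaction slope (mL/mg); default 0
#' @param beta_c coherence amplitude g2(0) - 1
#' @param noise additive Gaussian noise sd on g2; 0 = noiseless
#' @param seed integer seed; mandatory when `noise > 0`
#' @param n_tau lag points per correlogram (>= 20)
#' @param wavelength laser wavelength (nm)
#' @param refractive_index solvent refractive index
#' @param temperature bath temperature (K)
#' @return a `dls_dataset`: list with `curves` (data frame: angle,
#'   concentration, tau_s, g2, error), instrument constants and the truth
#'   echoed in attributes
#' @export
simulate_dls <- function(D_t, angles = seq(30, 150, by = 20),
                         concentrations = 1:5, k_D = 0, beta_c = 0.8,
                         noise = 0, seed = NULL, n_tau = 60L,
                         wavelength = 632.8, refractive_index = 1.33,
                         temperature = 295) {
  if (any(angles <= 0 | angles >= 180))
    stop("scattering angles must lie in (0, 180) degrees")
  stopifnot(n_tau >= 20L, D_t > 0)
  if (noise > 0) {
    if (is.null(seed)) stop("a seed is mandatory when noise > 0")
    set.seed(as.integer(seed))
  }
  rows <- list()
  for (conc in concentrations) {
    Dc <- D_t * (1 + k_D * conc)          # Angstrom^2/ns
    for (th in angles) {
      q <- q_from_angle(th, refractive_index, wavelength)   # 1/Angstrom
      Gamma <- Dc * 1e9 * q^2             # 1/s
      tau <- exp(seq(log(0.01 / (2 * Gamma)), log(12 / (2 * Gamma)),
                     length.out = n_tau))
      g2 <- 1 + beta_c * exp(-2 * Gamma * tau)
      err <- rep(max(noise, 1e-6), length(tau))
      if (noise > 0) g2 <- g2 + stats::rnorm(length(tau), sd = noise)
      rows[[length(rows) + 1L]] <- data.frame(
        angle = th, concentration = conc, tau_s = tau, g2 = g2, error = err)
    }
  }
  structure(list(curves = do.call(rbind, rows),
                 wavelength = wavelength,
                 refractive_index = refractive_index,
                 temperature = temperature),
            class = "dls_dataset",
            truth = list(D_t = D_t, k_D = k_D, beta_c = beta_c))
}
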