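# Dynamic light scattering: Siegert single-exponential correlogram fits,
# q^2 scaling of the decay rates and dilute-limit extrapolation.

#' Momentum transfer from a scattering angle
#'
#' q = (4 pi n / lambda) sin(theta / 2), returned in 1/Angstrom.
#'
#' @param theta scattering angle (degrees), in (0, 180)
#' @param n refractive index of the solvent (default 1.33, D2O)
#' @param wavelength laser wavelength (nm, default 632.8)
#' @return momentum transfer (1/Angstrom)
#' @export
q_from_angle <- function(theta, n = 1.33, wavelength = 632.8) {
  if (any(theta <= 0 | theta >= 180))
    stop("scattering angles must lie in (0, 180) degrees")
  (4 * pi * n / wavelength) * sin(theta * pi / 360) / 10
}

#' Fit a single-exponential Siegert model to one correlogram
#'
#' Weighted fit of g2(tau) = 1 + beta exp(-2 Gamma tau).  The lag window
#' must bracket the decay: if g2 has not decayed by at least half of its
#' coherence amplitude within the window the fit is flagged.
#'
#' @param tau lag times (s), increasing, >= 20 points
#' @param g2 intensity autocorrelation values
#' @param err pointwise uncertainties; equal weights if omitted
#' @return a `g2_fit` list: `Gamma` (1/s), `beta`, standard errors,
#'   `decay_captured` flag and residuals
#' @export
fit_g2 <- function(tau, g2, err = NULL) {
  stopifnot(length(tau) >= 20L, !is.unsorted(tau), length(g2) == length(tau))
  if (is.null(err) || !all(is.finite(err)) || !all(err > 0))
    err <- rep(1, length(tau))
  amp0 <- max(g2[1] - 1, 1e-3)
  # decay time from the lag where g2 - 1 first drops below amp0/2
  below <- which(g2 - 1 < amp0 / 2)
  t_half <- if (length(below)) tau[below[1]] else tau[length(tau)]
  G0 <- log(2) / (2 * t_half)
  fit <- .wls_fit(c(Gamma = G0, beta = amp0),
                  function(p) 1 + p[["beta"]] * exp(-2 * p[["Gamma"]] * tau),
                  g2, err, lower = c(1e-12, 0), upper = c(Inf, 2))
  p <- fit$par
  decay_captured <- (p[["Gamma"]] * tau[length(tau)] > 1) &&
    (p[["Gamma"]] * tau[1] < 0.5)
  if (!decay_captured)
    warning("lag window does not bracket the correlogram decay")
  resid <- g2 - (1 + p[["beta"]] * exp(-2 * p[["Gamma"]] * tau))
  structure(list(Gamma = unname(p[["Gamma"]]), beta = unname(p[["beta"]]),
                 Gamma_se = unname(fit$se[["Gamma"]]),
                 beta_se = unname(fit$se[["beta"]]),
                 chi2_red = fit$chi2_red, decay_captured = decay_captured,
                 residuals = resid),
            class = "g2_fit")
}

#' Translational diffusion coefficient from decay rates versus q^2
#'
#' Weighted zero-intercept regression Gamma = D q^2 over >= 3 angles; the
#' slope is converted from Angstrom^2/s to Angstrom^2/ns.  A free-intercept
#' check is run alongside: an intercept significant at 3 sigma triggers a
#' "non-diffusive component" warning.
#'
#' @param Gamma decay rates (1/s), one per angle
#' @param q momentum transfers (1/Angstrom)
#' @param Gamma_err uncertainties on Gamma; equal weights if omitted
#' @return a `dls_D_fit` list: `D_t` (Angstrom^2/ns), `D_t_se`, and the
#'   intercept diagnostics
#' @export
fit_D_from_gamma <- function(Gamma, q, Gamma_err = NULL) {
  if (length(Gamma) < 3L)
    stop("need >= 3 angles for the Gamma versus q^2 regression")
  stopifnot(length(q) == length(Gamma), all(Gamma > 0))
  if (is.null(Gamma_err) || !all(is.finite(Gamma_err)) || !all(Gamma_err > 0))
    Gamma_err <- rep(1, length(Gamma))
  w <- 1 / Gamma_err^2
  x <- q^2
  slope <- sum(w * x * Gamma) / sum(w * x^2)          # Angstrom^2/s
  slope_se <- sqrt(1 / sum(w * x^2))
  fit_i <- stats::lm(Gamma ~ x, weights = w)
  ic <- suppressWarnings(summary(fit_i))$coefficients
  intercept <- ic[1, 1]; intercept_se <- ic[1, 2]
  if (is.finite(intercept_se) && intercept_se > 0 &&
      abs(intercept) > 3 * intercept_se &&
      abs(intercept) > 1e-6 * max(Gamma))
    warning("non-diffusive component: Gamma versus q^2 intercept is ",
            signif(intercept, 3), " (", signif(abs(intercept) / intercept_se, 3),
            " sigma from zero)")
  structure(list(D_t = slope / 1e9, D_t_se = slope_se / 1e9,
                 intercept = intercept, intercept_se = intercept_se),
            class = "dls_D_fit")
}

#' Dilute-limit diffusion coefficient from a concentration series
#'
#' Weighted linear fit D_t(c) = D0 (1 + k_D c).  When the fitted slope is
#' not significant at 1 sigma the weighted mean is returned as D0 instead
#' and the result is flagged "averaged".
#'
#' @param D_t diffusion coefficients (Angstrom^2/ns), one per concentration
#' @param concentrations concentrations (mg/mL), >= 2
#' @param D_t_err uncertainties; equal weights if omitted
#' @return a `dilute_fit` list: `D0`, `D0_se`, `k_D` (mL/mg), `k_D_se`
#'   and `averaged`
#' @export
extrapolate_dilute <- function(D_t, concentrations, D_t_err = NULL) {
  stopifnot(length(D_t) == length(concentrations))
  if (length(concentrations) < 2L) stop("need >= 2 concentrations")
  if (is.null(D_t_err) || !all(is.finite(D_t_err)) || !all(D_t_err > 0))
    D_t_err <- rep(1, length(D_t))
  w <- 1 / D_t_err^2
  fit <- stats::lm(D_t ~ concentrations, weights = w)
  co <- summary(fit)$coefficients
  slope <- co[2, 1]; slope_se <- co[2, 2]
  averaged <- !is.finite(slope_se) || abs(slope) < slope_se
  if (averaged) {
    D0 <- sum(w * D_t) / sum(w)
    D0_se <- sqrt(1 / sum(w))
    k_D <- 0; k_D_se <- NA_real_
  } else {
    D0 <- co[1, 1]; D0_se <- co[1, 2]
    k_D <- slope / D0
    k_D_se <- abs(k_D) * sqrt((slope_se / slope)^2 + (D0_se / D0)^2)
  }
  structure(list(D0 = D0, D0_se = D0_se, k_D = k_D, k_D_se = k_D_se,
                 averaged = averaged),
            class = "dilute_fit")
}

#' Full DLS analysis chain
#'
#' Fits every correlogram of a dataset, regresses the decay rates on q^2
#' per concentration, extrapolates to infinite dilution and converts the
#' result to a hydrodynamic radius.
#'
#' @param dataset a `dls_dataset` (see [simulate_dls()] / [read_dls()])
#' @param eta solvent viscosity (Pa s) for the Stokes-Einstein conversion;
#'   default the pure-D2O value at the dataset temperature
#' @return a `dls_result` list: per-curve table `decays`, per-concentration
#'   table `by_concentration`, `dilute` ([extrapolate_dilute()] result) and
#'   `R_h` (nm) with `R_h_se`
#' @export
fit_dls <- function(dataset, eta = viscosity_of(dataset$temperature)) {
  stopifnot(inherits(dataset, "dls_dataset"))
  curves <- split(dataset$curves,
                  interaction(dataset$curves$angle,
                              dataset$curves$concentration, drop = TRUE))
  decays <- do.call(rbind, lapply(curves, function(cv) {
    g <- fit_g2(cv$tau_s, cv$g2, cv$error)
    data.frame(angle = cv$angle[1], concentration = cv$concentration[1],
               q = q_from_angle(cv$angle[1], dataset$refractive_index,
                                dataset$wavelength),
               Gamma = g$Gamma, Gamma_se = g$Gamma_se, beta = g$beta)
  }))
  rownames(decays) <- NULL
  by_conc <- do.call(rbind, lapply(split(decays, decays$concentration),
                                   function(dd) {
    f <- fit_D_from_gamma(dd$Gamma, dd$q, dd$Gamma_se)
    data.frame(concentration = dd$concentration[1],
               D_t = f$D_t, D_t_se = f$D_t_se)
  }))
  rownames(by_conc) <- NULL
  dil <- if (nrow(by_conc) >= 2L) {
    extrapolate_dilute(by_conc$D_t, by_conc$concentration, by_conc$D_t_se)
  } else {
    # single concentration: no extrapolation possible, report as-is
    structure(list(D0 = by_conc$D_t[1], D0_se = by_conc$D_t_se[1],
                   k_D = 0, k_D_se = NA_real_, averaged = TRUE),
              class = "dilute_fit")
  }
  R_h <- stokes_einstein_radius(dil$D0, dataset$temperature, eta)
  structure(list(decays = decays, by_concentration = by_conc,
                 dilute = dil, eta = eta,
                 temperature = dataset$temperature,
                 R_h = R_h, R_h_se = R_h * dil$D0_se / dil$D0),
            class = "dls_result")
}

#' @export
print.dls_result <- function(x, ...) {
  cat(sprintf("DLS: D0 = %.4g +/- %.2g A^2/ns (%s), R_h = %.3g nm at %g K\n",
              x$dilute$D0, x$dilute$D0_se,
              if (x$dilute$averaged) "averaged" else
                sprintf("k_D = %.3g mL/mg", x$dilute$k_D),
              x$R_h, x$temperature))
  invisible(x)
}
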