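# Hydrodynamic interpretation of fitted diffusion coefficients:
# Stokes-Einstein conversions, crowding corrections for effective hard
# spheres, rotation-translation combination for rigid spheres and
# cluster-size inversion.

# anchor viscosity table for D2O (Pa s)
.eta_anchors <- data.frame(T = c(280, 295, 310),
                           eta = c(1.830e-3, 1.175e-3, 0.830e-3))

#' D2O solvent viscosity
#'
#' Returns the solvent viscosity at the anchor temperatures 280, 295 and
#' 310 K (1.830e-3, 1.175e-3, 0.830e-3 Pa s) with log-linear interpolation
#' in between; no extrapolation outside [280, 310] K.  The
#' "ligand-adjusted" mode multiplies by a factor (default 1.08) accounting
#' for the viscosity increase from dissolved small-molecule ligand.
#'
#' @param T temperature (K), within [280, 310]
#' @param mode "pure-D2O" or "ligand-adjusted"
#' @param ligand_factor multiplicative viscosity factor for the
#'   ligand-adjusted mode
#' @return viscosity (Pa s)
#' @export
viscosity_of <- function(T, mode = c("pure-D2O", "ligand-adjusted"),
                         ligand_factor = 1.08) {
  mode <- match.arg(mode)
  if (!is.finite(T) || T < 280 || T > 310)
    stop("temperature must lie within [280, 310] K (no extrapolation ",
         "outside the anchor table)")
  eta <- exp(stats::approx(.eta_anchors$T, log(.eta_anchors$eta),
                           xout = T)$y)
  if (mode == "ligand-adjusted") eta <- eta * ligand_factor
  eta
}

# unit bridge: D in Angstrom^2/ns vs SI.  1 m^2/s = 1e11 A^2/ns.
.D_SI_to_A2ns <- 1e11

#' Hydrodynamic radius from a diffusion coefficient (Stokes-Einstein)
#'
#' R_h = k_B T / (6 pi eta D).
#'
#' @param D translational diffusion coefficient (Angstrom^2/ns), > 0
#' @param T temperature (K), > 0
#' @param eta solvent viscosity (Pa s), > 0
#' @return hydrodynamic radius (nm)
#' @export
stokes_einstein_radius <- function(D, T, eta) {
  stopifnot(all(D > 0), all(T > 0), all(eta > 0))
  .kB * T / (6 * pi * eta * (D / .D_SI_to_A2ns)) * 1e9
}

#' Diffusion coefficient from a hydrodynamic radius (Stokes-Einstein)
#'
#' D_t = k_B T / (6 pi eta R_h); exact inverse of
#' [stokes_einstein_radius()].
#'
#' @param R_h hydrodynamic radius (nm), > 0
#' @param T temperature (K), > 0
#' @param eta solvent viscosity (Pa s), > 0
#' @return translational diffusion coefficient (Angstrom^2/ns)
#' @export
stokes_einstein_D <- function(R_h, T, eta) {
  stopifnot(all(R_h > 0), all(T > 0), all(eta > 0))
  .kB * T / (6 * pi * eta * (R_h * 1e-9)) * .D_SI_to_A2ns
}

#' Rotational diffusion coefficient of a sphere (Stokes-Einstein-Debye)
#'
#' D_r = k_B T / (8 pi eta R^3).
#'
#' @param R_h sphere radius (nm), > 0
#' @inheritParams stokes_einstein_D
#' @return rotational diffusion coefficient (1/ns)
#' @export
stokes_einstein_Dr <- function(R_h, T, eta) {
  stopifnot(all(R_h > 0), all(T > 0), all(eta > 0))
  .kB * T / (8 * pi * eta * (R_h * 1e-9)^3) / 1e9
}

#' Effective hard-sphere volume fraction
#'
#' phi_t = phi (R_h / R_dry)^3: the dry volume fraction rescaled by the
#' hydrodynamic envelope.
#'
#' @param phi dry volume fraction
#' @param R_h hydrodynamic radius (any unit shared with `R_dry`)
#' @param R_dry dry protein radius, with R_h >= R_dry > 0
#' @return effective volume fraction
#' @export
effective_volume_fraction <- function(phi, R_h, R_dry) {
  stopifnot(phi >= 0, R_dry > 0)
  if (R_h < R_dry) stop("R_h must be >= R_dry")
  phi * (R_h / R_dry)^3
}

#' Short-time hard-sphere crowding factors
#'
#' Ratios of the short-time self-diffusion of colloidal hard spheres at
#' volume fraction `phi_t` to the dilute limit: translational
#' f_t = 1 - 1.8315 phi (1 + 0.12 phi - 0.70 phi^2) and rotational
#' f_r = 1 - 0.631 phi - 0.726 phi^2 (second-order virial forms from the
#' colloid literature).  Both are clipped below at 0.01 with a warning.
#'
#' @param phi_t effective hard-sphere volume fraction, in [0, 0.55]
#' @return list with elements `f_t` and `f_r`
#' @export
hs_short_time_factors <- function(phi_t) {
  if (!is.finite(phi_t) || phi_t < 0 || phi_t > 0.55)
    stop("phi_t must lie in [0, 0.55]")
  f_t <- 1 - 1.8315 * phi_t * (1 + 0.12 * phi_t - 0.70 * phi_t^2)
  f_r <- 1 - 0.631 * phi_t - 0.726 * phi_t^2
  if (f_t < 0.01 || f_r < 0.01) {
    warning("hard-sphere factor clipped at 0.01")
    f_t <- max(f_t, 0.01); f_r <- max(f_r, 0.01)
  }
  list(f_t = f_t, f_r = f_r)
}

# spherical Bessel j_l via half-integer Bessel J
.sph_jl <- function(l, x) {
  out <- numeric(length(x))
  small <- x < 1e-8
  out[small] <- if (l == 0) 1 else 0
  xb <- x[!small]
  if (length(xb))
    out[!small] <- suppressWarnings(sqrt(pi / (2 * xb)) * besselJ(xb, l + 0.5))
  out[!is.finite(out)] <- 0          # deep underflow at l >> x
  out
}

#' Rigid-sphere rotational mode weights
#'
#' Weights of the rotational modes l in the incoherent intermediate
#' scattering function of hydrogen uniformly distributed in a rigid
#' sphere of radius R, at x = qR:
#' B_l(x) = 3 (2l + 1) \\int_0^1 j_l(x u)^2 u^2 du.  The weights sum to 1
#' (completeness of the Rayleigh expansion); only B_0 survives at x = 0.
#'
#' @param x qR, dimensionless, >= 0
#' @param l_max highest mode; chosen automatically (tail < `tol`) if NULL
#' @param tol tail tolerance for the automatic truncation
#' @return numeric vector B_0 ... B_lmax
#' @export
sphere_mode_weights <- function(x, l_max = NULL, tol = 1e-8) {
  stopifnot(length(x) == 1L, x >= 0)
  if (x == 0) return(1)
  Bl <- function(l) 3 * (2 * l + 1) *
    stats::integrate(function(u) .sph_jl(l, x * u)^2 * u^2, 0, 1,
                     rel.tol = 1e-10, abs.tol = 1e-14)$value
  auto <- is.null(l_max)
  if (auto) l_max <- max(8L, ceiling(x) + 12L)
  B <- vapply(0:l_max, Bl, numeric(1))
  if (auto) {
    while (1 - sum(B) > tol && l_max < 256L) {
      add <- (l_max + 1L):(l_max + 8L)
      B <- c(B, vapply(add, Bl, numeric(1)))
      l_max <- l_max + 8L
    }
  }
  if (1 - sum(B) > tol)
    stop("mode expansion tail ", format(1 - sum(B)),
         " exceeds tolerance at l_max = ", l_max,
         "; request a larger l_max")
  B
}

#' Apparent diffusion coefficient of a rigid sphere from QENS
#'
#' First cumulant of the incoherent intermediate scattering function of a
#' rigid sphere with translational diffusion `D_t` and rotational
#' diffusion `D_r`, divided by q^2:
#' D_app(q) = D_t + (1/q^2) sum_l B_l(qR) l (l + 1) D_r.
#'
#' For hydrogen uniformly filling the sphere the mode sum has the closed
#' form sum_l B_l(x) l (l + 1) = 2 x^2 / 5, so the rotational
#' contribution is the constant (2/5) R^2 D_r at every q > 0 (it does
#' not vanish as q -> 0: B_l -> 0 for l > 0 exactly as fast as 1/q^2
#' diverges).  D_app reduces to D_t only for D_r = 0.  The expansion is
#' summed explicitly up to x = 30 (and checked against the identity in
#' the test suite); the closed form is used beyond.
#'
#' @param D_t translational diffusion coefficient (Angstrom^2/ns), > 0
#' @param D_r rotational diffusion coefficient (1/ns), >= 0
#' @param R sphere radius (nm), > 0
#' @param q momentum transfer (1/Angstrom), vectorised, > 0
#' @return apparent diffusion coefficients (Angstrom^2/ns)
#' @export
apparent_diffusion_sphere <- function(D_t, D_r, R, q) {
  stopifnot(D_t > 0, D_r >= 0, R > 0, all(q > 0))
  if (D_r == 0) return(rep(D_t, length(q)))
  R_A <- R * 10                      # nm -> Angstrom
  vapply(q, function(qi) {
    x <- qi * R_A
    mode_sum <- if (x <= 30) {
      B <- sphere_mode_weights(x)
      l <- seq_along(B) - 1
      sum(B * l * (l + 1))
    } else 2 * x^2 / 5
    D_t + mode_sum * D_r / qi^2
  }, numeric(1))
}

#' Hydrodynamic context
#'
#' Bundles the constants the crowding and cluster models need.
#'
#' @param temperature temperature (K)
#' @param eta solvent viscosity (Pa s); computed from [viscosity_of()]
#'   with `viscosity_mode` if omitted
#' @param viscosity_mode passed to [viscosity_of()]
#' @param phi dry protein volume fraction
#' @param R_h hydrodynamic radius of the tetramer (nm)
#' @param R_dry dry protein radius (nm); enables phi_t = phi (R_h/R_dry)^3
#' @param phi_t effective volume fraction; computed from `R_dry` if omitted
#' @return a `hydro_context` list
#' @export
hydro_context <- function(temperature, eta = NULL,
                          viscosity_mode = "pure-D2O", phi = 0.09,
                          R_h = 2.96, R_dry = NULL, phi_t = NULL) {
  if (is.null(eta)) eta <- viscosity_of(temperature, viscosity_mode)
  stopifnot(temperature > 0, eta > 0, phi >= 0, phi < 1)
  if (is.null(phi_t))
    phi_t <- if (!is.null(R_dry)) effective_volume_fraction(phi, R_h, R_dry)
             else phi
  structure(list(temperature = temperature, eta = eta, phi = phi,
                 R_h = R_h, R_dry = R_dry, phi_t = phi_t),
            class = "hydro_context")
}

#' Cluster size from an observed apparent diffusion coefficient
#'
#' Inverts the compact-sphere cluster model: a cluster of N tetramers is a
#' sphere of radius R_N = R_h N^(1/3) whose translational and rotational
#' diffusion are the Stokes-Einstein(-Debye) values reduced by the
#' short-time hard-sphere factors at the context's phi_t.  The predicted
#' QENS observable is the q-average of [apparent_diffusion_sphere()] over
#' `q_range`; N is found by monotone bisection so that this prediction
#' matches `D_obs`.  If `D_obs` exceeds the single-tetramer prediction the
#' function returns N = 1 with a warning (no sub-tetramer clusters).
#'
#' @param D_obs observed apparent diffusion coefficient (Angstrom^2/ns)
#' @param R_h_tetramer hydrodynamic radius of one tetramer (nm)
#' @param context a [hydro_context()]
#' @param q_range momentum transfers averaged over (1/Angstrom); default
#'   the backscattering q grid 0.2-1.9
#' @param N_max upper bracket for the search
#' @return a `cluster_estimate` list: `N` (tetramers per cluster),
#'   `radius_nm`, `D_pred` and `residual`
#' @export
estimate_cluster_size <- function(D_obs, R_h_tetramer, context,
                                  q_range = seq(0.2, 1.9, length.out = 16L),
                                  N_max = 1e4) {
  stopifnot(D_obs > 0, inherits(context, "hydro_context"))
  f <- hs_short_time_factors(context$phi_t)
  predict_D <- function(N) {
    R_N <- R_h_tetramer * N^(1 / 3)
    D_t <- f$f_t * stokes_einstein_D(R_N, context$temperature, context$eta)
    D_r <- f$f_r * stokes_einstein_Dr(R_N, context$temperature, context$eta)
    mean(apparent_diffusion_sphere(D_t, D_r, R_N, q_range))
  }
  D1 <- predict_D(1)
  if (D_obs >= D1) {
    if (D_obs > D1 * (1 + 1e-10))
      warning("observed D exceeds the single-tetramer prediction; ",
              "returning N = 1")
    return(structure(list(N = 1, radius_nm = R_h_tetramer, D_pred = D1,
                          residual = D_obs - D1), class = "cluster_estimate"))
  }
  lo <- 1; hi <- 2
  while (predict_D(hi) > D_obs && hi < N_max) { lo <- hi; hi <- hi * 2 }
  if (hi >= N_max && predict_D(hi) > D_obs)
    stop("no cluster size up to N_max matches the observed D")
  root <- stats::uniroot(function(N) predict_D(N) - D_obs, c(lo, hi),
                         tol = 1e-8)
  N <- root$root
  structure(list(N = N, radius_nm = R_h_tetramer * N^(1 / 3),
                 D_pred = predict_D(N), residual = root$f.root),
            class = "cluster_estimate")
}

#' @export
print.cluster_estimate <- function(x, ...) {
  cat(sprintf("Cluster estimate: N = %.3g tetramers (radius %.3g nm), predicted D = %.4g A^2/ns\n",
              x$N, x$radius_nm, x$D_pred))
  invisible(x)
}
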