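# Elastic incoherent structure factor (EISF) models: three-site methyl
# jumps and diffusion confined to a sphere, combined with an immobile
# fraction.

# spherical Bessel functions of order 0 and 1 with series limits at 0
.sph_j0 <- function(x) ifelse(abs(x) < 1e-6, 1 - x^2 / 6, sin(x) / ifelse(x == 0, 1, x))
.sph_j1 <- function(x) {
  small <- abs(x) < 1e-4
  out <- numeric(length(x))
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 30
  xl <- x[!small]
  out[!small] <- sin(xl) / xl^2 - cos(xl) / xl
  out
}

#' EISF of three-site methyl jumps
#'
#' A3(q) = (1/3) (1 + 2 j0(q d)) for reorientational jumps between three
#' equivalent sites a distance `d` apart (methyl group protons); A3(0) = 1
#' and A3 -> 1/3 at large q.
#'
#' @param q momentum transfer (1/Angstrom), vectorised
#' @param d jump distance (Angstrom), > 0; default the methyl proton
#'   jump distance 1.715 Angstrom
#' @return dimensionless EISF values
#' @export
eisf_a3jump <- function(q, d = 1.715) {
  stopifnot(d > 0)
  (1 + 2 * .sph_j0(q * d)) / 3
}

#' EISF of diffusion in or on a sphere
#'
#' Default `model = "volino"`: the confined-diffusion-in-a-sphere form
#' [3 j1(qR) / (qR)]^2 (Volino-Dianoux).  `model = "surface"` selects the
#' surface-of-a-sphere form [j0(qR)]^2.  Both equal 1 at q = 0.
#'
#' @param q momentum transfer (1/Angstrom), vectorised
#' @param R sphere radius (Angstrom), > 0
#' @param model "volino" or "surface"
#' @return dimensionless EISF values
#' @export
eisf_sphere <- function(q, R, model = c("volino", "surface")) {
  stopifnot(R > 0)
  model <- match.arg(model)
  x <- q * R
  if (model == "volino") {
    small <- abs(x) < 1e-4
    out <- numeric(length(x))
    out[small] <- (1 - x[small]^2 / 10)^2
    out[!small] <- (3 * .sph_j1(x[!small]) / x[!small])^2
    out
  } else {
    .sph_j0(x)^2
  }
}

#' Composite EISF model
#'
#' A0(q) = a + (1 - a) (b A3(q, d) + (1 - b) A_sphere(q, R)): an immobile
#' fraction `a`, a methyl three-site jump contribution with weight `b`,
#' and side-chain diffusion on/in a sphere of radius `R` for the rest.
#'
#' @param q momentum transfer (1/Angstrom)
#' @param a immobile fraction, in [0, 1]
#' @param b methyl-jump weight, in [0, 1]
#' @param R sphere radius (Angstrom)
#' @param d methyl jump distance (Angstrom)
#' @param sphere_model passed to [eisf_sphere()]
#' @return dimensionless EISF values; A0(0) = 1 for any parameters
#' @export
eisf_model <- function(q, a, b, R, d = 1.715, sphere_model = "volino") {
  a + (1 - a) * (b * eisf_a3jump(q, d) + (1 - b) * eisf_sphere(q, R, sphere_model))
}

#' Fit the composite EISF model to extracted A0(q)
#'
#' Weighted box-constrained fit of the composite EISF with a in [0, 1],
#' b in [0, 1] and R in [1, 50] Angstrom; the methyl jump distance `d` is
#' held fixed.  A0 inputs may slightly overshoot 1 (clipped at 1.05 on
#' entry, values above rejected).  Parameters that end on a box edge are
#' flagged unidentifiable.
#'
#' @param A0 extracted EISF values, in [0, 1.05]
#' @param q momentum transfers (1/Angstrom), >= 5 points
#' @param A0_err uncertainties on A0; equal weights if omitted
#' @param d fixed methyl jump distance (Angstrom)
#' @param sphere_model passed to [eisf_sphere()]
#' @return an `eisf_fit` list: `a`, `b`, `R`, `d`, standard errors,
#'   covariance, `unidentifiable` (character vector of flagged
#'   parameters) and the fitted curve function
#' @export
fit_eisf <- function(A0, q, A0_err = NULL, d = 1.715, sphere_model = "volino") {
  keep <- is.finite(A0) & is.finite(q)
  A0 <- A0[keep]; q <- q[keep]
  if (!is.null(A0_err)) A0_err <- A0_err[keep]
  if (length(q) < 5L) stop("EISF fit needs >= 5 usable q points")
  if (any(A0 < 0 | A0 > 1.05))
    stop("A0 values must lie in [0, 1.05]")
  A0 <- pmin(A0, 1)
  if (is.null(A0_err) || !all(is.finite(A0_err)) || !all(A0_err > 0))
    A0_err <- rep(1, length(A0))
  p0 <- c(a = max(min(min(A0), 0.95), 0.05), b = 0.3, R = 8)
  fit <- .wls_fit(p0,
                  function(p) eisf_model(q, p[["a"]], p[["b"]], p[["R"]], d,
                                         sphere_model),
                  A0, A0_err,
                  lower = c(0, 0, 1), upper = c(1, 1, 50))
  unident <- names(fit$par)[fit$at_bound]
  structure(list(a = unname(fit$par[["a"]]), b = unname(fit$par[["b"]]),
                 R = unname(fit$par[["R"]]), d = d,
                 a_se = unname(fit$se[["a"]]), b_se = unname(fit$se[["b"]]),
                 R_se = unname(fit$se[["R"]]),
                 cov = fit$cov, chi2_red = fit$chi2_red,
                 unidentifiable = unident, sphere_model = sphere_model,
                 q = q, A0 = A0,
                 curve = local({
                   pa <- unname(fit$par[["a"]]); pb <- unname(fit$par[["b"]])
                   pR <- unname(fit$par[["R"]]); pd <- d; sm <- sphere_model
                   function(q) eisf_model(q, pa, pb, pR, pd, sm)
                 })),
            class = "eisf_fit")
}

#' @export
print.eisf_fit <- function(x, ...) {
  cat(sprintf("EISF fit (%s sphere): a = %.3f +/- %.2g, b = %.3f +/- %.2g, R = %.3f +/- %.2g A (d = %.3f A fixed)\n",
              x$sphere_model, x$a, x$a_se, x$b, x$b_se, x$R, x$R_se, x$d))
  if (length(x$unidentifiable))
    cat("  unidentifiable (at box edge):",
        paste(x$unidentifiable, collapse = ", "), "\n")
  invisible(x)
}
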