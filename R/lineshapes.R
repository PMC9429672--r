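#' Unit-area Lorentzian density
#'
#' L(omega; hwhm, center) = (1/pi) * hwhm / ((omega - center)^2 + hwhm^2).
#' Integrates to one over the whole real line; on a finite window the
#' truncation loss is 1 - (1/pi) * (atan((b-c)/hwhm) - atan((a-c)/hwhm))
#' for window [a, b] — the heavy tails dominate all quadrature checks.
#'
#' @param omega energy transfer grid (micro-eV)
#' @param hwhm half width at half maximum (micro-eV), > 0
#' @param center line position (micro-eV)
#' @return density values (1/micro-eV)
#' @export
lorentzian <- function(omega, hwhm, center = 0) {
  if (!is.numeric(hwhm) || length(hwhm) != 1L || !is.finite(hwhm) || hwhm <= 0)
    stop("'hwhm' must be a single positive number")
  (hwhm / pi) / ((omega - center)^2 + hwhm^2)
}

#' Unit-area Gaussian density
#'
#' Normal density with standard deviation `sd`; FWHM = 2 sqrt(2 ln 2) sd.
#'
#' @param omega energy transfer grid (micro-eV)
#' @param sd standard deviation (micro-eV), > 0
#' @param center line position (micro-eV)
#' @return density values (1/micro-eV)
#' @export
gaussian <- function(omega, sd, center = 0) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("'sd' must be a single positive number")
  stats::dnorm(omega, mean = center, sd = sd)
}

#' Unit-area Voigt profile
#'
#' Convolution of a Lorentzian (HWHM `lor_hwhm`) with a Gaussian (standard
#' deviation `gauss_sd`), computed from the real part of the Faddeeva
#' function.  Continuous in its limits: `lor_hwhm = 0` gives the Gaussian
#' exactly and `gauss_sd -> 0` approaches the Lorentzian.
#'
#' @param omega energy transfer grid (micro-eV)
#' @param lor_hwhm Lorentzian HWHM (micro-eV), >= 0
#' @param gauss_sd Gaussian standard deviation (micro-eV), > 0
#' @param center line position (micro-eV)
#' @return density values (1/micro-eV)
#' @export
voigt <- function(omega, lor_hwhm, gauss_sd, center = 0) {
  if (!is.numeric(lor_hwhm) || length(lor_hwhm) != 1L || !is.finite(lor_hwhm) ||
      lor_hwhm < 0)
    stop("'lor_hwhm' must be a single non-negative number")
  if (!is.numeric(gauss_sd) || length(gauss_sd) != 1L || !is.finite(gauss_sd) ||
      gauss_sd <= 0) {
    if (is.numeric(gauss_sd) && length(gauss_sd) == 1L && gauss_sd == 0 &&
        lor_hwhm == 0)
      stop("voigt(): both widths zero")
    stop("'gauss_sd' must be a single positive number")
  }
  z <- (omega - center + 1i * lor_hwhm) / (gauss_sd * sqrt(2))
  Re(faddeeva_w(z)) / (gauss_sd * sqrt(2 * pi))
}

#' Spectral component descriptor
#'
#' A model spectrum before resolution convolution is a weighted sum of
#' symbolic components: `delta` (a Dirac line, materialised only through
#' the convolution) and `lorentzian`.
#'
#' @param kind "delta" or "lorentzian"
#' @param weight non-negative area of the component
#' @param hwhm Lorentzian HWHM (micro-eV); ignored for "delta"
#' @param center line position (micro-eV)
#' @return a `spectral_component` list
#' @export
spectral_component <- function(kind = c("delta", "lorentzian"), weight,
                               hwhm = 0, center = 0) {
  kind <- match.arg(kind)
  if (weight < 0) stop("component weight must be >= 0")
  if (kind == "lorentzian" && hwhm <= 0)
    stop("lorentzian component requires hwhm > 0")
  structure(list(kind = kind, weight = weight, hwhm = hwhm, center = center),
            class = "spectral_component")
}

#' Resolution-convolved spectrum model
#'
#' Builds the analytic convolution of a list of spectral components with a
#' sum-of-Gaussians resolution at one q.  A delta convolved with the
#' resolution returns the (weighted) resolution profile itself; a
#' Lorentzian convolved with each resolution Gaussian yields a Voigt
#' profile, so the full model is a weighted sum of Gaussians and Voigts.
#' The returned closure is linear in the component weights.
#'
#' @param components list of [spectral_component()] values (bare lists with
#'   the same fields are accepted)
#' @param resolution_q data frame with columns `weight`, `center`, `sd`
#'   describing the resolution Gaussians at this q (weights sum to 1)
#' @return function(omega) evaluating the convolved model density
#' @export
convolve_model <- function(components, resolution_q) {
  stopifnot(is.data.frame(resolution_q),
            all(c("weight", "center", "sd") %in% names(resolution_q)))
  for (comp in components) {
    if (!comp$kind %in% c("delta", "lorentzian"))
      stop("unknown component kind: ", comp$kind)
    if (comp$weight < 0) stop("component weights must be >= 0")
  }
  force(components); force(resolution_q)
  function(omega) {
    out <- numeric(length(omega))
    for (comp in components) {
      if (comp$weight == 0) next
      for (i in seq_len(nrow(resolution_q))) {
        w <- comp$weight * resolution_q$weight[i]
        ctr <- comp$center + resolution_q$center[i]
        out <- out + if (comp$kind == "delta") {
          w * gaussian(omega, sd = resolution_q$sd[i], center = ctr)
        } else {
          w * voigt(omega, lor_hwhm = comp$hwhm,
                    gauss_sd = resolution_q$sd[i], center = ctr)
        }
      }
    }
    out
  }
}
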