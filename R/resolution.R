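#' Instrument resolution model
#'
#' A per-q description of the instrument energy resolution as a sum of
#' Gaussian components, which closes the convolution of the Lorentzian
#' fit models analytically (Lorentzian x Gaussian = Voigt).  Components
#' may have nonzero centers to emulate instrument asymmetry.
#'
#' @param q momentum-transfer grid (1/Angstrom)
#' @param components list (one element per q) of data frames with columns
#'   `weight` (>= 0, summing to 1 within 1e-9), `center` (micro-eV) and
#'   `sd` (micro-eV, > 0)
#' @return a `resolution_model` object
#' @export
resolution_model <- function(q, components) {
  stopifnot(length(q) == length(components), length(q) >= 1L)
  for (i in seq_along(components)) {
    comp <- components[[i]]
    if (!is.data.frame(comp) || nrow(comp) < 1L ||
        !all(c("weight", "center", "sd") %in% names(comp)))
      stop("each resolution entry needs >= 1 row with weight, center, sd")
    if (any(comp$weight < 0)) stop("resolution weights must be >= 0")
    if (abs(sum(comp$weight) - 1) > 1e-9)
      stop("resolution weights at q = ", q[i], " do not sum to 1")
    if (any(comp$sd <= 0)) stop("resolution sd must be > 0")
  }
  structure(list(q = as.numeric(q), components = components),
            class = "resolution_model")
}

#' Single-Gaussian resolution from an instrument FWHM
#'
#' Convenience constructor: one centred Gaussian per q with the stated
#' full width at half maximum.
#'
#' @param q momentum-transfer grid (1/Angstrom)
#' @param fwhm resolution FWHM (micro-eV), recycled over q
#' @return a `resolution_model`
#' @export
gaussian_resolution <- function(q, fwhm) {
  fwhm <- rep_len(fwhm, length(q))
  comps <- lapply(fwhm, function(f)
    data.frame(weight = 1, center = 0, sd = fwhm_to_sd(f)))
  resolution_model(q, comps)
}

#' Look up the resolution components at one q
#'
#' @param resolution a `resolution_model`
#' @param q momentum transfer to match (within 1e-8 relative)
#' @return the data frame of Gaussian components at that q
#' @export
resolution_at <- function(resolution, q) {
  stopifnot(inherits(resolution, "resolution_model"))
  i <- which(abs(resolution$q - q) <= 1e-8 * max(1, abs(q)))
  if (length(i) != 1L)
    stop("resolution model has no entry for q = ", q)
  resolution$components[[i]]
}

#' @export
print.resolution_model <- function(x, ...) {
  ncomp <- vapply(x$components, nrow, integer(1))
  cat("Resolution model:", length(x$q), "q points,",
      paste(range(ncomp), collapse = "-"), "Gaussian component(s) per q\n")
  invisible(x)
}
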