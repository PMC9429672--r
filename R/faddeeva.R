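# Faddeeva (scaled complex complementary error) function, the workhorse
# behind the Voigt profile: V(x) = Re(w(z)) / (sd * sqrt(2*pi)) with
# z = (x + i*gamma) / (sd*sqrt(2)).

.faddeeva_cache <- new.env(parent = emptyenv())

# Weideman (1994, SIAM J. Numer. Anal. 31, 1497) rational expansion of w(z)
# on the upper half plane.  N = 36 gives ~1e-14 relative accuracy.
.weideman_coef <- function(N = 36L) {
  key <- as.character(N)
  cached <- .faddeeva_cache[[key]]
  if (!is.null(cached)) return(cached)
  M <- 2L * N
  M2 <- 2L * M
  k <- seq.int(-M + 1L, M - 1L)
  L <- sqrt(N / sqrt(2))
  theta <- k * pi / M
  t <- L * tan(theta / 2)
  f <- c(0, exp(-t^2) * (L^2 + t^2))
  n <- length(f)
  half <- ceiling(n / 2)
  fs <- c(f[(half + 1):n], f[1:half])      # fftshift
  a <- Re(stats::fft(fs)) / M2
  out <- list(a = rev(a[2:(N + 1)]), L = L)
  .faddeeva_cache[[key]] <- out
  out
}

#' Faddeeva function w(z)
#'
#' Computes w(z) = exp(-z^2) erfc(-iz) for complex `z` with non-negative
#' imaginary part, by Weideman's rational approximation.  The real part of
#' w evaluated at z = (omega + i*hwhm)/(sd*sqrt(2)) yields the Voigt
#' profile, i.e. the convolution of a Lorentzian with a Gaussian.
#'
#' @param z complex vector, Im(z) >= 0
#' @return complex vector w(z)
#' @seealso [voigt()]
#' @export
faddeeva_w <- function(z) {
  if (any(Im(z) < 0)) stop("faddeeva_w() requires Im(z) >= 0")
  coef <- .weideman_coef()
  L <- coef$L
  Z <- (L + 1i * z) / (L - 1i * z)
  p <- rep(0 + 0i, length(z))
  for (ak in coef$a) p <- p * Z + ak
  2 * p / (L - 1i * z)^2 + (1 / sqrt(pi)) / (L - 1i * z)
}
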