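# Plain-text tabular interchange: long-format CSV with a '#'-prefixed
# metadata header.  Instrument-native formats (NeXus etc.) are upstream
# reduction products and out of scope.

.read_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr_lines) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv
}

#' Write a spectrum set to a long-format CSV
#'
#' Columns `q`, `omega_ueV`, `intensity`, `error`, preceded by a
#' '#'-prefixed metadata header (instrument name, kind, resolution FWHM,
#' sample label, temperature).
#'
#' @param x a [spectrum_set()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_spectrum_set <- function(x, path) {
  stopifnot(inherits(x, "spectrum_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# instrument: ", x$profile$name),
    paste0("# kind: ", x$profile$kind),
    paste0("# fwhm_ueV: ", format(x$profile$fwhm, digits = 15)),
    paste0("# sample: ", x$sample),
    paste0("# temperature_K: ", format(x$temperature, digits = 15)),
    "q,omega_ueV,intensity,error"), con)
  df <- data.frame(
    q = rep(x$q, each = length(x$omega)),
    omega_ueV = rep(x$omega, length(x$q)),
    intensity = as.vector(t(x$intensity)),
    error = as.vector(t(x$error)))
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a spectrum set from a long-format CSV
#'
#' Inverse of [write_spectrum_set()].  The (q, omega) grid must be
#' rectangular; q blocks in non-canonical order are reordered with a
#' warning; a missing or non-positive error column is a parse error
#' naming the offending column or lines.
#'
#' @param path input file
#' @return a [spectrum_set()]
#' @export
read_spectrum_set <- function(path) {
  kv <- .read_header(path)
  for (need in c("kind", "fwhm_ueV", "sample", "temperature_K"))
    if (is.null(kv[[need]]))
      stop("parse error in ", path, ": missing header field '", need, "'")
  df <- utils::read.csv(path, comment.char = "#")
  for (col in c("q", "omega_ueV", "intensity", "error"))
    if (!col %in% names(df))
      stop("parse error in ", path, ": missing column '", col, "'")
  bad <- which(!is.finite(df$error) | df$error <= 0)
  if (length(bad))
    stop("parse error in ", path, ": non-positive or missing errors at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  qs <- unique(df$q)
  if (is.unsorted(qs, strictly = TRUE)) {
    warning("q blocks in ", path, " are not in increasing order; reordering")
    qs <- sort(qs)
  }
  omegas <- sort(unique(df$omega_ueV))
  if (nrow(df) != length(qs) * length(omegas))
    stop("parse error in ", path, ": ragged (q, omega) grid")
  key <- order(match(df$q, qs), match(df$omega_ueV, omegas))
  df <- df[key, ]
  intensity <- matrix(df$intensity, nrow = length(qs), byrow = TRUE)
  error <- matrix(df$error, nrow = length(qs), byrow = TRUE)
  profile <- instrument_profile(
    name = if (!is.null(kv$instrument)) kv$instrument else kv$kind,
    kind = kv$kind, q = qs, omega = omegas,
    fwhm = as.numeric(kv$fwhm_ueV))
  spectrum_set(profile, intensity, error, sample = kv$sample,
               temperature = as.numeric(kv$temperature_K))
}

#' Write a DLS dataset to CSV
#'
#' Columns `angle`, `concentration`, `tau_s`, `g2`, `error` with a
#' metadata header (wavelength, refractive index, temperature).
#'
#' @param x a `dls_dataset`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_dls <- function(x, path) {
  stopifnot(inherits(x, "dls_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# wavelength_nm: ", format(x$wavelength, digits = 15)),
    paste0("# refractive_index: ", format(x$refractive_index, digits = 15)),
    paste0("# temperature_K: ", format(x$temperature, digits = 15)),
    "angle,concentration,tau_s,g2,error"), con)
  utils::write.table(format(x$curves, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a DLS dataset from CSV
#'
#' Inverse of [write_dls()].
#'
#' @param path input file
#' @return a `dls_dataset`
#' @export
read_dls <- function(path) {
  kv <- .read_header(path)
  for (need in c("wavelength_nm", "refractive_index", "temperature_K"))
    if (is.null(kv[[need]]))
      stop("parse error in ", path, ": missing header field '", need, "'")
  df <- utils::read.csv(path, comment.char = "#")
  for (col in c("angle", "concentration", "tau_s", "g2", "error"))
    if (!col %in% names(df))
      stop("parse error in ", path, ": missing column '", col, "'")
  structure(list(curves = df,
                 wavelength = as.numeric(kv$wavelength_nm),
                 refractive_index = as.numeric(kv$refractive_index),
                 temperature = as.numeric(kv$temperature_K)),
            class = "dls_dataset")
}
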