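# End-to-end workflow: solvent -> protein time-of-flight fits ->
# jump-diffusion summary -> backscattering global fit with fixed internal
# dynamics -> EISF fit -> hydrodynamic interpretation, with the DLS chain
# as an independent branch.

.md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

.result_record <- function(stage, table, config_hash, input_hash) {
  stopifnot(all(c("name", "value", "uncertainty", "unit", "fixed") %in%
                  names(table)))
  structure(list(stage = stage, table = table,
                 provenance = list(config_hash = config_hash,
                                   input_hash = input_hash,
                                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "result_record")
}

#' @export
print.result_record <- function(x, ...) {
  cat("Result record [", x$stage, "]\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Run configuration for the full pipeline
#'
#' @param tof_solvent,tof_protein,bs_protein [spectrum_set()] objects or
#'   paths to files readable by [read_spectrum_set()]
#' @param bs_solvent_params data frame with columns `q`, `beta_d2o`,
#'   `gamma_d2o` (the fixed solvent inputs of the backscattering model)
#' @param dls a `dls_dataset` or a path readable by [read_dls()]
#' @param phi dry protein volume fraction
#' @param temperature temperature (K) used in the hydrodynamic stage
#' @param viscosity_mode passed to [viscosity_of()]
#' @param R_h_tetramer,R_dry tetramer hydrodynamic and dry radii (nm)
#' @param d fixed methyl jump distance (Angstrom)
#' @param sphere_model EISF sphere-model variant ("volino" or "surface")
#' @param scale_solvent scale the backscattering solvent amplitude by
#'   (1 - phi)
#' @param Gamma_override optional per-q internal widths (micro-eV) for the
#'   backscattering fit when no time-of-flight data are available
#' @param seed integer seed recorded with the run
#' @return a `run_config` list
#' @export
run_config <- function(tof_solvent = NULL, tof_protein = NULL,
                       bs_protein = NULL, bs_solvent_params = NULL,
                       dls = NULL, phi = 0.09, temperature = 295,
                       viscosity_mode = "pure-D2O", R_h_tetramer = 2.96,
                       R_dry = NULL, d = 1.715, sphere_model = "volino",
                       scale_solvent = TRUE, Gamma_override = NULL,
                       seed = 1L) {
  for (p in list(tof_solvent, tof_protein, bs_protein, dls))
    if (is.character(p) && !file.exists(p))
      stop("input file does not exist: ", p)
  structure(list(tof_solvent = tof_solvent, tof_protein = tof_protein,
                 bs_protein = bs_protein,
                 bs_solvent_params = bs_solvent_params, dls = dls,
                 phi = phi, temperature = temperature,
                 viscosity_mode = viscosity_mode,
                 R_h_tetramer = R_h_tetramer, R_dry = R_dry, d = d,
                 sphere_model = sphere_model, scale_solvent = scale_solvent,
                 Gamma_override = Gamma_override, seed = as.integer(seed)),
            class = "run_config")
}

.load_spectra <- function(x) {
  if (is.null(x)) NULL
  else if (inherits(x, "spectrum_set")) x
  else read_spectrum_set(x)
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: the pure-solvent and protein
#' time-of-flight fits, the jump-diffusion summary of the extracted
#' internal widths, the backscattering global fit (internal dynamics
#' fixed from the jump-diffusion result, or an explicit override), the
#' EISF fit, the hydrodynamic interpretation of the fitted D, and — as an
#' independent branch — the DLS chain.  A failed stage halts its
#' dependents but not independent branches; the backscattering stage
#' refuses to run without either time-of-flight results or an explicit
#' `Gamma_override`, because the internal width must be fixed externally.
#'
#' @param config a [run_config()]
#' @return named list of `result_record`s (and a `summary` record); stages
#'   that could not run carry an `error` attribute
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  config_hash <- .md5_of(config[setdiff(names(config),
                                        c("tof_solvent", "tof_protein",
                                          "bs_protein", "dls"))])
  records <- list()
  tof_solvent <- .load_spectra(config$tof_solvent)
  tof_protein <- .load_spectra(config$tof_protein)
  bs_protein <- .load_spectra(config$bs_protein)

  solvent_fit <- NULL; tof_fit <- NULL; jd <- NULL
  if (!is.null(tof_solvent)) {
    res <- profile_resolution(tof_solvent$profile)
    solvent_fit <- fit_solvent(tof_solvent, res)
    records$tof_solvent <- .result_record(
      "tof_solvent",
      data.frame(name = c("sigma1_mean", "sigma2_mean"),
                 value = c(mean(solvent_fit$sigma1), mean(solvent_fit$sigma2)),
                 uncertainty = c(mean(solvent_fit$sigma1_se),
                                 mean(solvent_fit$sigma2_se)),
                 unit = "ueV", fixed = FALSE),
      config_hash, .md5_of(tof_solvent))
    attr(records$tof_solvent, "per_q") <- solvent_fit
  }
  if (!is.null(tof_protein) && !is.null(solvent_fit)) {
    res <- profile_resolution(tof_protein$profile)
    tof_fit <- fit_protein_tof(tof_protein, res, solvent_fit, config$phi)
    jd <- fit_jump_diffusion(tof_fit$gamma_in5, tof_fit$q,
                             tof_fit$gamma_in5_se)
    records$jump_diffusion <- .result_record(
      "jump_diffusion",
      data.frame(name = c("D_i", "tau"),
                 value = c(jd$D_i, jd$tau),
                 uncertainty = c(jd$D_i_se, jd$tau_se),
                 unit = c("A^2/ns", "ns"), fixed = FALSE),
      config_hash, .md5_of(tof_protein))
    attr(records$jump_diffusion, "per_q") <- tof_fit
    attr(records$jump_diffusion, "fit") <- jd
  }

  gf <- NULL; ef <- NULL
  if (!is.null(bs_protein)) {
    if (is.null(jd) && is.null(config$Gamma_override)) {
      records$backscattering <- structure(list(stage = "backscattering"),
        class = "result_record",
        error = paste("backscattering fit requires the internal linewidth",
                      "to be fixed externally: provide time-of-flight data",
                      "or an explicit Gamma_override"))
    } else if (is.null(config$bs_solvent_params)) {
      records$backscattering <- structure(list(stage = "backscattering"),
        class = "result_record",
        error = "bs_solvent_params (fixed solvent inputs) are required")
    } else {
      res <- profile_resolution(bs_protein$profile)
      gf <- global_fit(bs_protein, res, config$bs_solvent_params,
                       internal = jd, phi = config$phi,
                       scale_solvent = config$scale_solvent,
                       Gamma_override = config$Gamma_override)
      records$backscattering <- .result_record(
        "backscattering",
        data.frame(name = "D", value = gf$D, uncertainty = gf$D_se,
                   unit = "A^2/ns", fixed = FALSE),
        config_hash, .md5_of(bs_protein))
      attr(records$backscattering, "fit") <- gf
      ef <- fit_eisf(gf$per_q$A0, gf$per_q$q, gf$per_q$A0_se,
                     d = config$d, sphere_model = config$sphere_model)
      records$eisf <- .result_record(
        "eisf",
        data.frame(name = c("a", "b", "R", "d"),
                   value = c(ef$a, ef$b, ef$R, ef$d),
                   uncertainty = c(ef$a_se, ef$b_se, ef$R_se, 0),
                   unit = c("", "", "A", "A"),
                   fixed = c(FALSE, FALSE, FALSE, TRUE)),
        config_hash, .md5_of(bs_protein))
      attr(records$eisf, "fit") <- ef

      eta <- viscosity_of(config$temperature, config$viscosity_mode)
      Rh_app <- stokes_einstein_radius(gf$D, config$temperature, eta)
      ctx <- hydro_context(config$temperature, eta = eta, phi = config$phi,
                           R_h = config$R_h_tetramer, R_dry = config$R_dry)
      cl <- estimate_cluster_size(gf$D, config$R_h_tetramer, ctx,
                                  q_range = bs_protein$q)
      records$hydrodynamics <- .result_record(
        "hydrodynamics",
        data.frame(name = c("eta", "R_h_apparent", "phi_t", "cluster_N"),
                   value = c(eta, Rh_app, ctx$phi_t, cl$N),
                   uncertainty = NA_real_,
                   unit = c("Pa s", "nm", "", "tetramers"),
                   fixed = c(TRUE, FALSE, TRUE, FALSE)),
        config_hash, .md5_of(bs_protein))
      attr(records$hydrodynamics, "cluster") <- cl
    }
  }

  if (!is.null(config$dls)) {
    dls <- if (inherits(config$dls, "dls_dataset")) config$dls
           else read_dls(config$dls)
    dr <- tryCatch(fit_dls(dls), error = function(e) e)
    if (inherits(dr, "error")) {
      records$dls <- structure(list(stage = "dls"), class = "result_record",
                               error = conditionMessage(dr))
    } else {
      records$dls <- .result_record(
        "dls",
        data.frame(name = c("D0", "k_D", "R_h"),
                   value = c(dr$dilute$D0, dr$dilute$k_D, dr$R_h),
                   uncertainty = c(dr$dilute$D0_se, dr$dilute$k_D_se,
                                   dr$R_h_se),
                   unit = c("A^2/ns", "mL/mg", "nm"), fixed = FALSE),
        config_hash, .md5_of(dls))
      attr(records$dls, "fit") <- dr
    }
  }

  summary_rows <- do.call(rbind, lapply(records, function(r) {
    if (!is.null(attr(r, "error")) || is.null(r$table)) return(NULL)
    cbind(stage = r$stage, r$table)
  }))
  records$summary <- .result_record(
    "summary",
    if (is.null(summary_rows))
      data.frame(name = character(), value = numeric(),
                 uncertainty = numeric(), unit = character(),
                 fixed = logical())
    else summary_rows[, c("name", "value", "uncertainty", "unit", "fixed")],
    config_hash, config_hash)
  attr(records$summary, "stages") <- names(records)
  records
}
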