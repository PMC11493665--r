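## Serialization: YAML parameter files with explicit unit suffixes, tidy
## CSV exports for curves and trajectories, JSON steady-state records.

.PARAM_KEYS <- c(
  kon_tcr = "kon_tcr_per_nM_per_s", koff_tcr = "koff_tcr_per_s",
  kon_taa = "kon_taa_per_nM_per_s", koff_taa = "koff_taa_per_s",
  kd_tcr = "kd_tcr_nM", kd_taa = "kd_taa_nM",
  ksyn_tcr = "ksyn_tcr_nM_per_s", kdeg_tcr = "kdeg_tcr_per_s",
  ksyn_taa = "ksyn_taa_nM_per_s", kdeg_taa = "kdeg_taa_per_s",
  kint_tcr_dimer = "kint_tcr_dimer_per_s",
  kint_taa_dimer = "kint_taa_dimer_per_s",
  kint_trimer = "kint_trimer_per_s",
  baseline_tcr = "baseline_tcr_nM", baseline_taa = "baseline_taa_nM")

#' Write an engagement parameter set to YAML
#'
#' One key per rate constant with an explicit unit suffix
#' (e.g. `kon_tcr_per_nM_per_s`), plus a `schema` version.  The file
#' round-trips through [read_engagement_params()].
#'
#' @param params [engagement_params()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_engagement_params <- function(params, path) {
  .validate_params(params)
  rec <- c(list(schema = 1L),
           setNames(lapply(names(.PARAM_KEYS), function(k) params[[k]]),
                    .PARAM_KEYS))
  yaml::write_yaml(rec, path, precision = 17L)
  invisible(path)
}

#' Read an engagement parameter set from YAML
#'
#' @param path File written by [write_engagement_params()].
#' @return [engagement_params()].
#' @export
read_engagement_params <- function(path) {
  rec <- yaml::read_yaml(path)
  missing <- setdiff(unname(.PARAM_KEYS), names(rec))
  if (length(missing))
    .stopf("parameter file %s is missing key(s): %s", path,
           paste(missing, collapse = ", "))
  v <- setNames(lapply(names(.PARAM_KEYS), function(k) rec[[.PARAM_KEYS[[k]]]]),
                names(.PARAM_KEYS))
  p <- engagement_params(
    kd_tcr = v$kd_tcr, kd_taa = v$kd_taa,
    kon_tcr = v$kon_tcr, kon_taa = v$kon_taa,
    kdeg_tcr = v$kdeg_tcr, kdeg_taa = v$kdeg_taa,
    kint_tcr_dimer = v$kint_tcr_dimer, kint_taa_dimer = v$kint_taa_dimer,
    kint_trimer = v$kint_trimer,
    baseline_tcr = v$baseline_tcr, baseline_taa = v$baseline_taa,
    koff_tcr = v$koff_tcr, koff_taa = v$koff_taa)
  for (k in c("ksyn_tcr", "ksyn_taa")) {
    if (abs(p[[k]] - v[[k]]) > 1e-9 * max(p[[k]], v[[k]]))
      warning(sprintf(
        "%s in %s is inconsistent with kdeg * baseline; using the derived value",
        .PARAM_KEYS[[k]], path))
  }
  p
}

## md5 of the serialized parameter set (identifies a run's inputs in logs)
.params_hash <- function(params) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp), add = TRUE)
  write_engagement_params(params, tmp)
  unname(tools::md5sum(tmp))
}

#' Export a dose-response curve to tidy CSV
#'
#' Columns `dose_nM`, `trimer_nM`, `dimer_tcr_nM`, `dimer_taa_nM`;
#' re-importable with [read_curve_csv()].
#'
#' @param curve A `dose_response_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "dose_response_curve"))
  df <- data.frame(dose_nM = curve$dose, trimer_nM = curve$trimer,
                   dimer_tcr_nM = curve$dimer_tcr,
                   dimer_taa_nM = curve$dimer_taa)
  write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- read.csv(path)
  need <- c("dose_nM", "trimer_nM", "dimer_tcr_nM", "dimer_taa_nM")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .stopf("curve file %s is missing column(s): %s", path,
           paste(missing, collapse = ", "))
  structure(data.frame(dose = df$dose_nM, trimer = df$trimer_nM,
                       dimer_tcr = df$dimer_tcr_nM,
                       dimer_taa = df$dimer_taa_nM),
            class = c("dose_response_curve", "data.frame"))
}

#' Export a trajectory to tidy CSV
#'
#' Long format: `time_s`, `species`, `concentration_nM`, `dose_nM`,
#' `exposure_mode`.
#'
#' @param trajectory An `engagement_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "engagement_trajectory"))
  write.csv(as.data.frame(trajectory), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a steady-state result to JSON
#'
#' Record with the parameter-set hash, dose, per-species concentrations,
#' solver residual and method.
#'
#' @param result A `steady_state_result`.
#' @param params The generating [engagement_params()].
#' @param dose Clamped dose, nM.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_steady_state_json <- function(result, params, dose, path) {
  stopifnot(inherits(result, "steady_state_result"))
  rec <- list(schema = 1L,
              params_md5 = .params_hash(params),
              dialect = if (isTRUE(params$consistent)) "consistent"
                        else "as-printed",
              dose_nM = dose,
              method = result$method,
              converged = result$converged,
              residual_nM_per_s = result$residual,
              concentrations_nM = as.list(result$state))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a perturbation-ensemble summary to CSV
#'
#' One row per draw: per-parameter factors, peak statistics and the
#' shape-retained flag.
#'
#' @param ensemble A `perturbation_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "perturbation_ensemble"))
  df <- ensemble$summary
  names(df)[names(df) == "peak_trimer"] <- "peak_trimer_nM"
  names(df)[names(df) == "peak_dose"] <- "peak_dose_nM"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
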