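## Run configuration: YAML/JSON loading with validation, defaults traceable
## to the shipped parameter files, and unit conversion helpers.

config_keys <- c("study", "subject", "physiology", "parameter_overrides",
                 "drug_parameter_overrides", "scenario", "doses", "horizon",
                 "dt", "solver", "aldosterone_drive", "out_dir", "seed")

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, applies defaults from the shipped
#' parameter files, and validates keys (unknown keys are rejected with the
#' nearest valid candidate named). The resulting object carries everything
#' needed to assemble and run a scenario.
#'
#' Recognized keys: `study` (label into [study_table()]), `subject` (explicit
#' [subject_params()] fields), `physiology` (path to an alternative
#' physiology CSV), `parameter_overrides` / `drug_parameter_overrides`
#' (dotted paths into [raas_params()] / [drug_params()]), `scenario` (one of
#' `steady_state`, `oral_ena`, `iv_enaat`, `custom`), `doses` (list of
#' `{time, amount_mg, route, compound}` records for `custom`), `horizon`,
#' `dt`, `solver` (`rtol`, `atol`), `aldosterone_drive`, `out_dir`, `seed`.
#'
#' @param path file path, or NULL for pure defaults
#' @return object of class `run_config`
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop_config("config file not found: ", path)
    if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  raw <- raw %||% list()
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown))
    stop_config("unknown config key '", unknown[1], "'",
                suggest_key(unknown[1], config_keys))
  scenario <- raw$scenario %||% "steady_state"
  if (!scenario %in% c("steady_state", "oral_ena", "iv_enaat", "custom"))
    stop_config("unknown scenario '", scenario, "'",
                suggest_key(scenario,
                            c("steady_state", "oral_ena", "iv_enaat", "custom")))
  subject <- if (!is.null(raw$study)) subject_params(raw$study)
             else do.call(subject_params, raw$subject %||% list())
  params <- raas_params()
  for (nm in names(raw$parameter_overrides %||% list()))
    params <- set_param(params, nm, raw$parameter_overrides[[nm]])
  drug <- drug_params()
  for (nm in names(raw$drug_parameter_overrides %||% list()))
    drug <- set_param(drug, nm, raw$drug_parameter_overrides[[nm]])
  solver <- raw$solver %||% list()
  doses <- lapply(raw$doses %||% list(), function(d)
    dose_event(d$time, d$amount_mg, d$route %||% "oral", d$compound %||% "ena"))
  structure(list(
    scenario = scenario, subject = subject, params = params, drug = drug,
    physiology = raw$physiology, doses = doses,
    horizon = raw$horizon %||% 4500, dt = raw$dt %||% 5,
    rtol = solver$rtol %||% 1e-8, atol = solver$atol %||% 1e-12,
    aldosterone_drive = raw$aldosterone_drive %||% "whole_body",
    out_dir = raw$out_dir %||% ".", seed = raw$seed
  ), class = "run_config")
}

#' Canonical serialization of a configuration
#'
#' Writes the fully-resolved configuration as YAML. Loading the written file
#' and writing it again yields an identical serialization (round-trip
#' stability).
#'
#' @param config a `run_config`
#' @param path output path; NULL returns the YAML string
#' @return the YAML string, invisibly if written to a file
#' @export
write_config <- function(config, path = NULL) {
  subj_fields <- c("body_weight", "dose_mg", "fasted", "vmax_liv",
                   "renal_clearance_ena", "renal_clearance_enaat",
                   "ace_c_ref", "v_liver")
  ser <- list(scenario = config$scenario,
              subject = unclass(config$subject)[subj_fields],
              doses = lapply(config$doses, unclass),
              horizon = config$horizon, dt = config$dt,
              solver = list(rtol = config$rtol, atol = config$atol),
              aldosterone_drive = config$aldosterone_drive,
              out_dir = config$out_dir, seed = config$seed)
  txt <- yaml::as.yaml(ser)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Run a configured scenario
#'
#' Assembles the system for the configuration's scenario, solves the
#' pre-administration steady state, and (for dosing scenarios) simulates the
#' dose protocol: `oral_ena` doses the subject's oral enalapril dose at
#' t = 1500 min from steady state; `iv_enaat` gives the same amount as
#' intravenous enalaprilat; `custom` uses the configured dose list.
#'
#' @param config a `run_config`
#' @return list with `system`, `steady_state`, and (if dosing) `trajectory`
#' @export
run_scenario <- function(config) {
  body <- build_reference_body(config$subject, physiology = config$physiology)
  with_drug <- config$scenario != "steady_state"
  opts <- system_options(include_raas = TRUE, include_drug = with_drug,
                         aldosterone_drive = config$aldosterone_drive,
                         rtol = config$rtol, atol = config$atol)
  sys <- assemble_system(body, config$params,
                         drug = if (with_drug) config$drug, options = opts)
  ss <- solve_steady_state(sys)
  out <- list(system = sys, steady_state = ss)
  if (with_drug) {
    doses <- switch(config$scenario,
      oral_ena = list(dose_event(1500, config$subject$dose_mg, "oral", "ena")),
      iv_enaat = list(dose_event(1500, config$subject$dose_mg, "intravenous",
                                 "enaat")),
      custom = config$doses)
    out$trajectory <- simulate_trajectory(sys, ss, doses = doses,
                                          horizon = config$horizon,
                                          dt = config$dt)
  }
  out
}

#' Convert pg/ml to umol/L
#'
#' `umol/L = (pg/ml) * 1e-6 / (MW in kDa)`. The tabulated prorenin reference
#' (69 pg/ml at 57 kDa) converts to 1.21e-6 umol/L.
#'
#' @param pg_per_ml concentration (pg/ml)
#' @param mw_kda molecular weight (kDa)
#' @return concentration (umol/L)
#' @export
#' @examples
#' pgml_to_umol(69, 57)  # 1.21e-06
pgml_to_umol <- function(pg_per_ml, mw_kda) {
  assert_nonneg(pg_per_ml, "pg_per_ml")
  if (any(mw_kda <= 0)) stop_domain("mw_kda must be > 0")
  pg_per_ml * 1e-6 / mw_kda
}

#' @rdname pgml_to_umol
#' @param umol_per_l concentration (umol/L)
#' @export
umol_to_pgml <- function(umol_per_l, mw_kda) {
  assert_nonneg(umol_per_l, "umol_per_l")
  if (any(mw_kda <= 0)) stop_domain("mw_kda must be > 0")
  umol_per_l * mw_kda * 1e6
}
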