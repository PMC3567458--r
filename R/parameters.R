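#' Default RAAS model parameters
#'
#' Returns the nested list of kinetic and physiological constants for the
#' circulating hormone cascade: molecular weights, steady-state reference
#' plasma concentrations, half-lives, secretion constants, Michaelis-Menten
#' constants for the renin (AGT to angiotensin 1) and ACE (angiotensin 1 to
#' angiotensin 2) conversions, AT1 and ACE binding constants, and the
#' feedback-inhibited prorenin-activation constants. Values are read from the
#' parameter file shipped with the package (`extdata/raas_parameters.yaml`),
#' which users may copy and edit.
#'
#' Units: concentrations umol/L, times min, volumes L; `k_secretion` L/min;
#' `k_on` L/umol/min; `k_off`, `kcat` 1/min; `k_production` umol/min.
#'
#' @param file optional path to an alternative parameter YAML file
#' @return nested named list with one block per species/enzyme
#' @export
#' @examples
#' p <- raas_params()
#' p$ang2$reference_plasma_conc
raas_params <- function(file = NULL) {
  p <- yaml::read_yaml(file %||% extdata("raas_parameters.yaml"))
  validate_raas_params(p)
  p
}

validate_raas_params <- function(p) {
  need <- c("agt", "renin", "ace", "ang1", "ang2", "at1", "aldosterone",
            "prorenin", "carboxylesterase")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop_config("parameter file missing block(s): ",
                                paste(miss, collapse = ", "))
  for (sp in c("agt", "renin", "ang1", "ang2", "aldosterone", "prorenin")) {
    if (p[[sp]]$t_half <= 0) stop_config(sp, ": t_half must be > 0")
    if (p[[sp]]$reference_plasma_conc < 0)
      stop_config(sp, ": reference_plasma_conc must be >= 0")
  }
  if (p$renin$km <= 0 || p$ace$km <= 0 || p$prorenin$km_kid <= 0 ||
      p$carboxylesterase$km_liv <= 0)
    stop_config("Michaelis constants must be > 0")
  invisible(p)
}

#' Names of the identifiable ("optimization") RAAS parameters
#'
#' The dotted paths of the rate constants and reference values that were fitted
#' rather than taken from literature: these are the free parameters of the
#' default steady-state identification problem.
#'
#' @return character vector of dotted paths into [raas_params()]
#' @export
optimized_raas_parameters <- function() {
  c("agt.t_half", "agt.k_secretion",
    "renin.kcat", "renin.km", "renin.t_half",
    "ace.kcat", "ace.km",
    "ang1.t_half",
    "ang2.k_inhibition",
    "at1.c_ref", "at1.k_on", "at1.k_off",
    "aldosterone.k_production", "aldosterone.k_secretion", "aldosterone.t_half",
    "prorenin.c_cell_ref", "prorenin.vmax_kid", "prorenin.km_kid",
    "prorenin.k_secretion", "prorenin.t_half")
}

#' Default drug (enalapril/enalaprilat) parameters
#'
#' Physicochemical properties, clearances, absorption and hepatic-permeation
#' settings for the parent-metabolite model, read from
#' `extdata/drug_parameters.yaml`. Study-specific values (carboxylesterase
#' Vmax, per-kg renal clearances, ACE reference concentration, liver volume)
#' live in [subject_params()], not here.
#'
#' @param file optional path to an alternative parameter YAML file
#' @return nested named list with blocks `ena`, `enaat`, `absorption`,
#'   `permeation`
#' @export
drug_params <- function(file = NULL) {
  p <- yaml::read_yaml(file %||% extdata("drug_parameters.yaml"))
  for (cmp in c("ena", "enaat")) {
    if (p[[cmp]]$molecular_weight_g_mol <= 0)
      stop_config(cmp, ": molecular weight must be > 0")
    if (p[[cmp]]$k_org <= 0) stop_config(cmp, ": k_org must be > 0")
  }
  if (p$absorption$f_abs < 0 || p$absorption$f_abs > 1)
    stop_config("absorption.f_abs must lie in [0, 1]")
  p
}

#' Table of study populations
#'
#' The six oral-enalapril study populations with their doses, fasted state and
#' the study-specific model parameters (carboxylesterase Vmax, renal
#' clearances per kg, ACE reference concentration, intracellular liver
#' volume).
#'
#' @return data.frame, one row per study
#' @export
study_table <- function() {
  read.csv(extdata("studies.csv"), stringsAsFactors = FALSE)
}

#' Subject and study parameters
#'
#' Builds the per-subject parameter record used by [build_reference_body()]
#' and [assemble_system()]. Either give a `study` label (one of
#' `study_table()$study`) to take that population's values, or set fields
#' directly; explicit fields override study values.
#'
#' @param study optional study label
#' @param body_weight body weight (kg)
#' @param dose_mg oral enalapril dose (mg)
#' @param fasted logical
#' @param vmax_liv carboxylesterase Vmax (umol/min/L)
#' @param renal_clearance_ena Ena renal clearance (L/min/kg)
#' @param renal_clearance_enaat Enaat renal clearance (L/min/kg)
#' @param ace_c_ref ACE reference concentration (umol/L)
#' @param v_liver intracellular liver volume (L)
#' @return object of class `subject_params`
#' @export
#' @examples
#' subject_params("gu")$v_liver
subject_params <- function(study = NULL, body_weight = NULL, dose_mg = NULL,
                           fasted = NULL, vmax_liv = NULL,
                           renal_clearance_ena = NULL,
                           renal_clearance_enaat = NULL,
                           ace_c_ref = NULL, v_liver = NULL) {
  base <- list(study_label = "reference", n_individuals = 1L,
               body_weight = 70, dose_mg = 10, fasted = TRUE,
               vmax_liv = 184.87, renal_clearance_ena = 6.02e-3,
               renal_clearance_enaat = 2.99e-4, ace_c_ref = 2.59,
               v_liver = 1.5)
  if (!is.null(study)) {
    tab <- study_table()
    i <- match(tolower(study), tab$study)
    if (is.na(i))
      stop_config("unknown study label: ", study,
                  suggest_key(study, tab$study))
    base <- list(study_label = tab$study[i], n_individuals = tab$n_individuals[i],
                 body_weight = tab$body_weight_kg[i], dose_mg = tab$dose_mg[i],
                 fasted = tab$fasted[i], vmax_liv = tab$vmax_liv[i],
                 renal_clearance_ena = tab$renal_clearance_ena[i],
                 renal_clearance_enaat = tab$renal_clearance_enaat[i],
                 ace_c_ref = tab$ace_c_ref[i], v_liver = tab$v_liver_L[i])
  }
  override <- list(body_weight = body_weight, dose_mg = dose_mg,
                   fasted = fasted, vmax_liv = vmax_liv,
                   renal_clearance_ena = renal_clearance_ena,
                   renal_clearance_enaat = renal_clearance_enaat,
                   ace_c_ref = ace_c_ref, v_liver = v_liver)
  override <- override[!vapply(override, is.null, logical(1))]
  subj <- modifyList(base, override)
  num <- c("body_weight", "dose_mg", "vmax_liv", "renal_clearance_ena",
           "renal_clearance_enaat", "ace_c_ref", "v_liver")
  for (f in num) {
    if (!is.numeric(subj[[f]]) || !is.finite(subj[[f]]) || subj[[f]] <= 0)
      stop_config("subject field '", f, "' must be a positive number")
  }
  structure(subj, class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat("<subject_params>", x$study_label, "\n")
  cat(sprintf("  weight %.1f kg, dose %g mg %s, V_liver %.2f L, ACE C_Ref %.2f umol/L\n",
              x$body_weight, x$dose_mg,
              if (isTRUE(x$fasted)) "(fasted)" else "(fed)",
              x$v_liver, x$ace_c_ref))
  invisible(x)
}
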