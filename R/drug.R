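## Parent-metabolite drug kinetics: oral absorption of enalapril (Ena),
## hepatic carboxylesterase conversion to enalaprilat (Enaat), renal and
## hepatic clearance. ACE binding itself reuses binding_rate().

#' Hepatic carboxylesterase conversion rate (Ena to Enaat)
#'
#' Michaelis-Menten hydrolysis in the hepatocytes:
#' `vmax_liv * v_liver * c_ena_cell / (c_ena_cell + km_liv)`; removes Ena and
#' adds Enaat 1:1 in the liver intracellular space.
#'
#' @param vmax_liv study-specific Vmax (umol/min/L)
#' @param km_liv Michaelis constant (umol/L), default 710
#' @param v_liver intracellular liver volume (L)
#' @param c_ena_cell hepatocyte Ena concentration (umol/L)
#' @return conversion rate (umol/min)
#' @export
#' @examples
#' hepatic_conversion_rate(178.18, 710, 1.57, 710)  # half-maximal: 139.9
hepatic_conversion_rate <- function(vmax_liv, km_liv, v_liver, c_ena_cell) {
  assert_nonneg(c_ena_cell, "c_ena_cell")
  if (any(km_liv <= 0)) stop_domain("km_liv must be > 0")
  vmax_liv * v_liver * c_ena_cell / (c_ena_cell + km_liv)
}

#' Renal clearance rate
#'
#' Irreversible elimination from kidney plasma with a per-kg clearance:
#' `cl_per_kg * body_weight * c_kidney_plasma`.
#'
#' @param cl_per_kg renal clearance (L/min/kg)
#' @param body_weight body weight (kg)
#' @param c_kidney_plasma kidney plasma concentration (umol/L)
#' @return elimination rate (umol/min)
#' @export
renal_clearance_rate <- function(cl_per_kg, body_weight, c_kidney_plasma) {
  assert_nonneg(cl_per_kg, "cl_per_kg")
  assert_nonneg(c_kidney_plasma, "c_kidney_plasma")
  cl_per_kg * body_weight * c_kidney_plasma
}

#' First-order oral absorption rate
#'
#' Total first-order emptying of the gut depot, `ka * gut_amount` (umol/min).
#' Of this flux a fraction `f_abs` reaches the liver-inflow plasma; the
#' remainder is never absorbed. The depot therefore always empties at rate
#' `ka`, and the total absorbed mass over infinite time is `f_abs * dose`.
#'
#' @param ka absorption rate constant (1/min)
#' @param f_abs absorbed fraction in \[0, 1\] (validated here, applied by the
#'   simulator when splitting the flux)
#' @param gut_amount amount remaining in the depot (umol)
#' @return depot emptying rate (umol/min)
#' @export
oral_absorption_rate <- function(ka, f_abs, gut_amount) {
  assert_nonneg(ka, "ka")
  assert_nonneg(gut_amount, "gut_amount")
  if (any(f_abs < 0) || any(f_abs > 1)) stop_domain("f_abs must lie in [0, 1]")
  ka * gut_amount
}

#' Dose event
#'
#' One administration event for [simulate_trajectory()].
#'
#' @param time event time (min), >= 0
#' @param amount_mg dose (mg), > 0
#' @param route `"oral"` or `"intravenous"`
#' @param compound `"ena"` or `"enaat"`
#' @return object of class `dose_event`
#' @export
#' @examples
#' dose_event(1500, 10)  # 10 mg oral enalapril at t = 1500 min
dose_event <- function(time, amount_mg, route = c("oral", "intravenous"),
                       compound = c("ena", "enaat")) {
  route <- match.arg(route)
  compound <- match.arg(compound)
  if (!is.finite(time) || time < 0) stop_domain("dose time must be >= 0")
  if (!is.finite(amount_mg) || amount_mg <= 0) stop_domain("dose amount must be > 0")
  if (route == "oral" && compound == "enaat")
    stop_config("oral enalaprilat is not modelled (poorly absorbed); use IV")
  structure(list(time = time, amount_mg = amount_mg, route = route,
                 compound = compound), class = "dose_event")
}

#' Convert a dose in mg to umol
#' @param amount_mg dose (mg)
#' @param mw_g_mol molecular weight (g/mol)
#' @return amount (umol)
#' @export
dose_mg_to_umol <- function(amount_mg, mw_g_mol) {
  assert_nonneg(amount_mg, "amount_mg")
  amount_mg / mw_g_mol * 1000
}
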