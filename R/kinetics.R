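## The RAAS rate laws. Each is a pure scalar/vectorized function of state and
## parameters; the simulator composes them over the compartment graph. Units:
## concentrations umol/L, volumes L, flows L/min, rates umol/min unless the
## docs say per-litre (umol/min/L).

#' Convective plasma transport rate
#'
#' Mass leaving an organ's plasma with the plasma fraction of blood flow:
#' `q_organ * (1 - hct) * c_pls_organ`.
#'
#' @param q_organ organ blood flow (L/min)
#' @param hct hematocrit fraction in \[0, 1)
#' @param c_pls_organ organ plasma concentration (umol/L)
#' @return transport rate (umol/min)
#' @export
#' @examples
#' convective_transport_rate(1.0, 0.47, 2.0)  # 1.06
convective_transport_rate <- function(q_organ, hct, c_pls_organ) {
  assert_nonneg(q_organ, "q_organ")
  assert_nonneg(c_pls_organ, "c_pls_organ")
  if (any(hct < 0) || any(hct >= 1)) stop_domain("hct must lie in [0, 1)")
  q_organ * (1 - hct) * c_pls_organ
}

#' First-order hormone secretion rate
#'
#' Secretion of an intracellularly produced hormone into the organ's plasma,
#' proportional to its intracellular concentration:
#' `k_secretion * c_cellular`.
#'
#' @param k_secretion rate constant (L/min)
#' @param c_cellular intracellular concentration (umol/L)
#' @return secretion rate (umol/min)
#' @export
secretion_rate <- function(k_secretion, c_cellular) {
  assert_nonneg(k_secretion, "k_secretion")
  assert_nonneg(c_cellular, "c_cellular")
  k_secretion * c_cellular
}

#' Feedback-inhibited prorenin activation rate
#'
#' Conversion of renal intracellular prorenin to plasma renin, competitively
#' inhibited by the renal plasma angiotensin 2 concentration:
#' `vmax_kid * v_kidney * c_pro / (c_pro + km_kid * (1 + c_ang2 / k_inhibition))`.
#' The single rate simultaneously removes intracellular prorenin and adds
#' renin to the kidney plasma.
#'
#' @param vmax_kid maximal activation rate (umol/min/L)
#' @param km_kid Michaelis constant (umol/L)
#' @param k_inhibition inhibition constant for angiotensin 2 (umol/L)
#' @param v_kidney intracellular kidney volume (L)
#' @param c_prorenin_cell renal intracellular prorenin concentration (umol/L)
#' @param c_ang2_renal_plasma renal plasma angiotensin 2 concentration (umol/L)
#' @return activation rate (umol/min)
#' @export
prorenin_activation_rate <- function(vmax_kid, km_kid, k_inhibition, v_kidney,
                                     c_prorenin_cell, c_ang2_renal_plasma) {
  assert_nonneg(c_prorenin_cell, "c_prorenin_cell")
  assert_nonneg(c_ang2_renal_plasma, "c_ang2_renal_plasma")
  if (any(km_kid <= 0) || any(k_inhibition <= 0))
    stop_domain("km_kid and k_inhibition must be > 0")
  vmax_kid * v_kidney * c_prorenin_cell /
    (c_prorenin_cell + km_kid * (1 + c_ang2_renal_plasma / k_inhibition))
}

#' First-order degradation rate (per litre of plasma)
#'
#' `c * ln(2) / half_life`, applied in every plasma compartment holding the
#' species (multiply by the compartment plasma volume for umol/min).
#'
#' @param c plasma concentration (umol/L)
#' @param half_life half-life (min), > 0
#' @return degradation rate (umol/min/L)
#' @export
degradation_rate <- function(c, half_life) {
  assert_nonneg(c, "concentration")
  if (any(half_life <= 0)) stop_domain("half_life must be > 0")
  c * log(2) / half_life
}

#' Michaelis-Menten conversion rate
#'
#' Enzymatic conversion of a prohormone in an organ's plasma:
#' `kcat * v0 * c_enzyme * c_prohormone / (c_prohormone + km)`. Removes the
#' prohormone and adds the product in the same compartment; the enzyme is
#' catalytic.
#'
#' @param kcat turnover number (1/min)
#' @param km Michaelis constant (umol/L)
#' @param v0 organ plasma volume (L)
#' @param c_enzyme enzyme concentration (umol/L)
#' @param c_prohormone prohormone concentration (umol/L)
#' @return conversion rate (umol/min)
#' @export
mm_conversion_rate <- function(kcat, km, v0, c_enzyme, c_prohormone) {
  assert_nonneg(c_enzyme, "c_enzyme")
  assert_nonneg(c_prohormone, "c_prohormone")
  if (any(km <= 0)) stop_domain("km must be > 0")
  kcat * v0 * c_enzyme * c_prohormone / (c_prohormone + km)
}

#' Net receptor/enzyme binding rate (per litre of plasma)
#'
#' Net complex formation `k_on * c_free_target * c_ligand - k_off * c_complex`.
#' Used both for angiotensin 2 binding the AT1 receptor and for enalaprilat
#' binding (and thereby blocking) ACE.
#'
#' @param k_on association constant (L/umol/min)
#' @param k_off dissociation constant (1/min)
#' @param c_free_target free receptor/enzyme concentration (umol/L)
#' @param c_ligand free ligand concentration (umol/L)
#' @param c_complex complex concentration (umol/L)
#' @return net binding rate (umol/min/L); positive = complex forming
#' @export
binding_rate <- function(k_on, k_off, c_free_target, c_ligand, c_complex) {
  assert_nonneg(c_free_target, "c_free_target")
  assert_nonneg(c_ligand, "c_ligand")
  assert_nonneg(c_complex, "c_complex")
  k_on * c_free_target * c_ligand - k_off * c_complex
}

#' Aldosterone synthesis rate
#'
#' Synthesis driven by the AT1-angiotensin-2 complex with a basal zero-order
#' term: `k_secretion * c_complex + k_production`.
#'
#' @param k_secretion complex-driven rate constant (L/min)
#' @param k_production basal production (umol/min)
#' @param c_complex driving AT1-Ang2 complex concentration (umol/L)
#' @return synthesis rate (umol/min)
#' @export
aldosterone_synthesis_rate <- function(k_secretion, k_production, c_complex) {
  assert_nonneg(c_complex, "c_complex")
  k_secretion * c_complex + k_production
}
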