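## The reduced whole-body physiology: organ plasma volumes, plasma-perfusing
## blood flows, hematocrit and per-organ ACE/AT1 expression. Organs are
## perfused in parallel between the arterial and venous pools; the lung sits
## in series (venous -> lung -> arterial) so that pulmonary ACE sees total
## cardiac output.

#' The 15 body organs of the expression table
#' @return character vector of organ identifiers
#' @export
body_organs <- function() {
  c("brain", "fat", "gonads", "heart", "kidney", "large_intestine", "liver",
    "lung", "muscle", "pancreas", "plasma", "skin", "spleen",
    "small_intestine", "stomach")
}

#' Reference physiology table
#'
#' Reads the packaged reference-human table: plasma volume, blood flow and
#' relative ACE/AT1 expression per organ, plus the venous and arterial blood
#' pools. Total plasma volume is about 3 L and cardiac output about
#' 6.6 L/min blood for a 70 kg adult. Users may supply their own file with
#' the same columns.
#'
#' @param file optional path to an alternative CSV
#' @return data.frame with columns `organ`, `plasma_volume_L`,
#'   `blood_flow_L_per_min`, `ace_expression_pct`, `at1_expression_pct`
#' @export
reference_physiology <- function(file = NULL) {
  tab <- read.csv(file %||% extdata("reference_physiology.csv"),
                  stringsAsFactors = FALSE)
  need <- c("organ", "plasma_volume_L", "blood_flow_L_per_min",
            "ace_expression_pct", "at1_expression_pct")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_config("physiology file missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Build the reduced whole-body compartment model
#'
#' Assembles the compartment graph used by the simulator: the 15 organs of
#' the expression table plus venous and arterial blood pools, with plasma
#' volumes and blood flows scaled linearly with body weight relative to
#' 70 kg. The lung is placed in series between the venous and arterial pools
#' and carries total cardiac output; all other organs are perfused in
#' parallel. Flow balance (inflow = outflow at every node) holds by
#' construction: the lung/pool flow is recomputed as the sum of the parallel
#' organ flows.
#'
#' @param subject a [subject_params()] record (sets body weight, intracellular
#'   liver volume and the ACE reference concentration)
#' @param hematocrit hematocrit fraction in (0, 1); default 0.47
#' @param physiology optional physiology table ([reference_physiology()]
#'   format) or path to a CSV; overrides the packaged table
#' @return object of class `body_model`: list with `compartments` data.frame
#'   (volumes in L, flows in L/min blood), `hematocrit`, `v_kidney_cell`,
#'   `v_liver_cell`, `subject`
#' @export
#' @examples
#' body <- build_reference_body(subject_params("gu"))
#' body$v_liver_cell  # 1.57 L
build_reference_body <- function(subject = subject_params(),
                                 hematocrit = 0.47,
                                 physiology = NULL) {
  if (!inherits(subject, "subject_params")) subject <- do.call(subject_params, subject)
  if (!is.numeric(hematocrit) || hematocrit <= 0 || hematocrit >= 1)
    stop_domain("hematocrit must lie in (0, 1)")
  tab <- if (is.character(physiology)) reference_physiology(physiology)
         else physiology %||% reference_physiology()
  expect <- c("arterial_blood", "venous_blood", body_organs())
  unknown <- setdiff(tab$organ, expect)
  if (length(unknown))
    stop_config("unknown organ name(s) in physiology table: ",
                paste(unknown, collapse = ", "))
  miss <- setdiff(expect, tab$organ)
  if (length(miss))
    stop_config("physiology table missing organ(s): ", paste(miss, collapse = ", "))
  tab <- tab[match(expect, tab$organ), ]
  if (any(tab$plasma_volume_L < 0) || any(tab$blood_flow_L_per_min < 0))
    stop_domain("volumes and flows must be >= 0")
  if (any(tab$ace_expression_pct < 0 | tab$ace_expression_pct > 100) ||
      any(tab$at1_expression_pct < 0 | tab$at1_expression_pct > 100))
    stop_domain("expression percentages must lie in [0, 100]")
  if (tab$ace_expression_pct[tab$organ == "lung"] != 100)
    stop_config("lung ACE expression must be the 100% reference")
  if (tab$at1_expression_pct[tab$organ == "kidney"] != 100)
    stop_config("kidney AT1 expression must be the 100% reference")

  scale <- subject$body_weight / 70
  tab$plasma_volume_L <- tab$plasma_volume_L * scale
  tab$blood_flow_L_per_min <- tab$blood_flow_L_per_min * scale
  ## enforce flow balance: series elements carry the summed parallel flow
  parallel <- setdiff(body_organs(), "lung")
  co <- sum(tab$blood_flow_L_per_min[match(parallel, tab$organ)])
  tab$blood_flow_L_per_min[tab$organ %in% c("lung", "venous_blood", "arterial_blood")] <- co
  if (sum(tab$plasma_volume_L) <= 0) stop_domain("total plasma volume must be > 0")

  structure(list(
    compartments = tab,
    hematocrit = hematocrit,
    cardiac_output = co,
    total_plasma_volume = sum(tab$plasma_volume_L),
    v_kidney_cell = 0.24,
    v_liver_cell = subject$v_liver,
    subject = subject
  ), class = "body_model")
}

#' @export
print.body_model <- function(x, ...) {
  cat("<body_model>", nrow(x$compartments), "compartments",
      sprintf("(total plasma %.2f L, CO %.2f L/min blood, HCT %.2f)\n",
              x$total_plasma_volume, x$cardiac_output, x$hematocrit))
  cat("  subject:", x$subject$study_label,
      sprintf("%.1f kg; V_liver %.2f L, V_kidney %.2f L (intracellular)\n",
              x$subject$body_weight, x$v_liver_cell, x$v_kidney_cell))
  invisible(x)
}

#' Expressed enzyme/receptor concentration in an organ
#'
#' Scales a reference concentration by the organ's relative expression:
#' `c_ref * e_ref_pct / 100`. Used for both ACE and the AT1 receptor.
#'
#' @param c_ref reference concentration (umol/L), the concentration in the
#'   organ with the highest expression
#' @param e_ref_pct relative expression in percent, in \[0, 100\]
#' @return concentration (umol/L); vectorized over both arguments
#' @export
#' @examples
#' expressed_concentration(7.69, 100)  # kidney AT1: 7.69
#' expressed_concentration(1.86, 15)   # brain ACE: 0.279
expressed_concentration <- function(c_ref, e_ref_pct) {
  assert_nonneg(c_ref, "c_ref")
  if (any(e_ref_pct < 0) || any(e_ref_pct > 100))
    stop_domain("e_ref_pct must lie in [0, 100]")
  c_ref * e_ref_pct / 100
}
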