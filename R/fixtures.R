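## Synthetic-data generation: virtual subjects sampled within the spans of
## the study populations, noisy oral-enalapril concentration-time curves for
## exercising the Monte Carlo identification, and (optionally noisy)
## steady-state concentration targets.

#' Generate synthetic fixtures
#'
#' Deterministic per seed; the caller's RNG state is restored.
#'
#' * `subjects`: samples body weight, carboxylesterase Vmax, renal
#'   clearances, ACE reference concentration, liver volume uniformly within
#'   the ranges spanned by the study populations; dose drawn from the
#'   administered doses (10/20 mg).
#' * `pk_curves`: simulates the oral-enalapril scenario (drug model only) for
#'   a subject, samples venous Ena and Enaat at clinical-like times (15 min
#'   to 48 h post-dose) and applies multiplicative lognormal noise
#'   (`sdlog = noise`, default 0.15, i.e. about 15% CV). `noise = 0`
#'   reproduces the model prediction exactly.
#' * `raas_targets`: the six reference steady-state venous concentrations,
#'   with optional lognormal noise.
#'
#' @param kind `"subjects"`, `"pk_curves"` or `"raas_targets"`
#' @param n number of subjects / curves / replicates (>= 1)
#' @param seed integer RNG seed (required)
#' @param subject subject for `pk_curves` (default [subject_params()])
#' @param noise lognormal `sdlog` for noisy kinds (default 0.15 for
#'   `pk_curves`, 0 for `raas_targets`)
#' @param drug,params parameter lists used for simulation/targets
#' @return data.frame (see details per kind)
#' @export
generate_fixtures <- function(kind = c("subjects", "pk_curves", "raas_targets"),
                              n = 1, seed, subject = subject_params(),
                              noise = NULL, drug = drug_params(),
                              params = raas_params()) {
  kind <- match.arg(kind)
  if (missing(seed) || is.null(seed)) stop_config("generate_fixtures requires a seed")
  if (n < 1) stop_domain("n must be >= 1")
  with_seed(seed, switch(kind,
    subjects = fixture_subjects(n),
    pk_curves = fixture_pk_curves(n, subject, noise %||% 0.15, drug, params),
    raas_targets = fixture_raas_targets(n, noise %||% 0, params)))
}

fixture_subjects <- function(n) {
  tab <- study_table()
  rng <- function(col) runif(n, min(tab[[col]]), max(tab[[col]]))
  data.frame(
    subject_id = seq_len(n),
    body_weight = runif(n, 56, 80),  # span reported for the study populations
    dose_mg = sample(sort(unique(tab$dose_mg)), n, replace = TRUE),
    fasted = sample(c(TRUE, FALSE), n, replace = TRUE),
    vmax_liv = rng("vmax_liv"),
    renal_clearance_ena = rng("renal_clearance_ena"),
    renal_clearance_enaat = rng("renal_clearance_enaat"),
    ace_c_ref = rng("ace_c_ref"),
    v_liver = rng("v_liver_L"))
}

#' Clinical-like sampling times for oral PK (min post-dose)
#' @return numeric vector, 15 min to 48 h
#' @export
pk_sampling_times <- function() {
  c(15, 30, 45, 60, 90, 120, 180, 240, 360, 480, 720, 1440, 2160, 2880)
}

## drug-only oral simulation; returns venous Ena/Enaat at the sampling times
simulate_oral_pk <- function(subject, drug, params,
                             times = pk_sampling_times(),
                             ka = NULL, f_abs = NULL, rtol = 1e-7,
                             atol = 1e-10, ace_binding = TRUE) {
  if (!is.null(ka)) drug$absorption$ka <- ka
  if (!is.null(f_abs)) drug$absorption$f_abs <- f_abs
  body <- build_reference_body(subject)
  sys <- assemble_system(body, raas = params, drug = drug,
                         options = system_options(include_raas = FALSE,
                                                  include_drug = TRUE,
                                                  ace_binding = ace_binding,
                                                  rtol = rtol, atol = atol))
  tr <- simulate_trajectory(sys, doses = list(dose_event(0, subject$dose_mg)),
                            times = sort(unique(c(0, times))))
  keep <- match(times, tr$times)
  data.frame(time_min = times,
             ena_umol_per_l = concentration_course(tr, "ena")[keep],
             enaat_umol_per_l = concentration_course(tr, "enaat")[keep])
}

## Lower limit of quantification applied to synthetic assay values (umol/L);
## about 0.4 ng/ml for enalapril, typical of LC-MS/MS plasma assays. Values
## below it are censored to NA, as in real concentration-time datasets.
pk_assay_loq <- 1e-3

fixture_pk_curves <- function(n, subject, noise, drug, params) {
  base <- simulate_oral_pk(subject, drug, params)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- base
    if (noise > 0) {
      d$ena_umol_per_l <- d$ena_umol_per_l *
        exp(stats::rnorm(nrow(d), 0, noise))
      d$enaat_umol_per_l <- d$enaat_umol_per_l *
        exp(stats::rnorm(nrow(d), 0, noise))
      d$ena_umol_per_l[d$ena_umol_per_l < pk_assay_loq] <- NA
      d$enaat_umol_per_l[d$enaat_umol_per_l < pk_assay_loq] <- NA
    }
    cbind(curve_id = i, d)
  }))
  attr(out, "true_ka") <- drug$absorption$ka
  attr(out, "true_f_abs") <- drug$absorption$f_abs
  attr(out, "loq_umol_per_l") <- if (noise > 0) pk_assay_loq else 0
  out
}

fixture_raas_targets <- function(n, noise, params) {
  sp <- c("agt", "renin", "prorenin", "ang1", "ang2", "aldosterone")
  ref <- vapply(sp, function(s) params[[s]]$reference_plasma_conc, numeric(1))
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    v <- if (noise > 0) ref * exp(stats::rnorm(length(ref), 0, noise)) else ref
    data.frame(replicate = i, species = sp, concentration_umol_per_l = v)
  }))
  rownames(out) <- NULL
  out
}

#' Oral-absorption identification problem from a synthetic curve
#'
#' Builds the Monte Carlo [fit_problem()] for recovering the absorption
#' constants (`ka`, `f_abs`) from a (possibly noisy) oral enalapril curve,
#' and the matching prediction model. Residuals are relative, over the
#' venous Ena concentrations at the curve's sampling times.
#'
#' @param curve one curve from `generate_fixtures("pk_curves", ...)`
#' @param subject the subject the curve was generated for
#' @param max_evaluations Monte Carlo draw budget
#' @param seed RNG seed
#' @param drug,params base parameter lists
#' @return list with `problem` and `model`
#' @export
absorption_fit_problem <- function(curve, subject = subject_params(),
                                   max_evaluations = 2000, seed = 1,
                                   drug = drug_params(),
                                   params = raas_params()) {
  curve <- curve[!is.na(curve$ena_umol_per_l), ]  # drop censored (< LOQ) samples
  if (nrow(curve) < 4)
    stop_config("need at least 4 quantifiable Ena samples to identify ka/f_abs")
  free <- data.frame(name = c("ka", "f_abs"),
                     init = c(drug$absorption$ka, drug$absorption$f_abs),
                     lower = c(0.005, 0.1), upper = c(0.2, 1.0),
                     log_scale = c(TRUE, FALSE))
  targets <- data.frame(observable = paste0("ena_t", curve$time_min),
                        ref = curve$ena_umol_per_l, weight = 1)
  ## the parent (Ena) curve is independent of the metabolite's ACE binding,
  ## so the objective can skip the stiff binding terms
  model <- function(par) {
    pred <- simulate_oral_pk(subject, drug, params,
                             times = curve$time_min,
                             ka = par[["ka"]], f_abs = par[["f_abs"]],
                             rtol = 1e-6, atol = 1e-10, ace_binding = FALSE)
    setNames(pred$ena_umol_per_l, paste0("ena_t", curve$time_min))
  }
  list(problem = fit_problem(free, targets, max_evaluations = max_evaluations,
                             seed = seed),
       model = model)
}
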