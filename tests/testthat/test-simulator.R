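test_that("term registry attributes every mechanism, activation only in kidney", {
  sys <- coupled_system()
  act <- system_terms(sys, "prorenin_activation_rate")
  expect_length(act, 1)
  expect_equal(act[[1]]$compartment, "kidney")
  ops <- vapply(sys$terms, `[[`, character(1), "op")
  expect_true(all(c("convective_transport_rate", "degradation_rate",
                    "mm_conversion_rate", "binding_rate", "secretion_rate",
                    "aldosterone_synthesis_rate", "oral_absorption_rate",
                    "hepatic_conversion_rate", "renal_clearance_rate") %in% ops))
})

test_that("transport alone conserves the total mass of every species", {
  sys <- assemble_system(ref_body(), ref_params(), ref_drug(),
                         system_options(include_raas = TRUE,
                                        include_drug = TRUE,
                                        reactions = FALSE,
                                        degradation = FALSE))
  y0 <- reference_state(sys)
  ## put some drug in plasma so its transport is exercised too
  y0["ena.venous_blood"] <- 5
  y0["enaat.arterial_blood"] <- 2
  tr <- simulate_trajectory(sys, y0, horizon = 500, dt = 50)
  for (sp in c("agt", "renin", "ang1", "ang2", "ena", "enaat")) {
    tot <- rowSums(tr$states[, grep(paste0("^", sp, "\\."),
                                    sys$state_names), drop = FALSE])
    expect_equal(max(abs(tot / tot[1] - 1)), 0, tolerance = 1e-8)
  }
})

test_that("degradation-only dynamics reduce to the analytic exponential", {
  sys <- assemble_system(ref_body(), ref_params(),
                         options = system_options(reactions = FALSE,
                                                  degradation = TRUE,
                                                  rtol = 1e-10, atol = 1e-16))
  t12 <- ref_params()$ang2$t_half
  tr <- simulate_trajectory(sys, horizon = 3 * t12, dt = t12 / 2)
  conc <- concentration_course(tr, "ang2")
  expect_equal(conc / conc[1], 2^(-tr$times / t12), tolerance = 1e-6)
})

test_that("the steady state meets the residual criterion and balances fluxes", {
  sys <- raas_system()
  ss <- raas_steady()
  expect_lt(attr(ss, "residual"), 1e-9)
  expect_true(all(ss >= 0))
  ## aldosterone: synthesis equals total degradation at steady state
  p <- ref_params()
  c_drive <- sum(ss[grep("^at1_complex", sys$state_names)]) /
    ref_body()$total_plasma_volume
  synth <- aldosterone_synthesis_rate(p$aldosterone$k_secretion,
                                      p$aldosterone$k_production, c_drive)
  V0 <- sys$body$compartments$plasma_volume_L
  conc <- ss[paste0("aldosterone.", sys$index$comps)] / V0
  degr <- sum(degradation_rate(conc, p$aldosterone$t_half) * V0)
  expect_equal(synth / degr, 1, tolerance = 1e-6)
})

test_that("the steady state is invariant to the initial condition", {
  sys <- raas_system()
  base <- venous_concentrations(sys, raas_steady())
  set.seed(3)
  for (i in 1:3) {
    y0 <- as.numeric(reference_state(sys)) *
      runif(sys$n_state, 0.5, 2)  # within a 10x perturbation ball
    ss <- solve_steady_state(sys, init = y0)
    expect_equal(venous_concentrations(sys, ss), base, tolerance = 1e-6)
  }
})

test_that("an undosed trajectory stays at the steady state", {
  sys <- raas_system()
  ss <- raas_steady()
  tr <- simulate_trajectory(sys, ss, horizon = 3000, dt = 250)
  for (sp in ref_species) {
    conc <- concentration_course(tr, sp)
    expect_equal(max(abs(conc / conc[1] - 1)), 0, tolerance = 5e-3)
  }
})

test_that("receptor and enzyme totals are conserved along a dosed trajectory", {
  sys <- coupled_system()
  ss <- memo("coupled_ss", solve_steady_state(sys))
  tr <- memo("coupled_traj",
             simulate_trajectory(sys, ss, doses = list(dose_event(1500, 10)),
                                 horizon = 4500, dt = 15))
  comp <- sys$body$compartments
  ## free + complex = expressed total by construction; the complex must stay
  ## within [0, total] for the free concentration to be physical
  at1_tot_amt <- expressed_concentration(ref_params()$at1$c_ref,
                                         comp$at1_expression_pct) *
    comp$plasma_volume_L
  ace_tot_amt <- expressed_concentration(sys$subject$ace_c_ref,
                                         comp$ace_expression_pct) *
    comp$plasma_volume_L
  for (o in comp$organ[comp$at1_expression_pct > 0]) {
    x <- tr$states[, paste0("at1_complex.", o)]
    expect_true(all(x >= -1e-12))
    expect_true(all(x <= at1_tot_amt[comp$organ == o] * (1 + 1e-9)))
  }
  for (o in comp$organ[comp$ace_expression_pct > 0]) {
    x <- tr$states[, paste0("ace_complex.", o)]
    expect_true(all(x >= -1e-12))
    expect_true(all(x <= ace_tot_amt[comp$organ == o] * (1 + 1e-9)))
  }
  ## and no state goes meaningfully negative anywhere
  expect_gt(min(tr$states), -1e-12)
})

test_that("identical inputs give bit-identical trajectory metadata hashes", {
  sys <- drug_only_system()
  t1 <- simulate_trajectory(sys, doses = list(dose_event(100, 10)),
                            horizon = 300, dt = 50)
  t2 <- simulate_trajectory(sys, doses = list(dose_event(100, 10)),
                            horizon = 300, dt = 50)
  expect_identical(t1$metadata$hash, t2$metadata$hash)
  expect_identical(t1$states, t2$states)
  t3 <- simulate_trajectory(sys, doses = list(dose_event(100, 20)),
                            horizon = 300, dt = 50)
  expect_false(identical(t1$metadata$hash, t3$metadata$hash))
})

test_that("halving solver tolerances leaves venous concentrations unchanged", {
  mk <- function(f) assemble_system(ref_body(), ref_params(), ref_drug(),
          system_options(include_raas = TRUE, include_drug = TRUE,
                         rtol = 1e-8 * f, atol = 1e-12 * f))
  run <- function(sys) {
    ss <- solve_steady_state(sys)
    tr <- simulate_trajectory(sys, ss, doses = list(dose_event(200, 10)),
                              horizon = 1200, dt = 100)
    vapply(c(ref_species, "ena", "enaat"), function(sp)
      concentration_course(tr, sp)[13], numeric(1))
  }
  a <- run(mk(1)); b <- run(mk(0.5))
  expect_equal(a, b, tolerance = 1e-3)
})

test_that("dosing errors are informative", {
  sys <- drug_only_system()
  expect_error(simulate_trajectory(sys, doses = list(dose_event(5000, 10)),
                                   horizon = 300), "beyond the horizon")
  raas_only <- raas_system()
  expect_error(simulate_trajectory(raas_only, doses = list(dose_event(10, 10)),
                                   horizon = 300), "without the drug model")
})
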