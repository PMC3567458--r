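test_that("rms_error computes weighted relative root mean square", {
  expect_equal(rms_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rms_error(2, 1), 1)
  expect_equal(rms_error(c(1.3, 1.4), c(1, 1)), sqrt((0.09 + 0.16) / 2))
  expect_equal(rms_error(c(2, 2), c(1, 4), relative = FALSE),
               sqrt((1 + 4) / 2))
  expect_error(rms_error(1, 0), "relative = FALSE")
  expect_error(rms_error(c(1, 2), 1), "equal length")
})

test_that("the simplex agrees with an independent Nelder-Mead on a test bowl", {
  free <- data.frame(name = c("a", "b"), init = c(4, -2),
                     lower = c(-50, -50), upper = c(50, 50),
                     log_scale = FALSE)
  targets <- data.frame(observable = c("a", "b"), ref = c(3, 5), weight = 1)
  prob <- fit_problem(free, targets, max_evaluations = 600)
  model <- function(par) par
  fit <- fit_simplex(prob, model, restarts = 2)
  ## independent oracle: stats::optim on the same objective
  ora <- stats::optim(c(4, -2),
                      function(z) rms_error(z, c(3, 5)),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  expect_equal(unname(fit$par), c(3, 5), tolerance = 1e-3)
  expect_equal(unname(fit$par), unname(ora$par), tolerance = 1e-3)
  expect_lte(fit$value, fit$initial_value)
  expect_true(all(diff(fit$trace) <= 0))  # best-so-far is non-increasing
})

test_that("an already-optimal start is returned unchanged", {
  free <- data.frame(name = "a", init = 3, lower = 0.1, upper = 10,
                     log_scale = TRUE)
  targets <- data.frame(observable = "a", ref = 3, weight = 1)
  fit <- fit_simplex(fit_problem(free, targets, max_evaluations = 200),
                     function(par) par)
  expect_equal(unname(fit$par), 3, tolerance = 1e-6)
  expect_equal(fit$value, 0, tolerance = 1e-8)
})

test_that("a doubled angiotensin-2 half-life is recovered within 1%", {
  params <- ref_params()
  model <- raas_steady_state_model(ref_body(), params)
  truth <- get_param(params, "ang2.t_half")
  free <- data.frame(name = "ang2.t_half", init = truth * 2,
                     lower = truth / 10, upper = truth * 10, log_scale = TRUE)
  base_ss <- memo("base_ss_pred",
                  venous_concentrations(raas_system(), raas_steady()))
  targets <- data.frame(observable = names(base_ss), ref = unname(base_ss),
                        weight = 1)
  fit <- fit_simplex(fit_problem(free, targets, max_evaluations = 150), model,
                     restarts = 1)
  expect_equal(unname(fit$par) / truth, 1, tolerance = 0.01)
})

test_that("Monte Carlo search is seeded, bounded and reproducible", {
  free <- data.frame(name = c("a", "b"), init = c(1, 0.5),
                     lower = c(0.01, 0.1), upper = c(100, 1),
                     log_scale = c(TRUE, FALSE))
  targets <- data.frame(observable = c("a", "b"), ref = c(3, 0.7), weight = 1)
  model <- function(par) par
  one <- fit_monte_carlo(fit_problem(free, targets, max_evaluations = 1,
                                     seed = 9), model)
  expect_equal(one$evaluations, 1)
  expect_true(one$par[["a"]] >= 0.01 && one$par[["a"]] <= 100)
  a <- fit_monte_carlo(fit_problem(free, targets, max_evaluations = 200,
                                   seed = 4), model)
  b <- fit_monte_carlo(fit_problem(free, targets, max_evaluations = 200,
                                   seed = 4), model)
  expect_identical(a$par, b$par)
  expect_true(all(diff(a$trace) <= 0))
  c2 <- fit_monte_carlo(fit_problem(free, targets, max_evaluations = 200,
                                    seed = 5), model)
  expect_false(identical(a$par, c2$par))
  expect_error(fit_monte_carlo(fit_problem(free, targets), model), "seed")
})

test_that("the default RAAS fit problem is well-formed", {
  prob <- raas_fit_problem()
  expect_equal(nrow(prob$free), length(optimized_raas_parameters()))
  expect_equal(nrow(prob$targets), 6)
  expect_true(all(prob$free$init >= prob$free$lower &
                    prob$free$init <= prob$free$upper))
  expect_error(fit_problem(data.frame(name = "a", init = 5, lower = 1,
                                      upper = 2, log_scale = FALSE),
                           data.frame(observable = "a", ref = 1, weight = 1)),
               "within their bounds")
})
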