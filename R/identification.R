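## Parameter identification: simplex (fminsearch-style Nelder-Mead) against
## steady-state targets, and seeded Monte Carlo random search against
## concentration-time data. The error function is in both cases a root mean
## square of (by default relative) residuals.

#' Root-mean-square error
#'
#' `sqrt(mean(w * ((pred - obs) / obs)^2))` in relative mode (the default;
#' targets span six orders of magnitude, so absolute residuals would weight
#' only the largest), or `sqrt(mean(w * (pred - obs)^2))` in absolute mode.
#'
#' @param predicted,observed equal-length numeric vectors
#' @param weights positive weights (default 1)
#' @param relative divide residuals by `observed` (default TRUE)
#' @return scalar error
#' @export
#' @examples
#' rms_error(c(1.3, 1.4), c(1, 1))  # sqrt((0.09 + 0.16)/2) = 0.3536
rms_error <- function(predicted, observed, weights = 1, relative = TRUE) {
  if (length(predicted) != length(observed) || !length(observed))
    stop_domain("predicted and observed must have equal length >= 1")
  if (any(weights <= 0)) stop_domain("weights must be > 0")
  if (relative && any(observed == 0))
    stop_domain("observed contains 0; use relative = FALSE (absolute residuals)")
  r <- if (relative) (predicted - observed) / observed else predicted - observed
  sqrt(mean(weights * r^2))
}

#' Define a fit problem
#'
#' @param free data.frame with columns `name` (dotted parameter path),
#'   `init`, `lower`, `upper`, `log_scale` (logical)
#' @param targets data.frame with columns `observable`, `ref`, `weight`
#' @param max_evaluations objective evaluation budget
#' @param seed RNG seed (required for Monte Carlo mode)
#' @param relative use relative residuals in the RMS error
#' @return object of class `fit_problem`
#' @export
fit_problem <- function(free, targets, max_evaluations = 5000, seed = NULL,
                        relative = TRUE) {
  stopifnot(is.data.frame(free),
            all(c("name", "init", "lower", "upper", "log_scale") %in% names(free)),
            is.data.frame(targets),
            all(c("observable", "ref", "weight") %in% names(targets)),
            nrow(targets) >= 1)
  if (any(free$init < free$lower | free$init > free$upper))
    stop_config("initial values must lie within their bounds")
  if (any(targets$weight <= 0)) stop_config("target weights must be > 0")
  structure(list(free = free, targets = targets,
                 max_evaluations = max_evaluations, seed = seed,
                 relative = relative), class = "fit_problem")
}

#' Default steady-state identification problem for the RAAS
#'
#' Free parameters are the identifiable rate constants and reference values
#' ([optimized_raas_parameters()]) initialized at their tabulated values with
#' x0.01 to x100 bounds on log scale; targets are the six reference
#' pre-administration venous plasma concentrations.
#'
#' @param params RAAS parameter list supplying initial values and targets
#' @param max_evaluations budget (default 4000)
#' @return a [fit_problem()]
#' @export
raas_fit_problem <- function(params = raas_params(), max_evaluations = 4000) {
  nms <- optimized_raas_parameters()
  init <- vapply(nms, function(n) get_param(params, n), numeric(1))
  free <- data.frame(name = nms, init = init, lower = init / 100,
                     upper = init * 100, log_scale = TRUE)
  sp <- c("agt", "renin", "prorenin", "ang1", "ang2", "aldosterone")
  targets <- data.frame(
    observable = sp,
    ref = vapply(sp, function(s) params[[s]]$reference_plasma_conc, numeric(1)),
    weight = 1)
  fit_problem(free, targets, max_evaluations = max_evaluations)
}

#' Steady-state prediction model for identification
#'
#' Returns a function mapping a named vector of free-parameter values to the
#' predicted venous steady-state concentrations (named by species). The
#' system is reassembled for every candidate (the intracellular closure is
#' recomputed under the candidate parameters) and the steady state is solved
#' with a warm start from the previous candidate's solution.
#'
#' @param body a `body_model`
#' @param params base RAAS parameters
#' @param horizon integration horizon passed to [solve_steady_state()]
#' @return function(named numeric) -> named numeric predictions
#' @export
raas_steady_state_model <- function(body = build_reference_body(),
                                    params = raas_params(), horizon = 3000) {
  cache <- new.env(parent = emptyenv())
  cache$warm <- NULL
  function(par) {
    p <- params
    for (nm in names(par)) p <- set_param(p, nm, par[[nm]])
    sys <- assemble_system(body, p, options = system_options())
    init <- cache$warm
    if (!is.null(init) && length(init) != sys$n_state) init <- NULL
    ss <- solve_steady_state(sys, init = init, horizon = horizon)
    cache$warm <- as.numeric(ss)
    venous_concentrations(sys, ss)
  }
}

transform_par <- function(x, log_scale) ifelse(log_scale, log10(x), x)
untransform_par <- function(z, log_scale) ifelse(log_scale, 10^z, z)

make_objective <- function(problem, model) {
  free <- problem$free
  lo <- transform_par(free$lower, free$log_scale)
  hi <- transform_par(free$upper, free$log_scale)
  obs <- problem$targets$ref
  w <- problem$targets$weight
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  counter$trace <- numeric(0)
  f <- function(z) {
    counter$n <- counter$n + 1L
    zc <- pmin(pmax(z, lo), hi)
    pen <- sum((z - zc)^2)
    par <- setNames(untransform_par(zc, free$log_scale), free$name)
    val <- tryCatch({
      pred <- model(par)
      pred <- pred[match(problem$targets$observable, names(pred))]
      if (any(!is.finite(pred))) Inf
      else rms_error(pred, obs, w, relative = problem$relative)
    }, error = function(e) Inf)
    out <- if (is.finite(val)) val + 100 * pen * (1 + val) else 1e10
    counter$trace <- c(counter$trace, out)
    out
  }
  list(f = f, counter = counter, lo = lo, hi = hi)
}

#' Nelder-Mead simplex identification
#'
#' fminsearch-style downhill simplex with the standard reflection, expansion
#' and contraction coefficients (1, 2, 0.5, 0.5), termination on relative
#' simplex spread below `tol` or budget exhaustion, and optional restarts
#' (the simplex is re-seeded around the incumbent best, a standard remedy for
#' premature collapse in higher dimensions). Parameters flagged `log_scale`
#' are searched in log10 space; bound violations are clamped and penalized.
#'
#' @param problem a [fit_problem()]
#' @param model function(named numeric parameter vector) -> named numeric
#'   predictions covering `problem$targets$observable`
#' @param tol relative simplex-spread termination tolerance
#' @param restarts maximum number of simplex restarts
#' @param step initial simplex step (in transformed units)
#' @return list with `par` (named, natural scale), `value` (final RMS error),
#'   `initial_value`, `evaluations`, `converged`, `simplex_spread`,
#'   `restarts_used`, `trace` (best-so-far error per evaluation)
#' @export
fit_simplex <- function(problem, model, tol = 1e-6, restarts = 4, step = 0.25) {
  ob <- make_objective(problem, model)
  free <- problem$free
  z0 <- transform_par(free$init, free$log_scale)
  budget <- problem$max_evaluations
  f0 <- ob$f(z0)
  best <- list(z = z0, f = f0)
  spread <- NA_real_
  used_restarts <- 0L
  for (r in seq_len(restarts + 1)) {
    remaining <- budget - ob$counter$n
    if (remaining < 2 * length(z0)) break
    out <- nelder_mead(ob$f, best$z, f0 = best$f, step = step,
                       tol = tol, max_eval = remaining)
    spread <- out$spread
    improved <- out$f < best$f * (1 - 1e-3) - 1e-12
    if (out$f < best$f) best <- list(z = out$z, f = out$f)
    if (r > 1) used_restarts <- used_restarts + 1L
    if (!improved && r > 1) break
    step <- step / 2
  }
  trace <- cummin(ob$counter$trace)
  list(par = setNames(untransform_par(pmin(pmax(best$z, ob$lo), ob$hi),
                                      free$log_scale), free$name),
       value = best$f, initial_value = f0,
       evaluations = ob$counter$n,
       converged = is.finite(spread) && spread < tol,
       simplex_spread = spread, restarts_used = used_restarts,
       trace = trace)
}

## plain downhill simplex; returns best vertex, value, final spread
nelder_mead <- function(f, z0, f0 = NULL, step = 0.25, tol = 1e-6,
                        max_eval = 1000) {
  n <- length(z0)
  alpha <- 1; gamma <- 2; rho <- 0.5; sigma <- 0.5
  V <- matrix(rep(z0, n + 1), nrow = n)
  for (i in seq_len(n)) V[i, i + 1] <- V[i, i + 1] + step
  used <- 0L
  fv <- numeric(n + 1)
  fv[1] <- if (is.null(f0)) { used <- used + 1L; f(V[, 1]) } else f0
  for (i in 2:(n + 1)) { fv[i] <- f(V[, i]); used <- used + 1L }
  spread <- function() {
    fr <- (max(fv) - min(fv)) / max(abs(min(fv)), 1e-12)
    xr <- max(abs(V - V[, which.min(fv)])) / max(max(abs(V)), 1e-12)
    max(fr, xr)
  }
  while (used < max_eval && spread() > tol) {
    o <- order(fv)
    V <- V[, o, drop = FALSE]; fv <- fv[o]
    centroid <- rowMeans(V[, 1:n, drop = FALSE])
    xr <- centroid + alpha * (centroid - V[, n + 1])
    fr <- f(xr); used <- used + 1L
    if (fr < fv[1]) {
      xe <- centroid + gamma * (xr - centroid)
      fe <- f(xe); used <- used + 1L
      if (fe < fr) { V[, n + 1] <- xe; fv[n + 1] <- fe }
      else { V[, n + 1] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      V[, n + 1] <- xr; fv[n + 1] <- fr
    } else {
      xc <- centroid + rho * (V[, n + 1] - centroid)
      fc <- f(xc); used <- used + 1L
      if (fc < fv[n + 1]) { V[, n + 1] <- xc; fv[n + 1] <- fc }
      else {
        for (i in 2:(n + 1)) {
          V[, i] <- V[, 1] + sigma * (V[, i] - V[, 1])
          fv[i] <- f(V[, i]); used <- used + 1L
          if (used >= max_eval) break
        }
      }
    }
  }
  i <- which.min(fv)
  list(z = V[, i], f = fv[i], spread = spread(), evaluations = used)
}

#' Monte Carlo (random search) identification
#'
#' Draws `max_evaluations` parameter vectors uniformly (log-uniformly for
#' parameters flagged `log_scale`) within their bounds and returns the best.
#' Deterministic for a fixed `problem$seed`; the caller's RNG state is
#' restored.
#'
#' @param problem a [fit_problem()] with finite bounds and a seed
#' @param model as in [fit_simplex()]
#' @return list with `par`, `value`, `evaluations`, `seed`, `trace`
#'   (best-so-far error per draw)
#' @export
fit_monte_carlo <- function(problem, model) {
  if (is.null(problem$seed)) stop_config("Monte Carlo mode requires a seed")
  free <- problem$free
  if (any(!is.finite(free$lower)) || any(!is.finite(free$upper)))
    stop_config("Monte Carlo mode requires finite bounds")
  lo <- transform_par(free$lower, free$log_scale)
  hi <- transform_par(free$upper, free$log_scale)
  obs <- problem$targets$ref
  w <- problem$targets$weight
  n <- problem$max_evaluations
  draws <- with_seed(problem$seed,
                     matrix(runif(n * nrow(free)), nrow = n))
  best <- NULL
  trace <- numeric(n)
  for (i in seq_len(n)) {
    z <- lo + draws[i, ] * (hi - lo)
    par <- setNames(untransform_par(z, free$log_scale), free$name)
    val <- tryCatch({
      pred <- model(par)
      pred <- pred[match(problem$targets$observable, names(pred))]
      rms_error(pred, obs, w, relative = problem$relative)
    }, error = function(e) Inf)
    if (is.null(best) || val < best$value) best <- list(par = par, value = val)
    trace[i] <- best$value
  }
  c(best, list(evaluations = n, seed = problem$seed, trace = trace))
}
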