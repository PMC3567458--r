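## Pre-administration steady state: long-horizon stiff integration followed
## by a damped-Newton root polish on the dynamic states (cumulative
## bookkeeping states are pure integrals and excluded). The residual measure
## is max over states of |dA/dt| / max(A, eps) in 1/min.

ss_residual <- function(f, y, eps = 1e-9) max(abs(f) / pmax(abs(y), eps))

## smooth merit for the Newton line search (2-norm of the scaled residual)
ss_merit <- function(f, y, eps = 1e-9) sqrt(sum((f / pmax(abs(y), eps))^2))

#' Solve for the pre-administration steady state
#'
#' Integrates the assembled system from `init` (default: the literature
#' reference state, [reference_state()]) over a long horizon and then
#' polishes the root of the right-hand side with a damped Newton iteration
#' using a forward-difference Jacobian. Drug states are held at zero: with no
#' dose the drug subsystem's fixed point is identically zero and the Newton
#' step preserves it.
#'
#' @param system a `raas_system`
#' @param init optional initial state (named numeric, umol)
#' @param horizon integration horizon per round (min), default 5000 (well
#'   beyond ten times the longest half-life chain)
#' @param tol convergence tolerance on max |dA/dt| / max(A, eps) (1/min)
#' @param eps floor (umol) in the relative residual denominator
#' @param max_rounds maximum integrate-then-polish rounds before failing
#' @return steady state (named numeric, class `raas_state`) with attributes
#'   `residual`, `converged`, `rounds`
#' @export
solve_steady_state <- function(system, init = NULL, horizon = 5000,
                               tol = 1e-9, eps = 1e-9, max_rounds = 4) {
  y <- as.numeric(init %||% system$reference_state)
  names(y) <- system$state_names
  dyn <- which(!(system$state_names %in% system$cumulative_states))
  f_of <- function(y) system$rhs(0, y, NULL)[[1]]

  ## Newton directly from the initial guess (cheap when warm-started);
  ## fall back to integrate-then-polish rounds with growing horizon when the
  ## guess lies outside the Newton basin.
  rounds <- 0L
  y_try <- newton_polish(f_of, y, dyn, tol = tol, eps = eps)
  res <- ss_residual(f_of(y_try)[dyn], y_try[dyn], eps)
  if (res < tol && all(y_try[dyn] > -1e-12)) {
    y <- y_try
  } else {
    repeat {
      rounds <- rounds + 1L
      sol <- deSolve::lsoda(y, times = c(0, horizon * rounds),
                            func = system$rhs, parms = NULL,
                            rtol = 1e-6, atol = 1e-13, maxsteps = 50000)
      y <- sol[nrow(sol), -1]
      y <- newton_polish(f_of, y, dyn, tol = tol, eps = eps)
      res <- ss_residual(f_of(y)[dyn], y[dyn], eps)
      if (res < tol || rounds >= max_rounds) break
    }
  }
  if (res >= tol) {
    f <- f_of(y)
    worst <- which.max(abs(f[dyn]) / pmax(abs(y[dyn]), eps))
    stop("steady state did not converge: residual ", format(res, digits = 3),
         " 1/min; worst state ", system$state_names[dyn][worst])
  }
  structure(setNames(pmax(y, 0), system$state_names), class = "raas_state",
            residual = res, converged = TRUE, rounds = rounds)
}

## damped Newton on the dynamic sub-block; returns y possibly improved.
## Line search uses the smooth 2-norm merit; convergence is checked on the
## max-norm residual. The Jacobian is reused across consecutive iterations
## while the merit is dropping fast (chord iterations).
newton_polish <- function(f_of, y, dyn, tol, eps, max_iter = 30) {
  f <- f_of(y)
  merit <- ss_merit(f[dyn], y[dyn], eps)
  J_lu <- NULL
  fresh <- FALSE
  for (it in seq_len(max_iter)) {
    if (ss_residual(f[dyn], y[dyn], eps) < tol * 0.1) break
    if (is.null(J_lu)) {
      J <- num_jacobian(f_of, y, dyn, f)
      J_lu <- tryCatch(lu_factor(J), error = function(e) NULL)
      if (is.null(J_lu)) break
      fresh <- TRUE
    }
    step <- tryCatch(lu_solve(J_lu, -f[dyn]), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    improved <- FALSE
    lambda <- 1
    for (k in 1:9) {
      cand <- y
      cand[dyn] <- y[dyn] + lambda * step
      if (all(cand[dyn] > -1e-12)) {
        fc <- f_of(cand)
        mc <- ss_merit(fc[dyn], cand[dyn], eps)
        if (is.finite(mc) && mc < merit) {
          ## refresh the Jacobian when progress is slow or the step was damped
          if (lambda < 1 || mc > 0.2 * merit) J_lu <- NULL
          y <- cand; f <- fc; merit <- mc; improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    fresh_now <- fresh
    fresh <- FALSE
    if (!improved) {
      if (!fresh_now) { J_lu <- NULL; next }  # retry with a fresh Jacobian
      break
    }
  }
  y
}

lu_factor <- function(J) {
  qr(J, LAPACK = TRUE)
}
lu_solve <- function(fac, b) {
  solve.qr(fac, b)
}

num_jacobian <- function(f_of, y, dyn, f0) {
  n <- length(dyn)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- max(1e-7 * abs(y[dyn[j]]), 1e-13)
    yp <- y
    yp[dyn[j]] <- yp[dyn[j]] + h
    J[, j] <- (f_of(yp)[dyn] - f0[dyn]) / h
  }
  J
}

#' Concentration of a species in a compartment
#'
#' @param system a `raas_system`
#' @param state a state vector (`raas_state`) or a trajectory state matrix row
#' @param species species name (e.g. `"ang2"`, `"enaat"`)
#' @param compartment compartment name, default the venous pool
#' @return concentration (umol/L)
#' @export
state_concentration <- function(system, state, species,
                                compartment = "venous_blood") {
  nm <- paste0(species, ".", compartment)
  i <- match(nm, system$state_names)
  if (is.na(i)) stop_config("no state named ", nm)
  vol <- compartment_volume(system, compartment)
  as.numeric(state[i]) / vol
}

compartment_volume <- function(system, compartment) {
  if (compartment == "liver_cell") return(system$body$v_liver_cell)
  if (compartment == "kidney_cell") return(system$body$v_kidney_cell)
  j <- match(compartment, system$index$comps)
  if (is.na(j)) stop_config("unknown compartment: ", compartment)
  system$index$V0[j]
}

#' Venous plasma concentrations of the RAAS species
#'
#' @param system a `raas_system`
#' @param state a steady state or trajectory row
#' @return named vector (umol/L) over the six circulating hormones
#' @export
venous_concentrations <- function(system, state) {
  sp <- intersect(c("agt", "renin", "prorenin", "ang1", "ang2", "aldosterone"),
                  system$index$species)
  setNames(vapply(sp, function(s) state_concentration(system, state, s),
                  numeric(1)), sp)
}
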