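## Dose-event simulation. Dose events are discontinuous depot/pool increments
## handled by the integrator's event mechanism (an exact restart at the event
## time, no smoothing), so trajectories are deterministic for fixed inputs.

#' Simulate the coupled system
#'
#' Integrates the assembled ODE system from an initial state over a time
#' grid, applying dose events (oral enalapril into the gut depot, intravenous
#' enalaprilat into the venous pool).
#'
#' @param system a `raas_system`
#' @param initial initial state (default [reference_state()]; typically a
#'   [solve_steady_state()] result for pre-administration protocols)
#' @param doses list of [dose_event()] records (times within the horizon)
#' @param horizon simulation end time (min)
#' @param dt output grid spacing (min)
#' @param times explicit output times (overrides `horizon`/`dt`)
#' @return object of class `raas_trajectory`: list with `times`, `states`
#'   (time x state matrix of amounts in umol), `system`, `metadata`
#'   (parameter/input hash, solver settings)
#' @export
#' @examples
#' \donttest{
#' sys <- assemble_system(build_reference_body(), raas_params(), drug_params(),
#'                        system_options(include_raas = TRUE, include_drug = TRUE))
#' ss <- solve_steady_state(sys)
#' tr <- simulate_trajectory(sys, ss, doses = list(dose_event(1500, 10)),
#'                           horizon = 3000, dt = 10)
#' }
simulate_trajectory <- function(system, initial = NULL, doses = list(),
                                horizon = 3000, dt = 5, times = NULL) {
  if (inherits(doses, "dose_event")) doses <- list(doses)
  y0 <- as.numeric(initial %||% system$reference_state)
  names(y0) <- system$state_names
  if (is.null(times)) {
    if (horizon <= 0) stop_domain("horizon must be > 0")
    times <- seq(0, horizon, by = dt)
  }
  ev <- NULL
  if (length(doses)) {
    ev <- do.call(rbind, lapply(doses, function(d) {
      if (!inherits(d, "dose_event")) stop_config("doses must be dose_event records")
      if (d$time > max(times)) stop_config("dose at t = ", d$time,
                                           " lies beyond the horizon")
      if (d$compound == "ena") {
        var <- if (d$route == "oral") "ena.gut" else "ena.venous_blood"
        mw <- system$drug$ena$molecular_weight_g_mol
      } else {
        var <- "enaat.venous_blood"
        mw <- system$drug$enaat$molecular_weight_g_mol
      }
      if (!var %in% system$state_names)
        stop_config("system was assembled without the drug model; cannot dose")
      data.frame(var = var, time = d$time,
                 value = dose_mg_to_umol(d$amount_mg, mw), method = "add")
    }))
    times <- sort(unique(c(times, ev$time)))
  }
  sol <- deSolve::lsoda(y0, times = times, func = system$rhs, parms = NULL,
                        rtol = system$options$rtol, atol = system$options$atol,
                        maxsteps = 100000,
                        events = if (is.null(ev)) NULL else list(data = ev))
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- system$state_names
  meta <- list(
    hash = object_hash(list(y0 = y0, doses = doses, times = times,
                            rtol = system$options$rtol,
                            atol = system$options$atol,
                            raas = system$raas, drug = system$drug,
                            subject = unclass(system$subject))),
    solver = list(method = "lsoda", rtol = system$options$rtol,
                  atol = system$options$atol))
  structure(list(times = sol[, 1], states = states, system = system,
                 metadata = meta), class = "raas_trajectory")
}

#' @export
print.raas_trajectory <- function(x, ...) {
  cat("<raas_trajectory>", length(x$times), "time points, ",
      ncol(x$states), "states, t in [", min(x$times), ",", max(x$times), "] min\n")
  invisible(x)
}

#' Concentration time course from a trajectory
#'
#' @param traj a `raas_trajectory`
#' @param species species name
#' @param compartment compartment name (default venous pool)
#' @return numeric vector (umol/L) along `traj$times`
#' @export
concentration_course <- function(traj, species, compartment = "venous_blood") {
  nm <- paste0(species, ".", compartment)
  i <- match(nm, traj$system$state_names)
  if (is.na(i)) stop_config("no state named ", nm)
  traj$states[, i] / compartment_volume(traj$system, compartment)
}

#' Tidy data frame of a trajectory
#'
#' Long format with one row per (time, species, compartment). Bookkeeping
#' states (gut depot, cumulative cleared/unabsorbed amounts) are omitted;
#' complexes and intracellular pools are reported as concentrations over
#' their compartment volumes.
#'
#' @param x a `raas_trajectory`
#' @param row.names,optional,... ignored (data.frame method signature)
#' @return data.frame with columns `time_min`, `species`, `compartment`,
#'   `concentration_umol_per_L`
#' @export
as.data.frame.raas_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  keep <- setdiff(x$system$state_names,
                  c("ena.gut", x$system$cumulative_states))
  out <- do.call(rbind, lapply(keep, function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    sp <- parts[1]; comp <- paste(parts[-1], collapse = ".")
    data.frame(time_min = x$times, species = sp, compartment = comp,
               concentration_umol_per_L =
                 x$states[, nm] / compartment_volume(x$system, comp))
  }))
  rownames(out) <- NULL
  out
}

#' Write a trajectory to CSV
#'
#' @param traj a `raas_trajectory`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
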