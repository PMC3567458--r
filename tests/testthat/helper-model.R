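# Shared fixtures, built in code. Heavier objects are memoised per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

ref_body <- function() memo("body", build_reference_body())
ref_params <- function() memo("params", raas_params())
ref_drug <- function() memo("drug", drug_params())

ref_species <- c("agt", "renin", "prorenin", "ang1", "ang2", "aldosterone")

ref_concs <- function() {
  p <- ref_params()
  vapply(ref_species, function(s) p[[s]]$reference_plasma_conc, numeric(1))
}

raas_system <- function() memo("raas_sys", assemble_system(ref_body(), ref_params()))

raas_steady <- function() memo("raas_ss", solve_steady_state(raas_system()))

coupled_system <- function(ace_binding = TRUE) {
  memo(paste0("coupled_", ace_binding),
       assemble_system(ref_body(), ref_params(), ref_drug(),
                       system_options(include_raas = TRUE, include_drug = TRUE,
                                      ace_binding = ace_binding)))
}

drug_only_system <- function(ace_binding = TRUE) {
  memo(paste0("drugonly_", ace_binding),
       assemble_system(ref_body(), ref_params(), ref_drug(),
                       system_options(include_raas = FALSE, include_drug = TRUE,
                                      ace_binding = ace_binding,
                                      rtol = 1e-8, atol = 1e-12)))
}

## total amount of a plasma-circulating species over all compartments
species_total <- function(system, state, species) {
  sum(state[grep(paste0("^", species, "\\."), system$state_names)])
}

## log-linear terminal slope of a concentration course over a time window
terminal_slope <- function(times, conc, window) {
  keep <- times >= window[1] & times <= window[2] & conc > 0
  stats::coef(stats::lm(log(conc[keep]) ~ times[keep]))[[2]]
}
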