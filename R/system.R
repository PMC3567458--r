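## Assembly of the coupled ODE system over the body model. State variables
## are molar amounts (umol) per (species, compartment) pair:
##   - plasma amounts for every circulating species in all 17 compartments,
##   - AT1-Ang2 and ACE-Enaat complexes per expressing organ,
##   - intracellular pools (hepatic AGT, renal prorenin, hepatocyte Ena/Enaat),
##   - the oral gut depot and cumulative bookkeeping states for mass audits.
## Every derivative term is attributable to exactly one rate-law function and
## is recorded in the introspectable term registry (`system$terms`).

#' Simulator options
#'
#' @param include_raas include the hormone cascade (default TRUE)
#' @param include_drug include the enalapril/enalaprilat model
#' @param ace_binding enable reversible Enaat-ACE binding (the drug's mode of
#'   action); disabling it is useful to expose the terminal-phase mechanism
#' @param transport enable convective plasma transport
#' @param reactions enable all reaction/secretion/clearance terms (disable
#'   together with `degradation` for pure-transport conservation checks)
#' @param degradation enable first-order plasma degradation
#' @param aldosterone_drive which AT1-Ang2 complex pool drives aldosterone
#'   synthesis: plasma-volume-weighted whole-body mean (default) or kidney only
#' @param rtol,atol solver tolerances (amounts in umol)
#' @return list of class `system_options`
#' @export
system_options <- function(include_raas = TRUE, include_drug = FALSE,
                           ace_binding = TRUE, transport = TRUE,
                           reactions = TRUE, degradation = TRUE,
                           aldosterone_drive = c("whole_body", "kidney"),
                           rtol = 1e-8, atol = 1e-12) {
  structure(list(include_raas = include_raas, include_drug = include_drug,
                 ace_binding = ace_binding, transport = transport,
                 reactions = reactions, degradation = degradation,
                 aldosterone_drive = match.arg(aldosterone_drive),
                 rtol = rtol, atol = atol), class = "system_options")
}

#' Assemble the coupled RAAS + drug ODE system
#'
#' Builds the deterministic right-hand side over a [build_reference_body()]
#' compartment graph. Free ACE and free AT1 are represented as expressed
#' total minus complex, so receptor/enzyme conservation holds by
#' construction. Zero-order synthesis rates for the intracellular AGT and
#' prorenin pools are computed here from the reference plasma concentrations
#' under the current parameters (steady-state closure) and then frozen.
#'
#' @param body a `body_model`
#' @param raas RAAS parameters ([raas_params()]); NULL to omit the cascade
#' @param drug drug parameters ([drug_params()]); NULL to omit the drug model
#' @param options a [system_options()] list
#' @return object of class `raas_system` with elements `rhs(t, y, parms)`,
#'   `state_names`, `reference_state`, `terms` (term registry), `index`,
#'   `closure`, `body`, `raas`, `drug`, `options`
#' @export
assemble_system <- function(body = build_reference_body(),
                            raas = raas_params(), drug = NULL,
                            options = NULL) {
  if (!inherits(body, "body_model")) stop_config("body must be a body_model")
  if (is.null(options))
    options <- system_options(include_raas = !is.null(raas),
                              include_drug = !is.null(drug))
  if (options$include_raas && is.null(raas))
    stop_config("RAAS parameters required: supply raas_params() (see the shipped parameter file for the expected fields)")
  if (options$include_drug && is.null(drug))
    stop_config("drug parameters required: supply drug_params()")
  if (!options$include_raas && !options$include_drug)
    stop_config("nothing to assemble: enable the RAAS and/or the drug model")

  comp <- body$compartments
  ncomp <- nrow(comp)
  comps <- comp$organ
  V0 <- comp$plasma_volume_L
  hct <- body$hematocrit
  Qp <- comp$blood_flow_L_per_min * (1 - hct)  # plasma flows
  i_art <- match("arterial_blood", comps)
  i_ven <- match("venous_blood", comps)
  i_lung <- match("lung", comps)
  i_kid <- match("kidney", comps)
  i_liv <- match("liver", comps)
  parallel <- which(!(comps %in% c("arterial_blood", "venous_blood", "lung")))
  subj <- body$subject

  ## convective transport matrix: dA = M %*% C (C in umol/L, dA in umol/min)
  M <- matrix(0, ncomp, ncomp)
  for (i in parallel) {
    M[i, i_art] <- M[i, i_art] + Qp[i]
    M[i, i] <- M[i, i] - Qp[i]
    M[i_ven, i] <- M[i_ven, i] + Qp[i]
  }
  qp_tot <- sum(Qp[parallel])
  M[i_ven, i_ven] <- M[i_ven, i_ven] - qp_tot
  M[i_lung, i_ven] <- M[i_lung, i_ven] + qp_tot
  M[i_lung, i_lung] <- M[i_lung, i_lung] - qp_tot
  M[i_art, i_lung] <- M[i_art, i_lung] + qp_tot
  M[i_art, i_art] <- M[i_art, i_art] - qp_tot

  ## expressed ACE per compartment (used by the Ang1->Ang2 conversion and as
  ## the Enaat binding target); the binding constants live in the RAAS ACE
  ## block, with the printed defaults as fallback for a drug-only system
  ace_tot <- expressed_concentration(subj$ace_c_ref, comp$ace_expression_pct)
  drugp_kon <- if (!is.null(raas)) raas$ace$k_on else 35.16
  drugp_koff <- if (!is.null(raas)) raas$ace$k_off else 2.15e-2

  species <- c(if (options$include_raas)
                 c("agt", "renin", "prorenin", "ang1", "ang2", "aldosterone"),
               if (options$include_drug) c("ena", "enaat"))
  nspecies <- length(species)
  plasma_names <- as.vector(outer(comps, species, function(co, sp) paste0(sp, ".", co)))
  state_names <- plasma_names
  terms <- list()
  reg <- function(op, species, compartment, note = NULL) {
    terms[[length(terms) + 1L]] <<- list(op = op, species = species,
                                         compartment = compartment, note = note)
  }
  for (sp in species) reg("convective_transport_rate", sp, "all")

  at1_idx <- integer(0); ace_idx <- integer(0)
  if (options$include_raas) {
    at1_idx <- which(comp$at1_expression_pct > 0)
    state_names <- c(state_names, paste0("at1_complex.", comps[at1_idx]),
                     "agt.liver_cell", "prorenin.kidney_cell")
  }
  if (options$include_drug) {
    ace_idx <- which(comp$ace_expression_pct > 0)
    state_names <- c(state_names, paste0("ace_complex.", comps[ace_idx]),
                     "ena.gut", "ena.liver_cell", "enaat.liver_cell",
                     "ena.unabsorbed", "ena.cleared_renal",
                     "ena.cleared_hepatic", "ena.converted",
                     "enaat.cleared_renal")
  }
  nstate <- length(state_names)
  nm <- function(x) match(x, state_names)
  nplasma <- ncomp * nspecies
  col_of <- function(sp) match(sp, species)

  idx <- list(plasma = seq_len(nplasma), species = species, comps = comps,
              V0 = V0, ncomp = ncomp)
  cumulative <- character(0)

  ## ---- RAAS constants -------------------------------------------------
  if (options$include_raas) {
    rs <- raas
    raas_cols <- match(c("agt", "renin", "prorenin", "ang1", "ang2",
                         "aldosterone"), species)
    kdeg <- log(2) / c(rs$agt$t_half, rs$renin$t_half, rs$prorenin$t_half,
                       rs$ang1$t_half, rs$ang2$t_half, rs$aldosterone$t_half)
    kdeg_mat <- outer(V0, kdeg)  # ncomp x 6, umol/min per unit concentration
    at1_tot <- expressed_concentration(rs$at1$c_ref, comp$at1_expression_pct)
    idx$at1_complex <- nm(paste0("at1_complex.", comps[at1_idx]))
    idx$agt_cell <- nm("agt.liver_cell")
    idx$prorenin_cell <- nm("prorenin.kidney_cell")
    i_agt <- col_of("agt"); i_renin <- col_of("renin")
    i_pro <- col_of("prorenin"); i_ang1 <- col_of("ang1")
    i_ang2 <- col_of("ang2"); i_aldo <- col_of("aldosterone")

    for (sp in c("agt", "renin", "prorenin", "ang1", "ang2", "aldosterone"))
      reg("degradation_rate", sp, "all")
    reg("mm_conversion_rate", "agt->ang1", "all", "renin-catalysed")
    reg("mm_conversion_rate", "ang1->ang2", "all", "ACE-catalysed, free ACE")
    for (o in comps[at1_idx]) reg("binding_rate", "ang2:at1", o)
    reg("prorenin_activation_rate", "prorenin->renin", "kidney")
    reg("secretion_rate", "prorenin", "kidney")
    reg("secretion_rate", "agt", "liver")
    reg("aldosterone_synthesis_rate", "aldosterone", "venous_blood")

    ## steady-state closure: zero-order synthesis balancing the reference state
    Vtot <- sum(V0)
    ref <- c(agt = rs$agt$reference_plasma_conc,
             renin = rs$renin$reference_plasma_conc,
             prorenin = rs$prorenin$reference_plasma_conc,
             ang1 = rs$ang1$reference_plasma_conc,
             ang2 = rs$ang2$reference_plasma_conc,
             aldosterone = rs$aldosterone$reference_plasma_conc)
    r5_ref <- mm_conversion_rate(rs$renin$kcat, rs$renin$km, Vtot,
                                 ref[["renin"]], ref[["agt"]])
    synth_agt <- degradation_rate(ref[["agt"]], rs$agt$t_half) * Vtot + r5_ref
    c_agt_cell_ref <- synth_agt / rs$agt$k_secretion
    r3_ref <- prorenin_activation_rate(rs$prorenin$vmax_kid, rs$prorenin$km_kid,
                                       rs$ang2$k_inhibition, body$v_kidney_cell,
                                       rs$prorenin$c_cell_ref, ref[["ang2"]])
    synth_pro <- r3_ref + secretion_rate(rs$prorenin$k_secretion,
                                         rs$prorenin$c_cell_ref)
    closure <- list(synthesis_agt = synth_agt, synthesis_prorenin = synth_pro,
                    c_agt_cell_ref = c_agt_cell_ref,
                    reference_conc = ref)
  } else closure <- NULL

  ## ---- drug constants -------------------------------------------------
  if (options$include_drug) {
    idx$ace_complex <- nm(paste0("ace_complex.", comps[ace_idx]))
    idx$gut <- nm("ena.gut")
    idx$ena_cell <- nm("ena.liver_cell")
    idx$enaat_cell <- nm("enaat.liver_cell")
    i_unabs <- nm("ena.unabsorbed"); i_ren_e <- nm("ena.cleared_renal")
    i_hep_e <- nm("ena.cleared_hepatic"); i_conv <- nm("ena.converted")
    i_ren_a <- nm("enaat.cleared_renal")
    cumulative <- c("ena.unabsorbed", "ena.cleared_renal",
                    "ena.cleared_hepatic", "ena.converted",
                    "enaat.cleared_renal")
    i_ena <- col_of("ena"); i_enaat <- col_of("enaat")
    ka <- drug$absorption$ka; f_abs <- drug$absorption$f_abs
    ps_liv <- drug$permeation$ps_liver
    korg_ena <- drug$ena$k_org; korg_enaat <- drug$enaat$k_org
    cl_hep <- drug$ena$hepatic_clearance_ml_min / 1000  # L/min
    km_liv <- raas$carboxylesterase$km_liv %||% 710

    reg("oral_absorption_rate", "ena", "gut")
    reg("hepatic_conversion_rate", "ena->enaat", "liver")
    reg("renal_clearance_rate", "ena", "kidney")
    reg("renal_clearance_rate", "enaat", "kidney")
    reg("secretion_rate", "ena hepatic clearance", "liver",
        "linear intrinsic clearance on hepatocyte Ena")
    if (options$ace_binding)
      for (o in comps[ace_idx]) reg("binding_rate", "enaat:ace", o)
  }

  flag_transport <- options$transport
  flag_deg <- options$degradation
  flag_rxn <- options$reactions
  flag_bind <- options$ace_binding
  aldo_whole <- options$aldosterone_drive == "whole_body"
  include_raas <- options$include_raas
  include_drug <- options$include_drug
  v_kid_cell <- body$v_kidney_cell
  v_liv_cell <- body$v_liver_cell
  Vtot_plasma <- sum(V0)
  i_plasma <- seq_len(nplasma)
  dimC <- c(ncomp, nspecies)
  inv_V0rep <- rep(1 / V0, nspecies)

  ## hoist every parameter the derivative needs into closure locals (the
  ## right-hand side is the hot loop of every solve)
  if (include_raas) {
    kcat_renin <- raas$renin$kcat; km_renin <- raas$renin$km
    kcat_ace <- raas$ace$kcat; km_ace <- raas$ace$km
    kon_at1 <- raas$at1$k_on; koff_at1 <- raas$at1$k_off
    at1_tot_e <- at1_tot[at1_idx]; V0_at1 <- V0[at1_idx]
    vmax_kid <- raas$prorenin$vmax_kid; km_kid <- raas$prorenin$km_kid
    k_inh <- raas$ang2$k_inhibition
    ksec_pro <- raas$prorenin$k_secretion
    ksec_agt <- raas$agt$k_secretion
    ksec_aldo <- raas$aldosterone$k_secretion
    kprod_aldo <- raas$aldosterone$k_production
    synth_pro_c <- closure$synthesis_prorenin
    synth_agt_c <- closure$synthesis_agt
    i_at1c <- idx$at1_complex; i_procell <- idx$prorenin_cell
    i_agtcell <- idx$agt_cell
    at1_kid_pos <- match(i_kid, at1_idx)
  }
  if (include_drug) {
    i_acec <- idx$ace_complex; i_gut <- idx$gut
    i_enacell <- idx$ena_cell; i_enaatcell <- idx$enaat_cell
    ace_tot_e <- ace_tot[ace_idx]; V0_ace <- V0[ace_idx]
    vmax_liv <- subj$vmax_liv
    cl_ren_ena <- subj$renal_clearance_ena * subj$body_weight
    cl_ren_enaat <- subj$renal_clearance_enaat * subj$body_weight
  }

  rhs <- function(t, y, parms) {
    y <- as.numeric(y)  # drop names: plain doubles in the hot path
    dy <- numeric(nstate)
    C <- y[i_plasma] * inv_V0rep
    dim(C) <- dimC
    dA <- if (flag_transport) M %*% C else matrix(0, ncomp, nspecies)

    if (include_raas) {
      if (flag_deg)
        dA[, raas_cols] <- dA[, raas_cols] - C[, raas_cols] * kdeg_mat
      if (flag_rxn) {
        c_agt <- C[, i_agt]; c_ang1 <- C[, i_ang1]
        ## renin-catalysed AGT -> Ang1 in every plasma compartment
        r5 <- kcat_renin * V0 * C[, i_renin] * c_agt / (c_agt + km_renin)
        ## ACE-catalysed Ang1 -> Ang2; C0 is free (unblocked) ACE
        free_ace_conc <- if (include_drug && flag_bind) {
          fa <- ace_tot
          fa[ace_idx] <- fa[ace_idx] - y[i_acec] / V0_ace
          fa
        } else ace_tot
        r6 <- kcat_ace * V0 * free_ace_conc * c_ang1 / (c_ang1 + km_ace)
        dA[, i_agt] <- dA[, i_agt] - r5
        dA[, i_ang1] <- dA[, i_ang1] + r5 - r6
        dA[, i_ang2] <- dA[, i_ang2] + r6
        ## AT1 binding per expressing organ
        ccplx <- y[i_at1c] / V0_at1
        r7A <- (kon_at1 * (at1_tot_e - ccplx) * C[at1_idx, i_ang2] -
                  koff_at1 * ccplx) * V0_at1
        dy[i_at1c] <- r7A
        dA[at1_idx, i_ang2] <- dA[at1_idx, i_ang2] - r7A
        ## renal prorenin pool: activation (-> plasma renin) and secretion
        c_pro_cell <- y[i_procell] / v_kid_cell
        r3 <- vmax_kid * v_kid_cell * c_pro_cell /
          (c_pro_cell + km_kid * (1 + C[i_kid, i_ang2] / k_inh))
        r2p <- ksec_pro * c_pro_cell
        dy[i_procell] <- synth_pro_c - r3 - r2p
        dA[i_kid, i_renin] <- dA[i_kid, i_renin] + r3
        dA[i_kid, i_pro] <- dA[i_kid, i_pro] + r2p
        ## hepatic AGT pool
        sec_agt <- ksec_agt * y[i_agtcell] / v_liv_cell
        dy[i_agtcell] <- synth_agt_c - sec_agt
        dA[i_liv, i_agt] <- dA[i_liv, i_agt] + sec_agt
        ## aldosterone synthesis driven by the AT1-Ang2 complex pool
        c_drive <- if (aldo_whole) sum(y[i_at1c]) / Vtot_plasma
                   else y[i_at1c[at1_kid_pos]] / V0[i_kid]
        dA[i_ven, i_aldo] <- dA[i_ven, i_aldo] +
          ksec_aldo * c_drive + kprod_aldo
      }
    }

    if (include_drug && flag_rxn) {
      out <- ka * y[i_gut]
      dy[i_gut] <- -out
      dy[i_unabs] <- (1 - f_abs) * out
      ## hepatocyte permeation, conversion, intrinsic clearance
      c_ena_cell <- y[i_enacell] / v_liv_cell
      c_enaat_cell <- y[i_enaatcell] / v_liv_cell
      flux_ena <- ps_liv * (C[i_liv, i_ena] - c_ena_cell / korg_ena)
      flux_enaat <- ps_liv * (C[i_liv, i_enaat] - c_enaat_cell / korg_enaat)
      conv <- vmax_liv * v_liv_cell * c_ena_cell / (c_ena_cell + km_liv)
      hep <- cl_hep * c_ena_cell
      dA[i_liv, i_ena] <- dA[i_liv, i_ena] + f_abs * out - flux_ena
      dA[i_liv, i_enaat] <- dA[i_liv, i_enaat] - flux_enaat
      dy[i_enacell] <- flux_ena - conv - hep
      dy[i_enaatcell] <- flux_enaat + conv
      dy[i_conv] <- conv
      dy[i_hep_e] <- hep
      ## renal clearance on kidney plasma
      ren_e <- cl_ren_ena * C[i_kid, i_ena]
      ren_a <- cl_ren_enaat * C[i_kid, i_enaat]
      dA[i_kid, i_ena] <- dA[i_kid, i_ena] - ren_e
      dA[i_kid, i_enaat] <- dA[i_kid, i_enaat] - ren_a
      dy[i_ren_e] <- ren_e
      dy[i_ren_a] <- ren_a
      ## ACE sequestration by Enaat (mode of action)
      if (flag_bind) {
        ccx <- y[i_acec] / V0_ace
        rbA <- (drugp_kon * (ace_tot_e - ccx) * C[ace_idx, i_enaat] -
                  drugp_koff * ccx) * V0_ace
        dy[i_acec] <- rbA
        dA[ace_idx, i_enaat] <- dA[ace_idx, i_enaat] - rbA
      }
    }

    dy[i_plasma] <- dA
    list(dy)
  }

  sys <- structure(list(
    rhs = rhs, state_names = state_names, n_state = nstate,
    index = idx, terms = terms, closure = closure,
    body = body, raas = raas, drug = drug, subject = subj,
    options = options, cumulative_states = cumulative,
    flow_matrix = M
  ), class = "raas_system")
  sys$reference_state <- reference_state(sys)
  sys
}

#' Reference initial state
#'
#' State vector at the literature reference: uniform plasma concentrations at
#' their tabulated steady-state values, intracellular pools at their closure
#' references, AT1 complexes at binding equilibrium with reference
#' angiotensin 2, and zero drug everywhere.
#'
#' @param system a `raas_system`
#' @return named numeric vector of amounts (umol), class `raas_state`
#' @export
reference_state <- function(system) {
  y <- setNames(numeric(system$n_state), system$state_names)
  V0 <- system$index$V0
  comps <- system$index$comps
  if (system$options$include_raas) {
    ref <- system$closure$reference_conc
    for (sp in names(ref))
      y[paste0(sp, ".", comps)] <- ref[[sp]] * V0
    kd <- system$raas$at1$k_off / system$raas$at1$k_on
    at1_tot <- expressed_concentration(system$raas$at1$c_ref,
                                       system$body$compartments$at1_expression_pct)
    occ <- ref[["ang2"]] / (ref[["ang2"]] + kd)
    at1_idx <- which(system$body$compartments$at1_expression_pct > 0)
    y[system$index$at1_complex] <- at1_tot[at1_idx] * occ * V0[at1_idx]
    y["agt.liver_cell"] <- system$closure$c_agt_cell_ref * system$body$v_liver_cell
    y["prorenin.kidney_cell"] <- system$raas$prorenin$c_cell_ref *
      system$body$v_kidney_cell
  }
  structure(y, class = "raas_state")
}

#' @export
print.raas_system <- function(x, ...) {
  cat("<raas_system>", x$n_state, "states over",
      x$index$ncomp, "compartments;",
      if (x$options$include_raas) "RAAS" else "",
      if (x$options$include_drug) "+ Ena/Enaat" else "", "\n")
  cat("  terms:", length(x$terms), "registered rate-law terms\n")
  invisible(x)
}

#' Look up terms in the registry
#'
#' @param system a `raas_system`
#' @param op rate-law function name to filter on (optional)
#' @return list of term descriptors (`op`, `species`, `compartment`, `note`)
#' @export
system_terms <- function(system, op = NULL) {
  t <- system$terms
  if (!is.null(op)) t <- Filter(function(e) e$op == op, t)
  t
}
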