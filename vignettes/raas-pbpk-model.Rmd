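---
title: "Methods: the circulating RAAS PBPK–PD model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the circulating RAAS PBPK-PD model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, its assumptions, the numerical choices
and the design decisions behind `raasim`, at the level of detail a
maintainer or reviewer needs to judge what the package does and does not
claim.

## The model

The circulating renin–angiotensin–aldosterone system is modelled as molar
amounts of AGT, renin, prorenin, angiotensin 1, angiotensin 2 and
aldosterone in the plasma of 17 compartments: 15 organs (brain, fat,
gonads, heart, kidney, large intestine, liver, lung, muscle, pancreas, a
systemic "plasma" compartment, skin, spleen, small intestine, stomach) plus
venous and arterial pools. Organs are perfused in parallel between the
arterial and venous pools; the lung sits in series (venous → lung →
arterial) so that pulmonary ACE — the 100% reference expression site — sees
total cardiac output. All hormones are assumed to circulate only in the
plasma; there are no interstitial or cellular hormone sub-compartments.
Two intracellular pools exist as explicit states because hormones are
secreted from them: hepatic AGT and renal prorenin. Membrane-bound species
(ACE, AT1) do not circulate; their per-organ concentrations are the
expressed fractions of a reference concentration, `C0 = CRef · ERef/100`.
Where the expression table gives both a percentage and an absolute value,
the percentage column is used, because the reference-concentration scaling
is defined on relative expression.

Mechanisms, each implemented as one exported rate-law function and
registered per compartment in the system's term registry:

| mechanism | rate law | location |
|---|---|---|
| convective transport | `Q (1−HCT) C` | all compartments |
| degradation | `C ln2 / t½` | every plasma compartment |
| AGT → Ang1 | Michaelis–Menten, renin as enzyme | every plasma compartment |
| Ang1 → Ang2 | Michaelis–Menten, free ACE as enzyme | every plasma compartment |
| Ang2 + AT1 | mass-action binding | organs with AT1 expression |
| prorenin → renin | competitive-inhibition activation | kidney only |
| secretion | first order in intracellular concentration | AGT: liver; prorenin: kidney |
| aldosterone synthesis | affine in AT1–Ang2 complex | into the venous pool |
| Ena → Enaat | Michaelis–Menten carboxylesterase | hepatocytes |
| Enaat + ACE | mass-action binding (the drug's mode of action) | organs with ACE expression |

Free receptor/enzyme is represented as expressed total minus complex, so
free + complex conservation holds exactly by construction; the tests verify
that complexes stay inside `[0, total]` along dosed trajectories. Bound
species are protected: Ang2 in the AT1 complex and Enaat in the ACE complex
neither degrade nor clear — only dissociation returns them. This is what
produces the prolonged terminal phase of enalaprilat, and the test suite
verifies that disabling ACE binding strictly steepens the terminal slope.
Renin and ACE are catalytic in their conversions: renin is removed only by
degradation, ACE only sequestered by enalaprilat.

## Reduced physiology

The organ plasma volumes and blood flows of the original platform model are
not public, so the package ships its own reference-human table
(`inst/extdata/reference_physiology.csv`): total plasma ≈ 3.0 L and
cardiac output ≈ 6.6 L/min blood for a 70 kg adult, distributed over the
organs in physiologically conventional proportions, scaled linearly with
body weight relative to 70 kg. Hematocrit defaults to 0.47 (adult male
reference). The gut organs drain directly to the venous pool (no portal
step); oral drug absorption deposits into the liver plasma directly, which
preserves first-pass exposure without a portal compartment. Steady-state
hormone balances depend mostly on total plasma volume and relative
expression, which this table preserves; absolute per-organ concentration
gradients inherit its uncertainty. Users can supply their own table
(`build_reference_body(physiology = ...)`).

The expression table's "Plasma" row is kept as its own parallel systemic
compartment carrying its tabulated 6% ACE expression; the venous and
arterial pools carry no expression, avoiding double counting.

## Steady-state closure

Intracellular AGT and prorenin are maintained by zero-order synthesis.
The synthesis rates are computed at assembly time so that the tabulated
reference state is self-consistent under the *current* parameters:
synthesis equals secretion (plus, for prorenin, activation) evaluated at the
reference concentrations. They are then frozen for the integration. This
closure is recomputed for every candidate parameter set during
identification — with synthesis frozen at the default-parameter values the
identification problem would be ill-posed, since no candidate could move the
secreted supply.

A structural consequence, stated openly: the AGT secretion constant and AGT
half-life become non-identifiable from steady-state concentrations alone
(the closure compensates any change), which is why the parameter-recovery
tests draw from the identifiable subset (renin, prorenin, Ang1, ACE and
aldosterone constants).

## Numerical choices

* **Integrator**: `deSolve::lsoda` (stiff, adaptive), `rtol = 1e-8`,
  `atol = 1e-12` µmol by default, exposed in `system_options()`. Half-lives
  span 0.72–12.87 min against multi-day PK horizons, so an implicit method
  is mandatory. The original platform's solver is unknown; numerical
  equivalence is defined by a convergence test (halving both tolerances
  changes reported venous concentrations by far less than 0.1%), not by
  matching a named integrator.
* **Steady state**: Newton is attempted directly from the initial guess
  (cheap when warm-started); if the guess is outside the Newton basin the
  solver falls back to long-horizon integration (5000 min per round,
  growing each round, with looser tolerances — integration is only the
  globalizer) followed by a damped-Newton polish with a forward-difference
  Jacobian and a smooth 2-norm line-search merit. Convergence requires
  `max |dA/dt| / max(A, 1e-9) < 1e-9 min⁻¹` over all dynamic states. The
  slowest system mode at the tabulated parameters has a time constant of
  roughly 2400 min, which is why pure integration is not used for
  convergence. Cumulative bookkeeping states (cleared, unabsorbed,
  converted) are pure integrals and are excluded from the root solve.
* **Dose events**: exact integrator restarts at event times (depot or pool
  increments), no smoothing; trajectories are bit-deterministic for fixed
  inputs, verified via a metadata hash.
* **Negative states**: the solver runs unconstrained and trajectories are
  asserted to stay above −1e-12 µmol; clipping would mask model errors.
  The Newton line search rejects candidate states below that floor.
* **Degenerate inputs**: rate laws validate their domains (`hct < 1`,
  positive Michaelis constants and half-lives, expression in [0, 100]) and
  raise typed configuration/domain errors; a relative RMS objective refuses
  zero-valued observations and points to absolute mode.

## Identification

The steady-state identification frees the 20 optimized constants
(`optimized_raas_parameters()`), initialized at their tabulated values with
×0.01–×100 bounds, log10-scaled; the objective is the relative
root-mean-square deviation of the six venous steady-state concentrations
from their reference values. Relative residuals are essential: the targets
span 0.60 down to 3.6e-7 µmol/L, so an absolute RMS would see only AGT.
The minimizer is a fminsearch-style Nelder–Mead simplex (reflection 1,
expansion 2, contraction 0.5, shrink 0.5), terminating on relative simplex
spread below 1e-6 or budget exhaustion, with restarts around the incumbent
best — the standard remedy for premature simplex collapse in 20 dimensions.
Bound violations are clamped and penalized. `stats::optim`'s Nelder–Mead
serves as an independent cross-check on test problems. With a 3000
evaluation budget the fit reduces the objective from ~80 to below 1e-9,
i.e. all six concentrations are reproduced essentially exactly; each
objective evaluation reassembles the system (closure included) and
re-solves the steady state warm-started from the previous candidate.

Absorption constants (`ka`, `f_abs`) are identified from concentration–time
data by seeded Monte Carlo random search (uniform draws, log-uniform for
`ka`) — deterministic per seed, best draw returned. The parent-drug
observables are independent of the metabolite's ACE binding, so the
objective simulates with binding disabled, which removes the stiffest terms
from each draw.

## The drug model

Enalapril is dosed orally in mg (converted via MW 376.5 g/mol; the maleate
salt correction is ignored because doses are reported as enalapril).
A first-order gut depot empties at `ka` (default 0.03 min⁻¹); a fraction
`f_abs` (default 0.6) reaches liver plasma and the rest is never absorbed.
Both defaults are identification targets, not assertions. Hepatocyte access
is by passive permeation (PS = 1 L/min, partition coefficients default 1.0
for these hydrophilic compounds, per-organ overridable); conversion to
enalaprilat happens intracellularly (Km 710 µmol/L, study-specific Vmax),
in parallel with a linear intrinsic hepatic clearance of 354 ml/min.
Renal clearances use the study-specific per-kg values; the whole-body
clearances also tabulated for the compounds are retained as metadata only,
since the per-kg values are the model-consistent optimization results.
Protein binding percentages are stored but rate laws act on total plasma
concentrations. IV enalaprilat and oral enalapril share one enalaprilat
parameterization.

## Aldosterone drive

The tissue source of aldosterone is not resolved by the model's organ list
(no adrenal compartment), so the synthesis term is driven by the
plasma-volume-weighted whole-body mean AT1–Ang2 complex concentration by
default, switchable to kidney-only (`system_options(aldosterone_drive =
"kidney")`). This is a declared modelling assumption, not a literature
value.

## Synthetic data

`generate_fixtures()` emulates the study designs used for the drug model:

* `subjects` samples weight, carboxylesterase Vmax, renal clearances, ACE
  reference concentration and liver volume uniformly within the spans of
  the six study populations.
* `pk_curves` simulates oral enalapril for a subject, samples at
  clinical-like times (15 min–48 h) and applies ~15% multiplicative
  lognormal noise. Noisy values below a quantification limit of
  1e-3 µmol/L (≈0.4 ng/ml, a typical LC-MS/MS limit) are censored to NA,
  as in real assay data; noise-free curves are returned uncensored and
  equal the model prediction exactly.
* `raas_targets` emits the six reference steady-state concentrations with
  optional noise.

What passing the recovery tests shows: the identification machinery
recovers generating parameters from data *of this model* under realistic
noise and censoring. It does not show that the model fits real clinical
concentration–time data — the reduced physiology (plasma-only distribution,
no portal circulation, unit partition coefficients) makes the simulated PK
faster than observed kinetics, and no clinical datasets ship with the
package.

## Problem sizes and default budgets

The shipped defaults are sized for a single-CPU desk run: the RAAS-only
system has 115 states and the coupled system 165; the steady-state
identification uses a 3000-evaluation simplex budget with up to 6 restarts;
Monte Carlo absorption recovery uses 2000 draws against one 48-h curve;
dosed demonstration trajectories run 4500–6000 min at 10–15 min output
resolution. All are arguments, not constants.

## Known limitations

* Blood pressure and heart rate are outside the model; so are other
  inhibitor classes (renin inhibitors, AT1 blockers, aldosterone-synthase
  inhibitors, diuretics), the ACE2/angiotensin-(1–7) arm, chymase pathways
  and tissue RAAS.
* Optimized parameter values are not claimed to be unique; the steady-state
  targets under-determine 20 parameters, and the identification reports the
  incumbent best, not a posterior.
* The absolute per-organ volumes/flows are package choices (see above);
  conclusions that depend on organ-level concentration gradients rather
  than systemic balances should be drawn with care.
* No circadian or delay effects; deterministic simulation only.
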