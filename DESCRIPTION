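Package: raasim
Title: Whole-Body PBPK-PD Simulation of the Circulating Renin-Angiotensin-Aldosterone System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic whole-body physiologically based pharmacokinetic and
    pharmacodynamic (PBPK-PD) simulator of the circulating endocrine
    renin-angiotensin-aldosterone system (RAAS) coupled to a parent-metabolite
    model of oral enalapril and its active metabolite enalaprilat. The hormone
    cascade (angiotensinogen, renin, prorenin, angiotensin 1 and 2, the AT1
    receptor and aldosterone) is modelled with Michaelis-Menten conversion,
    receptor binding kinetics, feedback-inhibited prorenin activation,
    first-order secretion and degradation over a reduced reference physiology
    (organ plasma volumes, blood flows, hematocrit, per-organ enzyme and
    receptor expression). Enalaprilat inhibits the angiotensin-converting
    enzyme (ACE) by reversible stoichiometric binding. The package provides
    pre-administration steady-state construction, dose-event simulation with a
    stiff ODE solver, Nelder-Mead and Monte Carlo parameter identification
    against steady-state and concentration-time targets, a virtual-subject and
    synthetic-data generator, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
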