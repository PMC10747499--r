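Package: mappk
Title: Intradermal Microarray-Patch PBPK Modelling of Long-Acting Cabotegravir
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-body physiologically based pharmacokinetic (PBPK) modelling
    of long-acting cabotegravir delivered by dissolving microarray patches
    (MAPs). Provides virtual rat and human cohort generation with
    tissue-composition-based partition coefficients, microneedle-array
    geometry and per-skin-layer dose partitioning, a coupled ODE model of
    nanoparticle release, trans-skin transport and blood-flow-limited
    systemic disposition, empirical one- and two-compartment parameter
    estimation by nonlinear least squares, predicted-versus-observed
    verification statistics (fold-error ratios and absolute average fold
    error), and once-weekly dose-regimen prediction against
    protein-adjusted IC90 efficacy targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
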