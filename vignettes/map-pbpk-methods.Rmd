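---
title: "Modelling intradermal microarray-patch pharmacokinetics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intradermal microarray-patch pharmacokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mappk` implements a whole-body physiologically based pharmacokinetic (PBPK)
model for long-acting cabotegravir delivered by dissolving microarray
patches (MAPs), together with the supporting machinery a modeller needs
around it: virtual cohorts, microneedle geometry, empirical parameter
estimation, predicted-versus-observed verification statistics, and
once-weekly regimen prediction against protein-adjusted IC90 (PA-IC90)
efficacy thresholds. This vignette documents the model, its assumptions,
the tunable parameters, and the design decisions taken where more than one
reading was defensible.

## The model

### Intradermal patch compartments

A patch carries `16 x 16` right-rectangular-pyramid microneedles per
0.49 cm² baseplate (600 µm tip height, 300 x 300 µm footprint) on a
drug-free 250 µm cuboidal base, loaded at 5.86 mg/cm²; 97% of the tip
height is inserted. The inserted frustum is sliced at the stratum corneum /
viable epidermis / dermis boundaries (rat thicknesses 18/32/2040 µm, human
17/47/2906 µm), and the dose is split across the three layers in proportion
to the needle volume residing in each layer, normalized over the *inserted*
volume (the non-inserted 3% of tip height never enters skin; its drug is
excluded rather than double-counting losses already absorbed by the fitted
apparent clearance). The depth coordinate is 0 at the skin surface with the
needle apex at the insertion depth, and layer boundaries are half-open.

Per layer `x`, three states describe the depot: drug still in its
nanoparticle formulation in the needle (`ND_x`), drug released from the
formulation but still in the needle (`RD_x`), and released drug that has
penetrated the layer (`PD_x`):

* `dND_x/dt = -K_NP * ND_x` — first-order nanoparticle release at
  `K_NP` (1/h), identical across layers (same formulation everywhere in the
  needle).
* `dRD_x/dt = K_NP * ND_x - (PC_x/W * SA_MN,x / V_MN,x) * RD_x` — transfer
  out of the needle scaled by the layer/water permeability coefficient
  (cm/h) and the needle's lateral surface area-to-volume ratio in that
  layer.
* Penetrating drug moves unidirectionally down the layers at the
  volumetric trans-skin rate `K_SKIN` (cm³/h), divided by the
  upper/lower-layer partition coefficient and the volume of the skin layer
  under the patch: e.g. the stratum corneum loses
  `(1/PC_SC/VE) * K_SKIN * PD_SC / V_SC` to the viable epidermis.

The dermis exchanges with the systemic circulation. The dermal blood flow
`Q_DE` delivers drug from arterial blood and clears the patch-covered
dermis as `Q_DE * (PD_DE / V_DE) * (R / TP_skin)`, where `R` is the
blood:plasma ratio and `TP_skin` the skin tissue:plasma partition
coefficient. We formulate this exchange as draining the *dermis* into the
venous pool; this is the only reading of the dermal exchange that conserves
mass, and mass conservation was treated as non-negotiable throughout (the
package's test suite asserts conservation to better than 1e-6 relative at
every output time). An alternative published formulation that couples the
venous amount into the dermis balance does not close the mass balance and
was not adopted.

`Q_DE` itself is not constrained by any published value for this system; it
is a configurable per-area perfusion with default 1 mL/h/cm² of
patch-covered skin (the scale of resting skin perfusion). Because the
dermis-to-blood step is transit, not elimination — at quasi-steady state
everything released eventually reaches the circulation — systemic
predictions are insensitive to its exact value, and the pipeline reports
flag it as an assumption.

### Systemic disposition

Outside the patch, disposition is blood-flow-limited with well-stirred
compartments: eleven perfused organs in parallel between arterial and
venous blood, lung in series carrying total cardiac output, and
`dA_t/dt = Q_t * (C_art - A_t * R / (V_t * Kp_t))` per organ. The apparent
clearance CL/F acts on the venous *blood* concentration, and plasma
concentration is blood concentration divided by `R` (= 0.5). The placement
of clearance on blood is a deliberate design choice: with the published
human intramuscular constants (CL/F 0.197 L/h, release rate 4.54e-4 1/h,
volume-of-distribution correction 0.01) it is the only placement whose
scale reproduces the published predicted human exposure, and the package's
acceptance checks exercise exactly that configuration.

An intramuscular dose is a first-order depot releasing into venous blood at
its route-specific `K_NP` (the entry compartment is configurable; venous
entry is the default since the model's verification metrics are insensitive
to a muscle-tissue transit).

Because every transfer is first-order, the whole system is linear and
time-invariant between doses. The engine assembles it once as a rate matrix
whose columns sum to zero (exact mass balance by construction, with
eliminated drug tracked as a state) and hands the stiff solver the analytic
Jacobian. Dosing is event-based: each administration adds to the depot
states, so residual drug from earlier patches is retained.

### Tissue partitioning and the volume of distribution

Tissue:plasma partition coefficients use the composition-based method with
the vegetable-oil:buffer partition coefficient derived from LogP
(`log10 P_vo:w = 1.115 * logP - 1.35`). Cabotegravir (pKa 10.04 and −0.7)
is essentially un-ionized at pH 7.4, so no ionization adjustment is
applied. Tissue unbound fractions use
`fu_t = 1 / (1 + 0.5 * (1 - fu_p)/fu_p)`, with `fu_t = 1` for adipose. An
empirical per-route correction factor multiplies every partition
coefficient (rat IM 5, rat MAP 0.05, human 0.01); applying it to the
coefficients rather than to the summed volume keeps a single consistent
parameterization for both the distribution volume and the dermis exchange
term.

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `K_NP` (patch) | 1/h | 3.43e-3 | release half-life ≈ 202 h; rat-estimated, reused in humans |
| `K_NP` (IM, human) | 1/h | 4.54e-4 | release half-life ≈ 1527 h |
| `K_SKIN` | cm³/h | 1.73e-3 | trans-skin volumetric rate; fixed constant, *not* scaled with patch area |
| CL/F (IM, human) | L/h | 0.197 | published apparent clearance |
| CL/F (patch, human) | L/h | 0.985 | = 0.197 / 0.20; the 20% patch bioavailability lives inside CL/F and is never applied twice |
| Vd correction | — | route-specific | multiplies all tissue:plasma coefficients |
| `Q_DE` | mL/h/cm² | 1.0 | assumed dermal per-area perfusion; transit only |
| dose loading | mg/cm² | 5.86 | fixes patch area: 300/150/75 mg → 51.2/25.6/12.8 cm² |

A consequence of holding `K_SKIN` fixed while patch area scales with dose:
the system is dose-proportional only at *fixed geometry*. Loading the same
51.2 cm² patch with 300/150/75 mg scales every concentration exactly
4:2:1; letting the area shrink with the dose changes the fractional
trans-layer rates (`K_SKIN / V_layer`) and makes the scaling approximate
(a few percent at these designs). The tests assert the exact property at
fixed geometry and the regimen-prediction workflow at its stochastic
tolerance.

## Empirical estimation

One- and two-compartment disposition models with first-order depot input
(Bateman equation and the biexponential macro-constant solution;
superposition for multiple doses) are fitted by Levenberg–Marquardt least
squares on untransformed concentrations (log-scale optional), with
parameters optimized on the log scale under box bounds
(`ka ∈ [1e-5, 1] 1/h` by default) and a seeded multi-start.

These depot models are structurally non-identifiable up to the *flip-flop
twin*: exchanging the absorption rate with a disposition exponent leaves
the concentration curve unchanged. Long-acting formulations are
absorption-rate limited by design, so fits are canonicalized to the branch
with the absorption rate as the slowest exponential (for one compartment
the exact map is `(ka, CL, V) → (CL/V, CL, CL/ka)`; for two compartments
the canonical parameters are reconstructed from the three exponential rates
and their coefficients). The multi-start accepts only strict RSS
improvements so equal-RSS twins cannot displace a user-supplied start.

The full PBPK model can itself be the regression function
(`estimate_clf_by_curvefit()`), with any of CL/F, `K_NP`, `K_SKIN` and the
Vd correction free; this mirrors how the route-specific clearances were
originally estimated against in vivo data.

## Synthetic data

No machine-readable concentration-time profiles exist for the in vivo
studies — only summary metrics printed in tables, which ship as read-only
fixtures (`load_fixture()`). Profile-level behaviour is therefore tested
against synthetic studies (`make_rat_map_study()`): six animals per design,
sparse schedules (single dose: days 1–28; weekly: pre-dose and 24 h
post-dose samples plus day 42), generated from a two-compartment depot
truth with the rat patch release rate 3.43e-3 1/h and disposition constants
chosen once to reproduce the observed concentration scale (Cmax ≈ 18
µg/mL). Measurement error is proportional (CV 0.15) plus additive (SD 0.01
µg/mL), truncated at zero — an assumed assay model, documented as such.
What passing synthetic tests demonstrate is parameter recoverability and
pipeline correctness at the study designs, not agreement with any real
animal.

Virtual cohorts: rat weights are normal truncated at ±3 SD with organ
volumes and flows scaled linearly from a 0.25 kg reference rat; human
cohorts allocate sex deterministically, draw age uniformly (18–60 y),
height normally and BMI log-normally per sex, and close organ mass balance
exactly on body weight through a residual carcass compartment. The
anthropometric constants are a documented default set (the original
regression sources are not reproduced here); all are overridable through
the physiology configuration. The generator does not emulate covariance
between organ fractions and age, disease states, or sex-specific skin
thickness (means are used for both species).

## Numerical choices

* Stiff solver (`lsoda`) with absolute tolerance 1e-9 µg and relative
  1e-8; the analytic Jacobian (the constant rate matrix) keeps the very
  fast organ equilibration (rate constants up to ~1e4 1/h under small
  partition corrections) cheap to integrate.
* Dose events at exact times, merged into the output grid; default grid
  0.5 h (1 h for six-month cohort runs).
* Trapezoidal AUC on the output grid, with edge interpolation; order-2
  convergence is tested.
* AAFE uses the absolute value of the log fold error,
  `10^(mean |log10(pred/obs)|)` — for a single pair this equals
  `max(r, 1/r)`, which is how the shipped verification tables behave.
  Pass bands (ratio 0.5–2, AAFE 1–2) are closed intervals; comparisons use
  full precision and rounding is display-only.
* Steady-state trough and peak are taken over the final complete dosing
  interval of the horizon, on the cohort *mean* curve (the per-subject
  distribution is also available); time-to-target is reported at daily
  resolution on the mean curve.

## Problem sizes

The shipped tests run cohorts of 1–20 subjects and six-month weekly
regimens on a 1 h grid (about 20 s total); the reproduction script uses the
full 100-subject human cohort, which completes in well under a minute.
These sizes were chosen as the smallest that exercise every code path at
meaningful statistical resolution.

## Known limitations

* Rat absolute exposure predictions are not reproducible from the printed
  route-specific constants (the published rat patch clearance is
  inconsistent with the published rat patch AUC by severalfold), so rat
  behaviour is verified through structural properties (conservation,
  linearity, analytic release kinetics) rather than value matching; the
  human configurations are verified against the published predicted values.
* Hair-follicle transport and lymphatic uptake are intentionally excluded;
  trans-layer movement is unidirectional for released drug.
* Protein binding, partition and permeability coefficients are constants;
  no nonlinearity, metabolites, or inter-occasion variability.
* The dermal perfusion default and the anthropometric equation set are
  assumptions, flagged in reports and overridable in configuration.
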