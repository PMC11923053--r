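---
title: "Models and methods behind carbsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind carbsens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the kinetic
model and its assumptions, the sensitivity and control analyses built on
it, the calibration strategy, the multivariate layer, and — importantly —
the numerical and design choices made where more than one defensible option
existed, with the reasons. Nothing here reports an empirical number that
the test suite or `scripts/acceptance.R` does not itself compute.

## The kinetic model

The model condenses the central carbohydrate metabolism of an
*Arabidopsis thaliana* leaf into five pools — fructose 6-phosphate (F6P),
glucose 6-phosphate (G6P), sucrose (Suc), fructose (Frc) and glucose
(Glc), all in µmol per gram dry weight — and twelve processes. F6P is
taken as the entry point of photosynthetic carbon: the influx is
`rNPS = k_NPS / 6`, the net CO₂ assimilation rate expressed in hexose
equivalents. Sucrose-phosphate synthase (rSPS) is a lumped two-substrate
law in F6P and in the fraction `k_udp` of G6P that is converted towards
UDP-glucose before entering the reaction; UDP-glucose itself is not a
pool. `k_udp` is bounded to [0.2, 0.5], the admissible range for that
conversion. Invertase (rINV) cleaves sucrose and is competitively
inhibited by Frc and non-competitively by Glc; fructokinase and
glucokinase (rFRCK, rGLCK) recover the hexoses into the phosphate pools
under product feedback from F6P and G6P respectively. First-order
processes close the network: sucrose export to sinks (r1 = k1_exp·Suc),
F6P export into other pathways (r2 = k2_exp·F6P), lumped starch synthesis
(rSTAsyn = k_STA·G6P) and the lumped flux into anthocyanins
(rANTHO = k_ANT·F6P). Starch degradation has no rate equation; `rSTAdeg`
is a constant parameter, fixed at 0 in all condition realizations because
they represent midday steady states in which mean net starch turnover is
absorbed into `k_STA`. Time is in hours, fluxes in µmol gDW⁻¹ h⁻¹ — a
declared convention propagated through all I/O, since rates and plots only
fix the unit ratio.

Two structural quirks are implemented *verbatim* because condition
parameterizations are fitted to this exact form:

* **The PGI pair.** Phosphoglucoisomerase appears as two one-way saturable
  fluxes weighted by the balance parameter `f`: rPGI1 consumes F6P (weight
  `f`) and rPGI2 *produces* G6P from a G6P-saturable law (weight `1 − f`),
  each inhibited by the opposite hexose phosphate. No mass-conservation
  correction is applied — rPGI1's carbon does not reappear in G6P, and
  rPGI2 acts as a G6P self-source. One practical consequence, exercised in
  the tests: with zero influx the empty state is a steady state but only
  *attracts* when rPGI2's linear gain `(1 − f)·vmax_PGI/Km_PGI` is below
  the first-order G6P drain. The reported measure `rPGI` is rPGI1 by
  default (configurable to rPGI2 or their mean, recorded in output
  metadata); whether rPGI1 = rPGI2 holds at a fitted steady state is not
  structurally enforced and is left as an empirical property of each fit.
* **The sucrose balance.** The printed equation system drains sucrose with
  r2 (the F6P export) while r1 — defined as the sucrose export — appears
  in no balance at all. The default mode `"scheme"` follows the reaction
  scheme (`dSuc/dt = rSPS − r1 − rINV`); mode `"as_printed"` reproduces
  the typography literally. The scheme-consistent form is the default
  because r1 is otherwise a dangling definition yet is analyzed as a flux
  throughout the downstream pipeline; neither mode is asserted to be the
  authors' intent, and both are first-class (the SBML export follows the
  selected mode, dropping the bookkeeping-only r1 reaction under
  `"as_printed"`).

Genotype is metadata only: mutant effects (flavonoid-pathway or
starch-pathway lesions) are carried entirely by the fitted parameter
values, matching the conditional-parameterization design. There is no
compartmentalization (plastid/cytosol are lumped) and no explicit starch or
anthocyanin pool.

## Steady states

`find_steady_state()` relaxes the system by integration
(`deSolve::lsoda`, default horizon 10⁴ h, tolerances 10⁻¹⁰) and then
refines the endpoint with a damped Newton iteration on the right-hand side
(numeric Jacobian, step halving, non-negativity projection). Convergence
requires **every individual component** of the RHS to fall below the
tolerance (default 10⁻⁹ µmol gDW⁻¹ h⁻¹ absolute), not just a norm. Both
stages are configurable through `ss_control()`. Warm starts (a guess with
a small residual) skip the relaxation stage, which is what makes the
thousands of steady-state re-solves of the control analysis cheap. A
useful structural identity, used as a test oracle: multiplying the ten
rate-scaling constants (k_NPS, the five vmax values, k1_exp, k2_exp,
k_STA, k_ANT) by a common λ > 0 leaves the steady state unchanged and
scales every flux by λ.

## The sensitivity score

For perturbations *i* of the nps scale with rate ratios rᵢ/r₀ and measure
readouts xᵢ against the unperturbed steady-state value x₀,

$$\gamma_x = \left(\prod_i^{N}\left|\log_2\!\Big(\frac{x_i}{x_0}\cdot
\frac{r_0}{r_i}\Big)\right|\right)^{1/N}.$$

A measure tracking nps proportionally scores 0; a measure that doubles
while nps is unchanged scores 1. The default protocol perturbs `k_NPS`
by ±5…30 % in 5 % increments (N = 12), simulating a 4 h window with an
instantaneous step (not a ramp) at 2 h and reading x_i — concentrations
*and* fluxes, the fluxes evaluated with the perturbed parameters at the
same instant — at the end of the window, i.e. 2 h after the step. The
readout time is configurable; a long-horizon readout converges to the
relaxed steady-state ratios, which the tests verify against an independent
re-solve oracle. The rate ratio is computed from the `k_NPS` ratio, which
equals the rNPS ratio exactly since rNPS = k_NPS/6. The high-light variant
applies one +25 % step (the modelled effect of raising growth light from
100 to roughly 250 µmol m⁻² s⁻¹ at 4 °C) and uses exposure *durations*
(default 3 h and 6 h after the step) in the role of the perturbations.

Degenerate cases are handled explicitly rather than silently: a relative
change of exactly 0 contributes |log₂ 1| = 0 and annihilates the geometric
mean (the protocol constructor warns); a measure driven to zero at a
readout yields an undefined logarithm and is reported as missing with a
warning — substituting an epsilon would bias γ downward unpredictably.

## Metabolic control analysis

The scaled control coefficient C_p^X = d ln X / d ln p is read as a
property of the **relaxed** system: perturb p multiplicatively by
(1 ± h), re-solve the steady state on each side (warm-started), and take
the central difference of the logarithms (default h = 10⁻⁴). Near an
admissible bound (f near 1, k_udp near 0.5) the step is shrunk so the
evaluation stays two-sided within bounds — never silently one-sided. An
analytic path via the implicit-function theorem (state response
dx/dp = −A⁻¹b with A the state Jacobian, plus the chain rule for fluxes)
is provided as an independent cross-check and agrees with the finite
differences in the tests. The perturbable set is all 24 parameters except
the structurally fixed `k_STAdeg`; `f` and `k_udp` are included.

Two summation theorems follow from the scaling law above — flux
coefficients over the ten rate-scaling constants sum to 1, concentration
coefficients to 0 — and serve as the module's primary accuracy
diagnostics (`summation_check()`); the acceptance suite requires both to
hold within 10⁻⁴ on every realization of a full synthetic study.
`high_cc_frequency()` counts coefficients whose **magnitude** exceeds a
threshold (default 1.5, where the coefficient distribution drops into a
wide tail). Absolute values are used deliberately: a strongly negative
coefficient marks the system as no less sensitive than a strongly positive
one. The counts pool parameter control coefficients (the default grouping
for the per-genotype / per-day comparison).

A regime worth naming, verified by a dedicated test: with a low `f`,
strong hexose-phosphate inhibition of the PGI pair, strong G6P feedback on
glucokinase and strong Glc inhibition of invertase, raising `f` *raises*
Glc while *depleting* Frc — the G6P-feedback chain (G6P accumulation
blocks glucokinase, Glc accumulates, Glc inhibits invertase, Frc starves)
dominates the direct effect. The signs are asserted only on a
parameterization exhibiting that regime.

## Calibration

Each condition is fitted individually under shared constraints
("strategy (b)"): common Km/Ki bounds for all conditions, the order
relation Km_FRCK > Km_GLCK, and Km_INV within a factor 3 of Km_FRCK (the
operationalization of "similar or close"; the band is configurable). The
third literature relation involving Km_PGI is self-contradictory as
printed in its source ("Km_FRCK > Km_PGI > Km_FRCK"), so neither reading
is a silent default: both are available as explicit presets of
`constraint_set()`. The cross-condition cohesion rule — each Km/Ki symbol
spans at most one order of magnitude across conditions — is checked
post hoc by `check_constraints()` rather than imposed as a joint-fit
penalty, because conditions are fitted individually under common bounds.

The objective follows the steady-state assumption directly: residuals are
the (scaled) right-hand side evaluated **at the observed pool sizes** —
parameters are sought that make the observed state a steady state — plus
weighted log-residuals pulling the nps-derived influx target, the starch
net-balance target and any enzyme-activity observations (named after the
vmax parameter they measure) to their observed values. Log residuals are
used because observations span orders of magnitude; weights default to
1/cv with a floor so noise-free data stay finite. Because a steady-state
design leaves many parameter directions under-determined (five balance
equations against ~15 free directions once the directly observed scales
are pinned), a mild ridge term shrinks every free parameter towards its
log-box centre: it keeps the least-squares problem over-determined and
selects a unique, reproducible representative of the unidentified
directions without measurably biasing the identified ones. Order relations
enter as hinge penalties with a 10 % separation margin (a flat hinge would
let the optimum sit exactly on the strict boundary), and the returned
optimum is re-checked against the strict relations. Optimization is
bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on the log scale with
Latin-hypercube multi-start (default 50 starts; the test and acceptance
runs use 12, which the recovery study shows suffices at this problem size)
plus one data-informed start seeded from the directly observed scales.
The reported fit score is computed from the *re-solved* steady state of
the fitted model against the observations, so a fit whose optimum is not a
reachable steady state cannot score well.

**Identifiability, declared.** With the study's observation design — the
five pools, an rNPS target, an rSTAsyn target and the five enzyme
activities — the structurally identified parameters are k_NPS, k_STA and
the five vmax values; recovery error in the acceptance study is scored on
that set ("up to structural identifiability"), at 5 % observation noise,
with the median relative error required below 15 % and the refitted steady
state within 10⁻³ of the observed pools. Km/Ki values, `f`, `k_udp` and
the export constants are *not* claimed to be recovered by this design;
they are constrained, not identified.

## Synthetic studies

`generate_study()` emulates the study design so every stage is testable
without downloads: a 5 genotype × 5 day grid (25 condition realizations),
parameter draws around a reference parameterization with a shared log₁₀
jitter (±0.35) plus per-symbol jitter (±0.1) for all Km/Ki — capping each
symbol's cross-condition spread below the cohesion factor of 10 while
preserving the order relations by construction — independent jitter for
the rate-scaling constants, a smooth log-linear acclimation drift (k_NPS
declining, enzyme capacities rising with days in the cold), and
genotype-archetype multipliers on single constants (0.1× k_ANT for the two
flavonoid-mutant archetypes, 0.1× k_STA for the starch-synthesis
archetype, 0.5× k_STA for the starch-retrieval archetype — a fixture
convention echoing the qualitative direction of the corresponding lesions,
not published values). Observations are the true steady states, the rNPS
and rSTAsyn fluxes and the vmax activities under unbiased multiplicative
lognormal noise (default CV 0.1, the scale of 4–6-replicate dispersion).
The reference parameterization itself was chosen once for realism —
pool sizes of a few to a few tens of µmol gDW⁻¹ with an influx of
20 µmol gDW⁻¹ h⁻¹ — and is documented in `default_parameters()`.

What the generator does **not** emulate: the actual published parameter
values or their covariance across conditions, replicate structure and
within-day dynamics, measurement error correlated across metabolites, or
any systematic model misspecification. Passing the recovery and pipeline
tests therefore demonstrates the correctness and stability of the
machinery under the stated statistical structure — not that the model is
identified or unbiased on real leaf-tissue data.

`planted_sensitivity_matrix()` provides the multivariate fixtures: a
rank-1 direction, an optional day-0 shift along it, isotropic noise, and a
positive base offset. Because the robustness test applies multiplicative
noise, the base offset sets the noise magnitude relative to the planted
structure; its default keeps the two at the proportion typical of
model-derived sensitivity matrices, whose entries are small positive
numbers.

## PCA, day-0 separation, robustness

`pca_gamma()` standardizes each measure column (mean 0, sd 1) and
decomposes by SVD; explained-variance fractions are computed over **all**
components (they sum to 1, and the leading four are the quantities
reported from a full pipeline run). Population- vs sample-sd
standardization changes nothing here: the uniform column rescaling cancels
from variance ratios and loadings. Component signs are fixed by a declared
convention — the Suc loading is made non-positive where nonzero, falling
back to making the largest-magnitude loading negative — so loadings are
comparable across runs; flips are recorded in the result. Conditions with
missing sensitivities (undefined logs upstream) are excluded with a
warning rather than imputed, since imputing would fabricate a sensitivity;
zero-variance measures cannot be standardized and are dropped with a
warning.

`day0_separation()` returns |mean(PC1 day-0) − mean(PC1 rest)| divided by
the pooled *within-group* standard deviation of the PC1 scores (the
sharper of the two readings of "pooled"), plus the mean silhouette width
of the two-group partition on PC1. It is invariant to condition order and
to the sign convention; groups with fewer than two members set a
low-confidence flag instead of failing.

`robustness_test()` multiplies every matrix entry by independent lognormal
factors whose central 95 % interval spans 1 ± noise_level, redoes the PCA
and the separation, and reports the fraction of repetitions in which the
statistic stays above a configured fraction (default one half — a declared
choice, not taken from any source) of its unperturbed value. The default
noise_level of 0.5 reflects worst-case model-versus-data deviations of
isolated measures; both knobs are arguments.

## Problem sizes, tolerances, determinism

The shipped checks run the full 25-condition design for the
summation-theorem suite, the sensitivity/PCA pipeline and the recovery
study (12 optimization starts per condition, 5 % noise), 100 repetitions
for the robustness test, and a three-step linear chain with closed-form
coefficients as the control-analysis oracle — sizes chosen so the whole
suite completes in minutes on one CPU while still exercising every code
path at full design width. All stochastic stages (generator, multi-start
design, robustness noise, shuffles) are driven by explicit integer seeds;
reruns are bitwise identical given the same configuration, which the
pipeline test asserts via artifact checksums. Steady-state tolerance is
10⁻⁹ per component, finite-difference steps 10⁻⁴ relative with Richardson
consistency checked by step halving, and the sensitivity sweep is
reproducible to machine precision against a literal re-computation from
its stored time courses.

## Known limitations

* The PGI pair's lack of mass conservation means total carbon is not a
  conserved quantity; the model is a fitted phenomenological balance, not
  a stoichiometric one, and rPGI1 = rPGI2 at steady state is not
  guaranteed.
* Identifiability is limited by design (see Calibration); fitted Km/Ki
  values should be read as constraint-satisfying representatives.
* The day-0 separation statistic is a descriptive effect size, not a test;
  no p-value is attached, and with 5 day-0 conditions its null
  distribution is wide (the shuffle test in the suite quantifies this).
* `k_STAdeg` is exposed for exploratory simulation only; no analysis layer
  perturbs it.
* The sensitivity protocol models nps steps as instantaneous rescalings of
  `k_NPS`; light intensity per se (and its photosynthesis physiology) is
  out of scope.
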