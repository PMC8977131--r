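---
title: "Methods: diffusion modelling of perceptual learning and its brain correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion modelling of perceptual learning and its brain correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the numerical choices behind them, what the synthetic data do and do not
emulate, and the design decisions that were genuinely open.

## The diffusion model and its parameterization

A two-choice decision is modelled as a Wiener process starting at `z`
(absolute units) between absorbing boundaries 0 and `TH`, drifting at a
rate drawn once per trial from Normal(`DR`, `s`), with within-trial
diffusion coefficient `sigma`. Start point and nondecision time vary
across trials as Uniform(`z` ± `sz`/2) and Uniform(`Ter` ± `st`/2);
observed RT is decision time plus nondecision time. Under accuracy
coding the upper boundary is the correct response — appropriate here
because the task is a symmetric 45°/135° identification, so stimulus
identity carries no modelling interest.

`sigma` is a scaling convention, not an estimable parameter: multiplying
`DR`, `s`, `sigma` by c and `TH`, `z`, `sz` by c changes nothing
observable (a property the test suite asserts). We fix `sigma = 0.1`,
the classic convention, so fitted magnitudes are comparable with the
bulk of the diffusion-modelling literature; it is an argument, not a
constant, for users who prefer `sigma = 1`.

### Density evaluation

The drift-free first-passage density uses the standard small-time and
large-time series with the usual truncation bounds, evaluating whichever
representation needs fewer terms (target accuracy 1e-12 per term
budget). Normal drift variability is integrated analytically: the
drift-dependent factor exp(−Av − Bv²) against a normal drift density has
the closed form given in the source, arranged so it stays finite as
`s → 0`. The uniform start-point and nondecision marginals use
fixed-order Gauss–Legendre quadrature (order 10 at the user-facing
surface; the fitter uses lower orders, see below). Defective CDFs
integrate the density over segments with per-segment Gauss–Legendre,
subdividing long segments relative to the diffusion time scale
`TH²/sigma²` so the rule tracks the density peak.

### Simulation

The simulator is deliberately a different route to the same
distributions: Euler–Maruyama with a Brownian-bridge crossing
correction, which evaluates within each step the probability that the
path crossed a boundary between endpoints and absorbs accordingly. The
correction removes the O(√dt) overshoot bias, so moderate steps
(1e-3 s) are accurate; the default is dt = 1e-4 s. Agreement between
simulator and analytic densities is asserted at Monte-Carlo tolerance in
the tests, which is what makes the pair a genuine cross-check rather
than one implementation wearing two hats.

## Fitting the block-constrained family

Six blocks (pre, tr1–tr5) are fitted jointly under five sharing
regimes: null, DR, DR-TH, DR-TH-Ter, full. Shared parameters count once
and free ones six times, giving k = 7, 12, 17, 22, 42; N is the total
trial count (600), so BIC = k·ln(600) − 2·lnL is comparable across
members.

The objective is the multinomial likelihood of quantile-bin counts:
observed {.1,.3,.5,.7,.9} RT quantiles per response per block bound six
bins whose expected probabilities come from the defective CDF, floored
at 1e-10. A response with fewer than 5 observations (errors late in
training, typically) collapses to a single count cell with probability
equal to that boundary's choice probability — the zero-error case is
then just the empty collapse. The threshold 5 is a package choice.

Internally the start point and its range are fractions of threshold
(`z/TH`, `sz/TH`). This is what makes "share the bias while the
threshold learns" well-posed — the parameter-space invariants
(0 < z − sz/2, z + sz/2 < TH, Ter ≥ st/2) reduce to box constraints
that hold for every block regardless of that block's threshold.
Reported parameters are always absolute.

Optimization is bounded L-BFGS-B on unit-box-rescaled parameters with a
structured forward-difference gradient: perturbing a block-free
parameter re-evaluates only that block's likelihood, shared parameters
re-evaluate all six. Starts are method-of-moments (an EZ-style inversion
of accuracy, RT mean and variance per block) plus optional jittered
multistarts; one or two quasi-Newton restarts from the incumbent
recover the final nats the line search leaves behind, and a restart
gain below 0.2 nat is the convergence declaration. `fit_all_models()`
runs the family in nesting order, warm-starting each member from the
previous one — which is also what guarantees the maximized likelihoods
respect the nesting ordering up to optimizer tolerance.

Fitting quadrature defaults to orders (4, 4, 5) for the start-point,
nondecision and CDF-segment rules; the cohort-level analyses in this
repository use (3, 3, 4) with a single start. These orders shift the
absolute log-likelihood by fractions of a nat, identically across family
members, so BIC differences are unaffected; they matter only for speed.
Problem sizes used by the shipped analyses and tests: 22 subjects × 600
trials per cohort, 10 cohorts for the model-recovery check, 20 subjects
for parameter recovery.

## The behavioral screens and deltas

Subjects are excluded for high starting performance (pre-block accuracy
strictly above 0.75) or implausibly fast responding. The fast-RT rule
needed an aggregation decision: we exclude when more than 10% of a
subject's trials are under 0.2 s (configurable), reading "did not engage"
as a property of the session rather than of single trials. The
max-training block is the more accurate of tr4/tr5 (fatigue guard), ties
to tr5 — arbitrary but fixed. Deltas are max-training minus pre, on
accuracy and on the selected model's DR, TH, Ter.

## MRS post-processing

Concentrations arrive quantified (LCModel-style), water-referenced, with
CRLB, linewidth, SNR and tissue fractions. Rows failing CRLB < 10% or
linewidth < 10 Hz, flagged for lipid contamination, or (under the
glutamine control analysis) with failed Gln fits are removed with a
per-row exclusion log. Retained concentrations are divided by
(1 − CSF fraction). Whether the original pipeline corrected before or
after reference switching is unstated; here correction applies to the
referenced value — the two orders differ only by a subject-constant
factor under NAA referencing, which the correlation-based statistics do
not see. NAA referencing divides by the same voxel's NAA.

## Connectivity

The soft cleanup regresses motion (the 24-regressor expansion) out of
voxels and component time courses, estimates every component's
contribution to each voxel jointly, and subtracts only the noise
components' fitted parts — preserving variance shared between signal
and noise components, hence "soft". Labelling all components as noise
recovers the full regression residual; labelling none recovers
motion-only residualization (both asserted in tests). High-pass
filtering regresses out a discrete-cosine set up to the 0.01 Hz cutoff,
the SPM-style choice matching the preprocessing lineage this emulates,
rather than a Butterworth filter. Group masks keep voxels present in at
least 50% of subjects (inclusive at the boundary). Eigenvariates
standardize voxels first — the literature is silent here, and without
standardization a few high-variance voxels own the summary — and the
sign is aligned with the mean voxel time course; the singular-value
scaling convention is cosmetic since every downstream quantity is a
correlation. Autoregressive prewhitening (FAST-style) is *not*
re-implemented: residual autocorrelation is acknowledged, and the
synthetic generator uses matched AR(1) structure so that inference on
synthetic data is calibrated against itself.

## Association statistics

Robust regression is IRLS with bisquare weights, tuning constant 4.685,
scale from the median absolute residual excluding the p smallest
(divided by 0.6745) and leverage-adjusted residuals — the conventions of
the widely used robustfit implementation, with p values from the t
distribution on n − p df rather than sandwich estimators. On exactly
linear data it is OLS with unit weights. Collinearity above |r| = 0.999
is refused. The dependent-correlation comparison is Steiger's Z1* with
the pooled correlation; the method name travels with the output because
the printed z of the study this emulates (−2.05) is not exactly
reproducible from rounded correlations under any standard variant (the
rounded triplet gives −2.01 here). The 2×2 mixed ANOVA is computed from
closed-form sums of squares with unweighted (Type III) main effects, as
in the commercial package this mirrors; with two within-levels no
sphericity correction applies, and the interaction F is algebraically
the squared two-sample t on the deltas. Post hoc pairwise gates use
α = 0.025 (Bonferroni for two tests).

## What the synthetic cohorts emulate — and what they don't

The generator mirrors the study geometry: 22 subjects, 100 trials × 6
blocks, 825 volumes × 2 runs at TR 0.727 s, two MRS regions with the
usual QC ranges, an 18/14 stimulation split. The generating model is
the DR-TH-Ter member: drift rate rises from 0.07 by a subject-level
gain ~ Normal(0.10, 0.08²), threshold drifts from 0.095 to 0.080,
nondecision time falls by ~0.08 s, and all three carry block-to-block
state jitter (SDs 0.025, 0.008, 0.06). Pre-block accuracy lands near
0.63, matching a task calibrated to ~60% with a 75% screening ceiling.
The nondecision variability was set by a design analysis performed once:
block-to-block Ter variation was chosen so the expected likelihood
advantage of freeing Ter (~2× the 5·ln(600) BIC penalty) makes the
generating member identifiable at 600 trials — without it, model
recovery would fail for lack of signal, not lack of method. Brain
coupling is a Gaussian copula on the *true* drift-rate change (target
r = −0.5 for EV glutamate), so estimation noise attenuates observed
correlations exactly as it would in real data. Voxel time series are
latent AR(1) signals (inter-ROI correlation r) with unit voxel noise,
signal amplitude 1.5, a planted shared noise component and motion
contributions.

Passing tests on these cohorts show the chain recovers planted
structure under its own assumptions. They do not show robustness to
what real data add: non-AR(1) physiological noise, imperfect ICA
decompositions, contaminated MRS spectra upstream of quantification,
session effects, or model misspecification of the decision process
itself.

## Numerical choices and degenerate inputs

Expected bin probabilities are floored at 1e-10; bin mass is clipped at
zero before flooring. Densities are zero at or before the earliest
possible RT. |r| = 1 inputs to Fisher z, zero-variance difference
vectors, zero-variance voxel matrices, CSF fractions ≥ 1, missing or
non-positive NAA, rank-deficient component sets and collinear predictors
are all rejected with named errors rather than propagated as NaN. Ties
in model selection go to fewer parameters; the tr4/tr5 accuracy tie
goes to tr5. Every stochastic API takes a mandatory seed, and generators
are pure functions of (config, seed).

## Known limitations

No hierarchical estimation (subjects are fitted independently); no
alternative objectives (χ², full-likelihood) for cross-validating the
quantile-bin choice; the bridge-corrected simulator still carries O(dt)
bias; the connectivity stage models neither prewhitening nor spatial
structure within ROIs; and the mixed ANOVA is limited to the 2×2 design
the analysis needs.
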