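---
title: "Methods: fetal brain T2* relaxometry, ROI summaries and cohort comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fetal brain T2* relaxometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalT2star)
```

## The measurement model

Multi-echo gradient-echo MRI samples the transverse signal decay at a
series of echo times TE. In each voxel the magnitude signal is modelled
as a mono-exponential,

$$ S(\mathrm{TE}) = S_0 \, e^{-\mathrm{TE}/T_2^*}, $$

where $S_0$ (arbitrary units) is the amplitude extrapolated to TE = 0 — a
proton-density proxy — and $T_2^*$ (ms) is the effective transverse
relaxation time. Deoxyhaemoglobin shortens $T_2^*$, which is why the mean
brain $T_2^*$ over a supratentorial ROI serves as an indirect marker of
tissue oxygenation and perfusion in the fetal brain. The reference
acquisition this package emulates is a 2-D multi-slice multi-echo
gradient-echo EPI protocol at 3 T: four echoes spanning 11.6–182 ms,
3 mm isotropic voxels, TR 2.6 s, one or two dynamics. Only the first and
last echo times of that protocol are public; the two interior echoes are
an assumption of this package, placed evenly (11.6, 68.4, 125.2,
182.0 ms). Every function takes the echo train as data, so this default
matters only to the simulator.

The model assumes a single tissue compartment per voxel and neglects
macroscopic B0-gradient dephasing; multi-compartment or
stretched-exponential decay and complex-valued fitting are out of scope.

## Voxel-wise fitting

`fitVoxel()`/`fitMap()` estimate $(S_0, T_2^*)$ by bounded nonlinear
least squares **in linear signal space**. Fitting the log-signal by OLS
would be algebraically convenient but distorts the noise weighting:
magnitude MRI noise is Rician, approximately constant-variance in the
linear domain at moderate SNR, and heteroscedastic after the log
transform. The log-linear fit is therefore kept only as a closed-form
oracle (`loglinearFit()`), exact on noiseless data, against which the
nonlinear fitter is verified to $10^{-4}$ relative.

Because the least-squares surface can have shallow or misleading basins
at low SNR, each voxel is fitted from `nInit = 10` random starts and the
**median** of the converged estimates is reported, independently for
$T_2^*$ and $S_0$ (the estimator specification speaks of a voxel-wise
median without fixing the parameter coupling; the independent median is
the more robust of the two readings). The median tolerates up to
$\lfloor (n-1)/2 \rfloor$ starts converging to a wrong local value.

Numerical choices, all surfaced in the provenance record of every map:

* **Optimiser** — Levenberg–Marquardt with analytic Jacobian and box
  constraints enforced by clamping, implemented in C++ for speed (a 64³
  phantom fits in about a second). Given $T_2^*$, $S_0$ enters linearly,
  so each accepted step is followed by a closed-form $S_0$ refinement,
  and when $S_0$ sits on a bound with the gradient pointing outward the
  step degenerates to a damped 1-D Newton step in $T_2^*$. Convergence:
  relative SSE decrease below `tolerance` (default $10^{-10}$) or a
  negligible parameter step; starts that exhaust `maxIterations`
  (default 200) are discarded.
* **Bounds** — $T_2^* \in [1, 800]$ ms. The upper bound sits far above
  tissue (~100–200 ms) and CSF (~400 ms at 3 T), so it never truncates
  plausible estimates; it exists so that non-decaying signals (e.g. pure
  noise or flat profiles) pin at 800 ms and are flagged `atBound` rather
  than producing an arbitrary number. $S_0$ starts and bounds are
  expressed as multipliers (default 0.1–2.0) of the voxel's maximum
  observed signal; note that with very short $T_2^*$ (below ~17 ms at
  this echo train) the first echo carries less than half of $S_0$ and
  the 2.0 multiplier can bind — irrelevant for fetal brain values but
  worth knowing when reusing the fitter.
* **Determinism** — start positions come from a counter-based RNG
  (splitmix64) keyed on `(seed, linear voxel index)`. Estimates are
  therefore bit-reproducible and independent of mask shape, voxel
  ordering, or parallel execution.
* **Degenerate inputs** — voxels whose first-echo signal is below
  `minSignal` (or exactly zero) are skipped; voxels where no start
  converges are flagged `fitOk = FALSE` and excluded from all downstream
  ROI statistics. Repeated dynamics are magnitude-averaged before
  fitting (an SNR gain; per-dynamic maps are not produced).

## ROI summarisation

The supratentorial ROI is processed in three steps, in this order:

1. **Conservative margin** — `erodeMask()` applies `margin` passes
   (default 1) of 6-connected morphological erosion, the operational
   counterpart of segmenting conservatively to keep non-cerebral tissue
   out of the ROI.
2. **CSF exclusion** — `applyCsfThreshold()` keeps voxels with fitted
   $T_2^* \le$ `cutoff` (default 250 ms) and `fitOk`. The threshold acts
   on fitted $T_2^*$, not raw signal: CSF is separated from tissue by a
   wide $T_2^*$ gap, making the cutoff robust to intensity scaling.
   Whether the original analysis thresholded $T_2^*$ or signal, and at
   what value, is not public; both the variable and the value are
   documented package choices, configurable per run.
3. **Summaries** — `summarizeROI()` reports the arithmetic mean of the
   in-mask $T_2^*$ values, their histogram skewness, and the ROI volume
   (voxel count × voxel volume, mL).

Skewness uses the adjusted Fisher–Pearson estimator
$G_1 = \frac{\sqrt{n(n-1)}}{n-2} m_3 / m_2^{3/2}$ by default (`g1`, the
unadjusted standardised third moment, is available), computed on the raw
voxel values rather than binned counts — binning would discard
information and no binning scheme is part of the method's definition.
$G_1$ of a constant ROI is undefined and reported missing with a
warning.

## Cohort-level statistics

Mean brain $T_2^*$ changes nonlinearly over gestation — rising to a peak
near 22 weeks as cell density increases, then declining — so the group
comparison uses **quadratic regression**: OLS of the outcome on GA, GA²,
a preterm-group indicator and an ethnicity covariate, with the group
coefficient (preterm − control, in outcome units) and its two-sided
p-value as the result. Volume and skewness use the same design with GA
entering linearly. Design choices where the analysis specification was
open:

* **Normality gate** — residuals are checked by Shapiro–Wilk at
  $\alpha = 0.05$; on failure the outcome is natural-log-transformed and
  the model refitted (`transformation_applied` records it). Outcomes
  with non-positive values (skewness can be negative) skip the transform
  with a warning.
* **Ethnicity coding** — binary White/non-White by default: with n = 92
  and near-empty cells in several of the five levels, full dummy coding
  is rank-unstable; the 5-level coding remains available
  (`ethnicityCoding = "full"`). If the covariate is collinear with the
  design it is dropped with a logged warning rather than silently
  propagating `NA`s.
* **No group × GA interaction** by default (a single group effect is the
  estimand); available as an option.
* **t-test variant** — pooled-variance Student's t for demographic
  comparisons (Welch optional); chi-squared without continuity
  correction for categorical variables, with a small-sample warning when
  any expected cell count falls below 1. Two-sided tests throughout, no
  multiple-testing correction. The demographic variables compared are
  maternal age, BMI and GA at MRI (continuous) and ethnicity and parity
  (categorical) — the variables the cohort-table contract carries.
* **Outcome tables** — percentages use the denominators a clinical
  summary table implies: delivery outcomes over all preterm subjects,
  neonatal complications over liveborn subjects, chorioamnionitis over
  subjects with histology available, funisitis over subjects with
  chorioamnionitis.

Regression estimates are invariant to centring GA; the test suite checks
this, the type-I error (5% ± 2% over 500 null replicates at the 25 vs 67
sample sizes), and that power grows with the simulated effect size.

## What the simulator emulates — and what it does not

`makePhantom()` builds ellipsoidal digital phantoms: a brain-tissue
compartment, a CSF compartment carved out of it (CSF takes precedence on
overlap), and zero-signal background. Each voxel's noiseless signal
follows the forward model exactly; noise is **Rician** — the magnitude of
the noiseless signal plus independent complex Gaussian noise of standard
deviation `noiseSigma` per channel, per echo and dynamic — as appropriate
for magnitude MRI. The Rayleigh limit ($\sigma\sqrt{\pi/2}$ mean in
zero-signal voxels) and the high-SNR limit are verified by Monte-Carlo
tests. Defaults: 32³ grid at 3 mm isotropic (a mid-gestation fetal head
is ~10 cm across), tissue $S_0 = 100$, CSF $S_0 = 120$, and
`noiseSigma = 2`, giving first-echo tissue SNR ≈ 50.

`simulateCohort()` draws, per subject, a gestational age uniformly from
19.3–31.7 weeks and a tissue $T_2^*$ of

$$ T_2^*(GA) = a\,GA^2 + b\,GA + c \;+\; \Delta\cdot
   \mathbb{1}[\text{preterm}] \;+\; \varepsilon,\qquad
   \varepsilon \sim N(0, \sigma_b^2), $$

then renders and writes a phantom per subject (per-subject RNG streams
derived from `(seed, subject index)`, so cohorts reproduce
subject-by-subject). No absolute fetal-brain $T_2^*$ values at 3 T were
available to anchor the trajectory, so its level is an explicit
assumption: the default $(a,b,c) = (-0.6, 26.4, -110.4)$ peaks at 180 ms
at 22 weeks and falls to ~120 ms by 32 weeks, consistent in shape with
the reported rise-then-decline and in scale with fetal values at 3 T
being roughly double adult tissue values. The default group offset
$\Delta = -8$ ms was chosen by a closed-form power computation: with
$\sigma_b = 10$ ms and 25 vs 67 subjects, the group contrast has a
standard error near 2.5 ms (including the variance inflation from the
ethnicity imbalance), giving ~85% power at $\alpha = 0.05$ — a
detectable-but-not-trivial effect appropriate for validating the
detection machinery.

Two skewness mechanisms are provided and deliberately kept distinct. At
image level, preterm phantoms receive a low-$T_2^*$ subpopulation
(default: 15% of tissue voxels lowered by 30 ms), a crude stand-in for
focal tissue heterogeneity; a low-value subpopulation necessarily drives
$G_1$ **negative**, and the tests assert exactly that sign behaviour. At
summary level, `simulateSummaryTable()` instead gives preterm subjects a
**positive** skewness offset (+0.3 by default), reproducing the
direction of the reported group difference directly. The two cannot be
reconciled by a single low-$T_2^*$ mechanism — that is a genuine tension
in the phenomenon's description, and the package exposes rather than
hides it: the image-level mechanism demonstrates that the skewness
statistic responds to within-brain heterogeneity with the
mathematically forced sign, while the summary-level simulator carries
the reported between-group direction into the regression machinery.

Simulated demographics (maternal age, BMI, ethnicity, parity, delivery
outcomes, histology flags) are drawn from the published group summary
statistics and exist only to exercise the comparison code paths.

The phantoms deliberately do **not** model anatomy (gyrification, tissue
parcellation), fetal motion, EPI distortion, B0 inhomogeneity, partial
volume at compartment boundaries beyond voxelisation, or slice-profile
effects. Passing the recovery tests therefore shows that the estimation
chain is correct under its own noise model at realistic SNR — not that
clinical fetal data, with motion and artefact, would be recovered with
the same fidelity. The headline clinical findings (lower mean brain
$T_2^*$ before very preterm birth, higher skewness, no volume
difference) depend on unreleased clinical images and are validated here
only as *direction checks* on simulated cohorts plus operating
characteristics of the tests.

## Problem sizes used in validation

The shipped validation (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) uses: 100 random noiseless draws for the oracle
equivalence; one 64³ phantom (~58,000 tissue voxels) plus a 3,000-replicate
grid-search Monte-Carlo oracle for recovery error; 120,000 replicate
voxels per noise level (common random numbers across
$\sigma \in \{4, 2, 1, 0.5\}$) to resolve the ~0.01–1 ms noise-induced
bias ordering; 500 null and 300 alternative cohort replicates at the
25 + 67 design for type-I error and power; and a full 92-subject
image-level pipeline run on 16³ phantom grids for the end-to-end
direction check — sizes chosen so each quantity's Monte-Carlo
uncertainty is small against the margin being tested while the whole
suite stays desk-scale.

## Known limitations

* The erosion structuring element is fixed to 6-connectivity; anisotropic
  margins are not supported.
* `readT2StarMap()` restores estimates and the fit-OK flag from disk but
  not the per-voxel residual/convergence diagnostics (stored maps carry
  only the three volumes plus provenance).
* The CSF threshold assumes the tissue–CSF $T_2^*$ gap; in pathologies
  that raise tissue $T_2^*$ toward the cutoff the exclusion would bite
  into tissue.
* The cohort regression treats subjects as independent and GA as exact;
  measurement error in GA dating is not modelled.
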