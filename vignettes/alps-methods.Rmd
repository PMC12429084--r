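---
title: "Methods: synthetic DTI-ALPS phantoms, cohort simulation, and bootstrap mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic DTI-ALPS phantoms, cohort simulation, and bootstrap mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsim)
```

`alpsim` implements the analysis chain used to study glymphatic function in
silent cerebral small vessel disease: compute the DTI-ALPS index from
diffusion MRI, grade enlarged perivascular space (ePVS) burden, and test
whether the index mediates the association between ePVS and processing
speed. Because cohorts of this kind are rarely shareable, the package puts
equal weight on a synthetic-data layer that reproduces the statistical
structure such an analysis assumes, so every stage can be validated against
known ground truth.

## The diffusion model and the ALPS index

Each voxel's signal follows the monoexponential tensor model
$S(g, b) = S_0 \exp(-b\, g^\top D g)$ with $D$ a symmetric positive
semi-definite 3×3 tensor in the scanner frame (x = right–left,
y = anterior–posterior, z = superior–inferior). `fit_tensor()` estimates
$(\ln S_0, D)$ per voxel by ordinary least squares on $\ln S$ with design
rows $(1, -b g_x^2, -b g_y^2, -b g_z^2, -2b g_x g_y, -2b g_x g_z,
-2b g_y g_z)$ — the classical log-linear fit, exact on noiseless data. This
needs at least one unweighted volume and six independent directions; fewer
is an error rather than a silently unstable fit.

At the level of the lateral-ventricle body, perivascular spaces run
predominantly right–left, perpendicular both to projection fibers (mainly
superior–inferior) and association fibers (mainly anterior–posterior).
Diffusivity along x in those two fiber systems therefore partly reflects
water movement along the perivascular spaces, and the index is

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{x\text{-}proj},\ D_{x\text{-}assoc})}
                      {\mathrm{mean}(D_{y\text{-}proj},\ D_{z\text{-}assoc})}.$$

Two properties are worth stating explicitly because the tests rely on
them:

* The $D_x, D_y, D_z$ entering the index are **diagonal tensor elements in
  the scanner frame, not eigenvalues**. For a fiber oblique to the axes the
  largest eigenvalue exceeds $D_{xx}$; `axis_diffusivities()` is tested to
  return the frame-dependent diagonals. Fractional anisotropy, by
  contrast, is computed from eigenvalues and is rotation-invariant.
* The index is scale-invariant: multiplying every tensor by $k > 0$
  leaves it unchanged.

ROIs are 5 mm spheres (12 voxels at the 2.5 mm isotropic resolution of the
emulated acquisition). Manual ROI placement is not reproducible in code, so
`roi_voxels()` determinizes it: the `target_voxel_count` voxels nearest the
center in millimetre distance, ties broken by lexicographic voxel index,
with an error if the ball would leave the volume. ROIs are placed in one
(left) hemisphere only, matching the acquisition protocol being emulated;
no left/right averaging is performed. The subcortical ROI is carried in
results for completeness but never enters the index — the formula uses only
the projection and association terms.

## Phantom construction

`phantom_spec()` partitions a grid (default 16³ voxels of 2.5 mm) into
projection, association and subcortical slabs plus isotropic background.
Each region gets a diagonal tensor: dominant diffusivity `d_axial`
(default 1.6e-3 mm²/s) along its fiber axis, perpendicular diffusivities
`d_perp_proj` = 0.8e-3 (y, projection region) and `d_perp_assoc` = 0.7e-3
(z, association region) — values in the range typical of deep white
matter. The x-axis entries are then solved by inverting the index formula
(`solve_axis_diffusivities()`, equal split between the two regions), so
the noiseless pipeline returns `target_alps` *exactly*; the roundtrip is
tested to 1e-6 across targets 1.0–2.5. An isotropic configuration gives
index 1 by construction.

The gradient table of the emulated protocol (32 directions, b = 1000
s/mm²) is not published, so the package uses a deterministic spherical
Fibonacci lattice plus one b0: near-uniform angular coverage that is
identical on every run and machine, stored in FSL bval/bvec dialect.

Noise is Rician, the correct model for magnitude MRI: the noiseless signal
is perturbed in two independent Gaussian channels of standard deviation
$S_0/\mathrm{SNR}_{b0}$ and the modulus taken. At SNR(b0) = 30 the
diffusion-weighted signal SNR is ~10, where the log-linear fit acquires a
small noise-floor bias; the group mean over 20 replicate phantoms is
nonetheless tested to recover the prescribed index within ±0.05.

Numerical details: signals at or below zero are clipped to
$10^{-8} S_0$ before the logarithm (avoids $-\infty$ under heavy noise);
tensors with negative eigenvalues are clamped to the nearest PSD tensor
and flagged per voxel (`clamped`), keeping downstream ROI means defined
while recording the degradation; voxels with no usable signal carry
`fit_ok = FALSE` and are excluded from ROI means, and an all-bad ROI is an
error.

## The synthetic cohort

`cohort_params()` defaults encode the replication study conditions: n = 60
adults aged 25–65 with low-to-moderate QRISK3 scores (the QRISK3 algorithm
itself is out of scope; scores are simulated within the 0–20% band and
only the published category thresholds are implemented), ePVS prevalence
43.3%, per-group means and SDs for age, SBP, BMI, QRISK3 and the WAIS-IV
indices, group flag rates for family history and hypertension, and ALPS
group summaries 1.80 ± 0.15 (no ePVS) versus 1.55 ± 0.30 (ePVS).

The mediator and outcome follow a standardized structural model with the
published path coefficients as generating truth:

* `alps_std` $= a\,X + \beta_{age} z_{age} + \varepsilon_M$, with binary
  exposure $X$ (ePVS), $a = -0.2813$, $\beta_{age} = -0.25$ (consistent in
  sign and size with the reported overall age–ALPS correlation of about
  −0.35), $\varepsilon_M \sim N(0, 0.945^2)$;
* `psi_std` $= b\,\mathrm{alps\_std} + c' X + \varepsilon_Y$ with
  $b = +0.8861$, $c' = 0.0412$, $\varepsilon_Y \sim N(0, 0.472^2)$.

The residual SDs are derived analytically so both constructed variables
have unit variance under the defaults, making the standardized fitted
coefficients directly comparable to the generating ones.

**Two ALPS scales on purpose.** The published group summaries
(1.80 ± 0.15 vs 1.55 ± 0.30) imply a standardized group separation of
roughly one SD, which cannot coexist in a single linear model with a
standardized exposure path of −0.28. The generator therefore carries both
scales: `alps`/`psi` are per-group affine rescalings of the structural
columns onto the configured group means and SDs (so printed group
summaries are recovered exactly by construction), while
`alps_std`/`psi_std` preserve the structural scale on which the path
coefficients are defined. Path-recovery analyses use the `_std` columns;
group-comparison analyses use the rescaled ones. This is a design
decision, documented here, not a property of any dataset.

Regional ePVS counts have no published distribution; the ePVS group draws
a shifted negative binomial (1 + NB with size 2 and mean 9 in the basal
ganglia, 11 in the centrum semiovale), giving mostly grades 1–3 as is
typical of community cohorts, and the no-ePVS group has zero counts.
Grades are always derived from counts through `grade_epvs()`, so the
count–grade invariant holds by construction. Binary exposure stays 0/1 in
all models; only the mediator and outcome are z-scored before path
estimation.

What the generator does **not** emulate: whole-brain anatomy, white matter
hyperintensities or visible ePVS lesions on the images, scanner artifacts
needing eddy-current or motion correction, non-Gaussian covariate
dependence beyond the group structure, or rater behaviour. Passing tests
therefore demonstrate the correctness and calibration of the *analysis*
under the stated generative assumptions — not the clinical validity of the
index on real scans.

## Rater agreement and categories

`cohens_kappa()` implements unweighted Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ with the Fleiss–Cohen–Everitt
large-sample variance for the confidence interval and the null-variance z
test for p; the variance formula was verified against an independent
reference implementation and those values are frozen in the tests.
Unweighted (rather than linearly weighted) kappa is used because the
emulated protocol reports only "kappa coefficients". When both raters use
a single category in perfect agreement, kappa is defined as 1 with a
degenerate, flagged interval. QRISK3 bands are applied with the printed
boundaries; scores falling in the printed gaps (e.g. 10.05) are assigned
upward, i.e. the operative rules are "> 10" and "> 20".

## The statistical battery

Standard tests are delegated to the R `stats` implementations behind a
uniform result type; the summary-statistic forms of the pooled t test and
Cohen's d are closed-form so printed tables can be audited without raw
data. All tests are two-sided. The choice between t and Mann–Whitney is an
explicit configuration flag (`use_ranks`), defaulting to t for the
replication recipe, since no normality-test rule is published. Logistic
models use Wald intervals (the convention of the SPSS lineage this
replicates), report odds ratios per unit, and per SD by refitting with
z-scored continuous predictors; complete separation is flagged
(`converged = FALSE`) instead of reporting meaningless estimates. VIFs are
$1/(1-R_j^2)$ from regressing each predictor on the rest. Fisher's exact
p is the two-sided hypergeometric-summation rule; the test suite checks it
against a full enumeration oracle over every 2×2 table with total n ≤ 60
(up to the row/column/transpose symmetries under which the p-value is
invariant), and checks the pooled t test's type-I error over 10,000 null
simulations.

One published value is knowingly not reproduced: a Cohen's d of −0.41 for
the processing-speed contrast, which none of the standard formulas
(pooled, control-SD, small-sample corrected) yields from the printed group
summaries (they give −0.44 to −0.47). The package reports the pooled-SD
value (−0.465) and does not force agreement.

## Mediation with bias-corrected bootstrap intervals

`mediate()` fits three OLS regressions on complete cases — mediator on
exposure + covariates (path a), outcome on exposure + mediator +
covariates (b, c′), outcome on exposure + covariates (c) — after
optionally z-scoring mediator and outcome. The indirect effect is
$a \cdot b$, and the OLS decomposition $c = c' + ab$ holds to numerical
precision on every sample, which the tests assert at 1e-10. Default
covariates are age, sex and QRISK3.

Inference resamples whole rows with replacement (case resampling,
covariates included) `n_boot` times (10,000 in the replication recipe) and
recomputes $a \cdot b$. Replicates in which the exposure collapses to a
single level are dropped and redrawn, capped at 10× `n_boot` attempts.
The interval is bias-corrected (BC, no acceleration term):
$z_0 = \Phi^{-1}(\#\{ab^* < ab\}/B)$, bounds at the empirical type-7
quantiles of $\Phi(2z_0 \mp z_{1-\alpha/2})$. The proportion defining
$z_0$ is clamped to $[1/(B+1), B/(B+1)]$ so the correction stays finite;
an all-constant bootstrap yields a degenerate, flagged interval. BC rather
than BCa is deliberate — it is the stated method of the emulated analysis
— and the Sobel test is intentionally not offered as primary inference.
A `t_stat = indirect / boot_sd` is exposed for descriptive comparison
only; it has no exact reference distribution and is not validated.

Calibration at the study's own size is part of the test suite: across 400
simulated cohorts of n = 60 with the default paths, the 95% BC interval
is required to cover the true indirect effect in 90–98% of runs (bootstrap
coverage at small n is approximate by nature), and with a pure-noise
mediator it may exclude zero in at most ~9% of runs.

## Problem sizes and reproducibility

Analyses in the test suite and acceptance script use: 16³-voxel phantoms
(12³ for pure-geometry tests) with 32 + 1 volumes; 20 replicate phantoms
for the noisy-recovery check; cohorts of n = 60 for study-scale checks,
n = 5,000 for path recovery (averaged over 16 replicate cohorts, since the
per-replicate Monte-Carlo SD of the exposure path is ≈ 0.04 and the mean
then resolves the generating value to ≈ 0.01), and n = 50,000 for marginal
convergence; 10,000 resamples for the canonical bootstrap and 399–499 for
repeated-simulation calibration loops. These sizes were chosen so each
check's Monte-Carlo error is small relative to what it asserts.

Every stochastic stage consumes an explicit integer seed; the pipeline
fans a single global seed out to per-stage child seeds by a fixed affine
scheme (`child_seed()`), so stages rerun in isolation reproduce their
in-pipeline results, and `run_pipeline()` reports are bit-identical given
the same configuration and seed.

## Known limitations

* Phantoms are piecewise-constant and artifact-free; they validate the
  estimator chain, not robustness to motion, eddy currents or partial
  volume.
* The ALPS ROI placement rule is a determinization of what is in practice
  a manual, SOP-guided step; real-data use requires user-supplied ROI
  centers (no atlas registration is provided).
* The per-group affine rescaling that pins group summaries exactly also
  means the rescaled `alps` column's standardized group contrast is, by
  construction, larger than the structural path a — use the `_std`
  columns for path-scale questions.
* Whether published rater agreement was computed on grades or on
  dichotomized presence/absence is unspecified; the package computes kappa
  on whatever categorical vectors it is given.
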