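# alpsim

Glymphatic (perivascular clearance) dysfunction is a proposed mechanism
behind enlarged perivascular spaces (ePVS), an early imaging sign of
cerebral small vessel disease that is associated with slower cognitive
processing even in asymptomatic adults. The DTI-ALPS index — *diffusion
tensor image analysis along the perivascular space* — is a non-invasive
proxy for glymphatic function read from an ordinary diffusion MRI scan.

`alpsim` is an R package for researchers who want to compute, simulate and
stress-test this analysis chain end to end:

* **Synthetic data.** Diffusion-weighted phantoms whose region tensors are
  solved so the noiseless pipeline returns a prescribed ALPS value exactly,
  degraded with Rician noise at a configurable b0 SNR; and cohort tables
  with configurable ePVS prevalence, group means and structural mediation
  paths, so every downstream stage is testable without patient data.
* **Tensor fitting.** Log-linear least-squares diffusion tensor estimation
  from NIfTI + FSL-style bval/bvec inputs, with axis diffusivities
  (scanner-frame Dxx/Dyy/Dzz) and fractional anisotropy.
* **ALPS index.** Deterministic spherical ROI selection (nearest-12-voxel
  rule) and the index

  ```
  ALPS = mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc)
  ```

  where `Dx_*` is diffusivity along the perivascular (right–left) axis in
  projection- and association-fiber ROIs and the denominator is diffusivity
  perpendicular to the dominant fibers.
* **ePVS grading and agreement.** The 0–4 semi-quantitative count scale
  (0; 1–10; 11–20; 21–40; ≥41), QRISK3 risk bands (low ≤10%, moderate
  10.1–20%, high ≥20.1%) and unweighted Cohen's kappa with its
  large-sample confidence interval.
* **Cohort statistics.** Pooled and Welch t tests (summary-statistic and
  raw forms), Mann–Whitney U, chi-square and Fisher exact tests, Pearson
  correlation, Cohen's d, logistic and linear regression (odds ratios per
  unit and per SD, standardized betas) and variance inflation factors.
* **Mediation.** Simple mediation (binary exposure → mediator → outcome
  with covariates) estimated by OLS path regressions, with the indirect
  effect `a·b` bootstrapped by case resampling and summarized with
  bias-corrected (BC) percentile intervals.

## Worked example

Recover a prescribed index through the full pipeline, then estimate the
mediation paths on a simulated cohort:

```r
library(alpsim)

# phantom prescribed at ALPS = 1.80, Rician noise at SNR(b0) = 30
spec <- phantom_spec(target_alps = 1.80, snr_b0 = 30, seed = 42)
dwi  <- generate_dwi_phantom(spec)
compute_subject_alps(dwi, phantom_rois(spec))
#> <alps_result> ALPS index 1.8020
#>   Dx-proj 0.001331  Dy-proj 0.0007945  Dx-assoc 0.001345  Dz-assoc 0.0006909 (mm2/s)

# simulated cohort: ePVS -> ALPS -> processing speed
cohort <- generate_cohort(cohort_params(n_subjects = 2000, seed = 1))
mediate(cohort, mediation_spec(mediator = "alps_std", outcome = "psi_std",
                               n_boot = 10000, seed = 2))
#> <mediation_result>
#>   a = -0.2809 (p = 5.58e-07), b = 0.8894 (p = 0), c' = 0.0509 (p = 0.0745)
#>   indirect a*b = -0.2498, 95% BC CI (-0.3510, -0.1508), c = -0.1990
#>   10000 bootstrap resamples, boot SD 0.0507
```

The recovered index (1.802) sits within noise of the prescribed 1.80; the
fitted paths match the generating coefficients (a = −0.2813,
b = +0.8861), the direct effect c′ is small and non-significant, and the
BC interval for the indirect effect excludes zero — the partial-mediation
pattern the generator encodes. A published group summary can be audited
directly from printed numbers:

```r
pooled_t_test(98.7, 12.7, 26, 105.1, 14.5, 34)
#> <stat_test_result> pooled-variance two-sample t test
#>   statistic = -1.786, df = 58, p = 0.07929
#>   effect size = -6.4 (-13.57 to 0.7722)
```

`run_pipeline(replication_recipe(seed = 1))` executes the whole chain
(cohort → phantoms → statistics → mediation) and returns a consolidated,
seed-reproducible report.

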