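# rsfcmed

Seed-based resting-state functional connectivity (RSFC) mediation analysis
for R: does brain connectivity carry part of a behaviour-symptom
relationship?

The package is aimed at researchers who have a per-subject behavioural
predictor X (for example an experiential-acceptance score), a clinical
outcome Y (for example post-traumatic stress symptom severity), and
resting-state fMRI. It implements the full analysis chain:

* **Cleaning** of realigned 4D images: discarding of initial volumes, motion
  quality control (1.5 mm / 1.5 degree / mean-FD 0.5 mm exclusion rules),
  nuisance regression with Friston-24 motion parameters, FD-based spike
  ("scrubbing") regressors, CompCor components from a noise-tissue mask and
  a linear trend, then Gaussian smoothing (4 mm FWHM) and ideal band-pass
  filtering (0.01-0.1 Hz).
* **Connectivity**: hippocampal-style seed partition into head/body/tail
  along the anterior-posterior axis, seed-mean time series, per-voxel
  Pearson correlation and Fisher r-to-z maps — the voxel-wise mediator M.
* **Mediation**: at every voxel the three-path model with covariates in all
  equations,

      M = a X + C g1 + e1
      Y = c' X + b M + C g2 + e2
      Y = c X + C g3 + e3        (so that a*b + c' = c exactly)

  with two-tailed bias-corrected bootstrap p-values for a, b, a*b and c'
  (subjects resampled with replacement; shared resample indices across
  voxels make whole-brain runs a few BLAS products).
* **Inference**: cluster-extent family-wise error correction from the
  permutation distribution of the maximum supra-threshold cluster size,
  with Freedman-Lane handling of covariates and sign-homogeneous clusters.
* **Power**: the Monte Carlo power analysis for indirect effects
  (per replication: fit M~X and Y~X+M on a simulated trivariate-normal
  sample, then test whether the equal-tail interval of a\*b\* over normal
  draws at the fitted estimates excludes zero).

Because the motivating clinical dataset is not public, a synthetic-cohort
generator (`cohort_spec()`, `gen_cohort()`) plants known standardized path
coefficients into simulated 4D images — including band-limited BOLD-like
signal, a structured confound for CompCor to find, and motion spikes for the
exclusion rules to catch — so every stage is testable against ground truth.

## A worked example

Simulate a cohort with a planted mediation effect (a = 0.65, b = 0.45,
direct path 0.3), run the whole pipeline, and read the cluster table:

```r
library(rsfcmed)

spec <- cohort_spec(n_subjects = 35, n_volumes = 200, grid = c(12, 12, 6),
                    rng_seed = 88, high_motion_subjects = c(5, 21))
cfg  <- run_config(spec = spec, B = 300, n_perm = 120,
                   alpha_primary = 0.05, rng_seed = 17)
res  <- run_pipeline(cfg)

res$qc$subject_id[res$qc$excluded]
#> [1] "sub005" "sub021"

dplyr::select(res$clusters, label, size, sign, corrected_p, mean_a, mean_b)
#> # A tibble: 4 x 6
#>   label  size  sign corrected_p   mean_a mean_b
#>   <int> <int> <dbl>       <dbl>    <dbl>  <dbl>
#> 1     1    45     1      0.0248  0.0286    11.4
#> 2     2     1     1      1       0.00515   19.9
#> 3     3     1     1      1      -0.00725  -22.6
#> 4     4     1    -1     1      -0.00496   21.4
```

The two deliberately high-motion subjects are excluded by the mean-FD rule
(35 scanned, 33 analysed). The 45-voxel cluster with corrected p = 0.025
sits inside the planted target region: its positive sign says acceptance and
symptom severity share a positively mediated path there, and `mean_a`,
`mean_b` are on the raw questionnaire scales (z per AAQ point; CAPS points
per z). Every run directory also receives the QC report, per-subject z-maps,
the mediation coefficient and p-value maps as NIfTI, the cluster label map,
and a provenance JSON with the configuration hash and seeds.

Single pieces work standalone, tidyverse-style:

```r
fit <- bootstrap_paths(x, m, y, covariates, B = 10000, rng_seed = 1)
tidy(fit)       # one row per path: estimate, std.error, p.value
glance(fit)     # n, B, flavor, redraw count

power_curve(c(20, 33, 60, 100)) |> autoplot()
```

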