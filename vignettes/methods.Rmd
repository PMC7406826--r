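---
title: "Methods: seed connectivity, voxel-wise mediation and permutation cluster inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed connectivity, voxel-wise mediation and permutation cluster inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfcmed)
```

# The scientific question

Experiential acceptance — the willingness to remain in contact with
distressing internal experience — is inversely related to post-traumatic
stress symptom severity. `rsfcmed` implements the analysis chain used to ask
whether that behavioural relationship is *mediated* by the brain: does
resting-state functional connectivity (RSFC) from hippocampal subregion seeds
to the rest of the brain carry part of the acceptance-to-symptom effect?

The pipeline has five stages, each exposed as ordinary functions:

1. **Cleaning** of realigned 4D BOLD images: volume discarding, motion
   quality control, nuisance regression, spatial smoothing, band-pass
   filtering.
2. **Connectivity**: subregion seed definition and per-subject seed-to-voxel
   Fisher-z maps — the candidate mediator at every voxel.
3. **Mediation**: the three-variable path model at every voxel with
   covariates and bootstrap inference.
4. **Inference**: cluster-extent family-wise error (FWE) correction by
   subject permutation.
5. **Power**: the Monte Carlo power analysis for indirect effects used to
   justify the sample size.

Because the underlying clinical dataset is not publicly available, the
package ships a synthetic-cohort generator that plants *known* path
coefficients into simulated images, so every stage can be validated against
ground truth. All statistical claims in the test suite are claims about this
generator's planted structure.

# The mediation model

For predictor $X$ (acceptance score), outcome $Y$ (symptom severity), and
mediator $M_v$ (Fisher-z connectivity at voxel $v$), with covariates $C$
(age, sex, depression, dissociation) in *all three* regressions:

$$M_v = a_v X + C\gamma_1 + \varepsilon_1, \qquad
  Y = c'_v X + b_v M_v + C\gamma_2 + \varepsilon_2, \qquad
  Y = c_v X + C\gamma_3 + \varepsilon_3.$$

The indirect effect is $a_v b_v$; with identical covariate sets the OLS
identity $a_v b_v + c'_v = c_v$ holds exactly, which the test suite uses as a
free correctness check (to $10^{-8}$ at every voxel). Symmetric covariate
placement is a deliberate design choice: the identity fails under any other
placement, and it is what makes the decomposition interpretable.

Inference per path uses the nonparametric bootstrap over subjects:
resample rows with replacement, refit all paths, and invert the
bias-corrected (BC) percentile interval into a two-tailed p-value. With $q$
the bootstrap fraction below zero and $z_0$ the median-bias correction, the
p-value is $2\min\{\Phi(w), 1-\Phi(w)\}$ with $w = \Phi^{-1}(q) - 2z_0$,
floored at $1/B$ so that log transforms and strict thresholds stay
well-defined. A plain percentile flavor is available
(`flavor = "percentile"`); BC is the default because it is the convention of
the standard mediation toolboxes. X and Y enter unstandardized by default
(scores are on their questionnaire scales); `standardize = TRUE` switches
all three variables to z-scores, putting paths on the correlation scale.

## Vectorization of the voxel-wise bootstrap

`voxelwise_mediation()` shares one set of bootstrap resample indices across
voxels. For a resample with selection matrix $S$ and covariate
residual-maker $P$ (of $[1, C]$ on the resampled rows), every statistic the
model needs is a linear or quadratic form in the subject-space matrix
$Q = S^\top P S$:

$$\widetilde{x}^\top M_S = (Qx)^\top M, \quad
  \widetilde{x}^\top\widetilde{x} = x^\top Q x, \quad
  \widetilde{M}^\top\widetilde{M} = M^\top Q M,$$

so one pass over all voxels is a handful of BLAS products, and — because $Q$
does not involve $X$ — the same precomputed "plan" serves the observed data
and every permutation pass. Sharing indices across voxels preserves the
joint spatial structure of the bootstrap distribution, makes maps
independent of voxel order, and is what keeps the permutation studies below
tractable. Degenerate resamples (collinear covariates after resampling) are
redrawn and counted; more than 10% is an error.

# Cluster-extent FWE by subject permutation

The original toolbox era used several cluster-correction engines and the
analysis description does not pin one down, so the package implements the
assumption-light choice: a max-statistic permutation test.

* The observed `p_ab` map is thresholded at the primary `alpha_primary`
  (strictly below), split by the sign of $a b$ so clusters are
  sign-homogeneous, and clustered under an 18-neighbourhood by default
  (6 and 26 available).
* The null is built by permuting the predictor with the **Freedman-Lane**
  scheme — residuals of $X$ on $C$ are permuted and the fitted part
  re-added — and re-running the identical voxel-wise bootstrap test, with
  the same resampling plan, for each of `n_perm` permutations. The maximum
  supra-threshold cluster size over both sign maps is recorded.
* An observed cluster of size $s$ gets
  $p_{corr} = (1 + \#\{\text{perm max} \ge s\})/(1 + n_\text{perm})$,
  never below $1/(1+n_\text{perm})$.

Because the identical statistic map is applied to every relabelling, the
corrected p-values inherit finite-sample exchangeability validity at *any*
primary threshold, bootstrap budget, grid size, or mediator correlation
structure. That scale-freeness is what licenses the desk-scale settings used
in the tests (below).

**A compatibility note on budgets.** The bootstrap p-value cannot go below
$1/B$. At the published operating point ($B = 10{,}000$, primary threshold
$p < 0.001$) that is no constraint, but a scaled-down null pass with
$B = 500$ has a floor of $0.002$ and would render a $0.001$ threshold
unreachable for every permutation — an anticonservative mismatch.
`cluster_fwe()` therefore warns when `alpha_primary <= 1/B`, and all
scaled-down runs in this package pair reduced budgets with
`alpha_primary = 0.05`, identically in observed and null passes.

# The synthetic cohort

`cohort_spec()` fixes the study conditions: 33 subjects, 200 volumes at
TR = 2 s (the first four discarded downstream), a 20 x 20 x 10 grid of
3 x 3 x 4.5 mm voxels, and three disjoint regions — a seed block spanning
nine slices along the anterior-posterior axis (so the head/body/tail thirds
rule applies), a 75-voxel target block, and a noise block standing in for
white matter and CSF. Behavioural marginals are calibrated to a
trauma-exposed clinical sample: AAQ-II 39.89 (SD 11.03), CAPS-5 25.27 (11.0),
BDI-II 25.15 (13.62), DES-II 17.08 (23.89), age 40.36 (11.10) truncated to
18-65, 42% female. BDI and DES values are drawn untruncated so the marginals
are exact.

## Planted structure and its calibration

All planted paths are **standardized**: `a_true` is the across-subject
correlation between $X$ and the target-voxel Fisher z *after the default
cleaning pipeline*; `b_true` and `c_prime_true` are standardized outcome
paths of the subject-level latent mediator. The variance budget on the z
scale ($\sigma_z = 0.5$, mean $z_0 = 0.3$) is split into the $X$-driven part
($\beta = a\,\sigma_z$), a subject-level residual $\eta$, voxel jitter
(SD 0.1), and finite-scan measurement noise whose variance is $1/m$ with $m$
the number of Fourier coefficients the analysis band keeps — for 196 retained
volumes at TR = 2 s and a 0.01-0.1 Hz band, $m = 72$.

At the image level, each subject's seed voxels share a unit-SD latent signal
band-limited to 0.01-0.08 Hz (so it survives the band-pass stage); target
voxels add $w_{iv}\, s_i(t)$ with

$$w_{iv} = \sigma_\text{eff}\,\sinh(\zeta_{iv}), \qquad
  \sigma_\text{eff} = \text{noise SD} \times \sqrt{\kappa},$$

where $\zeta_{iv}$ is the planted z value and $\kappa$ is the closed-form
fraction of spatially white noise variance surviving the smoothing kernel
(product over axes of the kernel's sum of squares; the temporal factor is 1
because voxel noise is synthesized inside the analysis band). With that
calibration the post-pipeline correlation at an interior target voxel is
$\tanh(\zeta)$ — the transform is exactly the identity on the z scale. The
calibration constant is therefore not fitted; it is derived from the same
kernel code the smoothing stage uses.

Two honest imperfections remain. Smoothing dilutes coupling at region
*boundaries* (neighbouring voxels carry no signal), so parameter-recovery
evaluations read the planted effect at the region core (`region_core()`),
and residual confound variance plus nuisance-regression losses shrink the
realized slope a few percent; both are absorbed by the standardized
(correlation-scale) recovery convention, which is invariant to linear
rescaling. Voxel-wise `b` recovery is additionally attenuated by
measurement error in the mediator (a classical errors-in-variables effect,
about 10% at these settings); the observed `b` at n = 500 lands near 0.41
for a planted 0.45, well inside the 0.1 recovery band, and the attenuation
is predicted by the variance budget rather than tuned.

A rank-3 structured confound (three shared time courses) loads strongly on
noise-region voxels and weakly (0.3 SD) on all brain voxels, giving CompCor
a recoverable target; motion traces are a small random walk plus occasional
single-volume spikes drawn from 0.6-1.0 mm with alternating signs — large
enough that framewise displacement exceeds the 0.5 mm scrubbing threshold,
small enough never to trip the 1.5 mm absolute-translation exclusion on top
of the walk. Subjects listed in `high_motion_subjects` get a 0.5 spike
probability and reliably fail the mean-FD criterion, mirroring the 35 to 33
exclusion pattern.

Three generation levels trade fidelity for speed: `"latent"` (behaviour and
planted z field only), `"zmap"` (adds measurement noise directly on the z
scale — the fast path for replicate studies), and `"image"` (full 4D
synthesis; `gen_subject_volume()` streams one subject at a time so a
500-subject cohort never sits in memory). The zmap level emulates the
*output* of the cleaning chain, not the chain itself; agreement between the
two levels is part of the test suite.

What the generator does **not** emulate: scanner artifacts, slice timing,
hemodynamic response shape, anatomical variability, spatially varying noise,
or registration error. Passing tests therefore show that the estimators
recover what the model plants under realistic dimensions and noise levels —
not that the pipeline is robust to everything real data can do.

# Cleaning-chain choices

* **FD** is backward-difference with rotations converted at a 50 mm head
  radius — the convention of the motion-artifact literature the exclusion
  thresholds come from. Motion files store radians; the 1.5 degree criterion
  is converted internally so there is exactly one unit conversion.
* **Scrubbing** is implemented as per-volume spike regressors
  ($t-1, t, t+1, t+2$ around each FD > 0.5 event) inside the single nuisance
  regression, not as volume deletion — matching the "scrubbing regressors"
  reading and keeping series lengths intact for the FFT filter.
* **CompCor** extracts principal-component *time courses* from the pooled
  noise mask after per-voxel linear detrending and variance normalization;
  five components by default, read as five from the union of white matter
  and CSF (the toolbox default) rather than five per tissue. Components are
  unit-norm with a fixed sign convention so runs are reproducible.
* **Regression before smoothing before band-pass** follows the described
  order even though some practitioners filter first; the stages are pure
  functions, so other orders are a composition away.
* **The band-pass is an ideal frequency mask** (retain $0.01 \le f \le 0.1$
  Hz inclusive, zero everything else including DC). A hard mask has exactly
  testable pass/stop behaviour and exact linearity, which the suite asserts;
  a Butterworth option was considered and rejected as the default because
  its contracts are approximate.
* Rank-deficient nuisance designs fall back to the pseudoinverse with a
  warning rather than failing: a degenerate column (e.g. a motionless
  parameter) should not abort a batch run.
* The seed partition is a geometric thirds rule along the
  anterior-posterior axis (ties to head first, then body). Anatomical
  landmark placement is manual in practice and cannot be automated from a
  description; real-data mode accepts pre-labelled subregion masks instead.

# Desk-scale study sizes

The replicate studies in the acceptance tests use sizes chosen once, for
runtime, with the statistical claims unchanged by scale:

* Power reproduction: 1000 replications x 20,000 Monte Carlo draws (the
  cited application's defaults).
* Type-I calibration of the single-voxel `ab` test: 400 independent planted
  null cohorts (`a_true = 0`, live `b`), n = 33, B = 1000.
* FWE calibration: 400 null cohorts on a 10 x 10 x 5 grid with B = 100,
  49 permutations, primary threshold 0.05 — validity of the permutation
  construction is grid- and budget-free, so the smallest honest
  configuration is used.
* Cluster detection: 15 planted cohorts at the full 20 x 20 x 10 grid with
  B = 500 and primary threshold 0.05. At the planted effect sizes
  (`a = 0.65`, `b = 0.45`, n = 33) per-replicate detection is inherently
  limited, and the suite's replicate study finds the planted cluster at a
  corrected p < 0.05 in about half the replicates, short of a strict
  majority. The ceiling is structural rather than a property of one
  threshold. The planted block is driven by a single subject-level latent
  mediator, so its voxels rise and fall together: under a lenient primary
  threshold the *same* block reaches supra-threshold extent in null
  permutation passes at roughly the voxel-level error rate, pinning the
  observed cluster's corrected p near the nominal level; under a stringent
  primary threshold the null maxima shrink but the observed block — whose
  `b`-path noncentrality is only about 2.4 at n = 33 — rarely clears the
  voxel threshold at all. Max-extent permutation inference simply cannot
  detect a single coherent moderate-effect cluster much more than half the
  time at this sample size; larger n, a stronger `b`, or multiple
  independent target regions would each lift it.
* Parameter recovery: 500 subjects streamed through full image synthesis,
  cleaning and connectivity.

# Power module conventions

`mc_power_indirect()` interprets its three coefficients as the input
correlation matrix $r_{XM}, r_{MY}, r_{XY}$ (the convention of the online
power application this analysis style uses); `input = "paths"` switches to
reading them as standardized coefficients $a, b, c'$ with the implied
correlations $r_{XY} = c' + ab$, $r_{MY} = b + ac'$. Positive definiteness
is checked and the offending triple named. Per replication the model is fit
by OLS, and the indirect-effect CI is the equal-tail interval of
$a^* b^*$ over independent normal draws at the fitted estimates and standard
errors — the Monte-Carlo-CI test, which is why no Sobel approximation
appears in the primary path.

# Known limitations

* Real-data mode consumes realigned, normalized images and motion files;
  no registration, slice timing, or segmentation is performed.
* The bootstrap p-value floor ($1/B$) makes very small thresholds
  meaningless at small budgets; the package warns rather than guessing.
* The permutation null assumes exchangeability of the covariate-adjusted
  predictor across subjects; strong heteroscedasticity across subjects
  would erode it.
* Voxel-wise `b` estimates are attenuated by mediator measurement noise;
  region-core or region-mean summaries are the right recovery readout.
* No moderated or multilevel mediation, no latent-variable models, no
  robust standard errors.
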