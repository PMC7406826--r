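#' Specify a synthetic resting-state cohort
#'
#' Defines the study conditions for the synthetic-cohort generator: cohort
#' size, acquisition geometry, the seed / target / noise regions, the planted
#' standardized path coefficients of the mediation model, and the noise and
#' head-motion parameters. Defaults mirror the acquisition of a 3T
#' resting-state protocol (200 volumes at TR = 2 s, 3 x 3 x 4.5 mm voxels) and
#' behavioural marginals typical of a trauma-exposed clinical sample.
#'
#' The planted structure: every seed-region voxel shares a subject-specific
#' latent signal band-limited to 0.01-0.08 Hz; each target-region voxel is
#' coupled to that signal with a subject-varying weight calibrated so that,
#' after the default cleaning pipeline, the Fisher-z seed connectivity at
#' target voxels satisfies `corr(X, z) = a_true` across subjects. The symptom
#' outcome is generated from the latent mediator (`b_true`), a direct path
#' (`c_prime_true`), covariate effects, and noise. Noise-region voxels carry a
#' shared rank-3 structured confound (also added at low amplitude to all brain
#' voxels) so that CompCor has a recoverable removal target.
#'
#' @param n_subjects Number of subjects (default 33).
#' @param n_volumes Volumes acquired per subject, before discarding (default 200).
#' @param tr Repetition time in seconds (default 2).
#' @param grid Length-3 integer voxel counts (default `c(20, 20, 10)`).
#' @param voxel_size Voxel edge lengths in mm (default `c(3, 3, 4.5)`).
#' @param seed_region,target_region,noise_region Integer vectors of linear
#'   voxel indices; defaults are disjoint boxes scaled to `grid`. The seed
#'   spans the anterior-posterior (y) axis so it can be partitioned into
#'   head / body / tail.
#' @param a_true,b_true,c_prime_true Planted standardized paths: X to mediator,
#'   mediator to outcome, and the direct X to outcome path.
#' @param noise_sd Standard deviation of each voxel's private noise, in signal
#'   units (the latent seed signal has unit SD).
#' @param spike_prob Per-volume probability of a head-motion spike large enough
#'   to push framewise displacement above 0.5 mm.
#' @param motion_jitter SD (mm) of the continuous translation jitter; rotation
#'   jitter is `motion_jitter / 100` radians.
#' @param high_motion_subjects Integer subject indices forced to heavy motion
#'   (spike probability 0.5), e.g. to exercise the exclusion criteria.
#' @param rng_seed Integer seed; identical specs and seeds give bit-identical
#'   cohorts.
#' @param z0 Mean planted Fisher-z connectivity at target voxels.
#' @param sigma_z SD of the planted Fisher-z values across subjects.
#' @param sigma_voxel SD of the voxel-specific jitter of the planted z field.
#' @param marginals Named list of behavioural means/SDs; see Details.
#' @return A validated object of class `cohort_spec`.
#' @details `marginals` accepts `aaq_mean`, `aaq_sd`, `caps_mean`, `caps_sd`,
#'   `bdi_mean`, `bdi_sd`, `des_mean`, `des_sd`, `age_mean`, `age_sd`,
#'   `female_p`; unspecified entries keep the defaults.
#' @examples
#' spec <- cohort_spec(n_subjects = 12, grid = c(10, 10, 5), rng_seed = 1)
#' spec
#' @export
cohort_spec <- function(n_subjects = 33, n_volumes = 200, tr = 2,
                        grid = c(20, 20, 10), voxel_size = c(3, 3, 4.5),
                        seed_region = NULL, target_region = NULL,
                        noise_region = NULL,
                        a_true = 0.65, b_true = 0.45, c_prime_true = 0.3,
                        noise_sd = 1, spike_prob = 0.02, motion_jitter = 0.02,
                        high_motion_subjects = integer(0), rng_seed = 1,
                        z0 = 0.3, sigma_z = 0.5, sigma_voxel = 0.1,
                        marginals = list()) {
  if (!is_count(n_subjects)) stopf("`n_subjects` must be a count")
  if (!is_count(n_volumes) || n_volumes <= 4) stopf("`n_volumes` must exceed 4")
  if (!is.numeric(tr) || tr <= 0) stopf("`tr` must be > 0")
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 1L)) stopf("`grid` must be 3 positive counts")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stopf("`voxel_size` must be 3 positive mm values")

  defaults <- default_regions(grid)
  seed_region   <- if (is.null(seed_region))   defaults$seed   else as.integer(seed_region)
  target_region <- if (is.null(target_region)) defaults$target else as.integer(target_region)
  noise_region  <- if (is.null(noise_region))  defaults$noise  else as.integer(noise_region)
  check_region(seed_region, grid, "seed_region")
  check_region(target_region, grid, "target_region")
  check_region(noise_region, grid, "noise_region")
  if (length(intersect(seed_region, target_region)) ||
      length(intersect(seed_region, noise_region)) ||
      length(intersect(target_region, noise_region)))
    stopf("seed_region, target_region and noise_region must be pairwise disjoint")

  # Model identifiability: four covariates (age, sex, BDI, DES) plus X, M and
  # an intercept must be estimable.
  n_covariates <- 4L
  if (n_subjects < 4L + n_covariates)
    stopf("`n_subjects` must be at least %d for a model with %d covariates (identifiability)",
          4L + n_covariates, n_covariates)
  for (p in c("a_true", "b_true", "c_prime_true"))
    if (abs(get(p)) >= 1) stopf("`%s` is a standardized path; |value| must be < 1", p)
  if (noise_sd < 0) stopf("`noise_sd` must be nonnegative")
  if (spike_prob < 0 || spike_prob > 1) stopf("`spike_prob` must be in [0, 1]")
  if (length(high_motion_subjects) &&
      (any(high_motion_subjects < 1) || any(high_motion_subjects > n_subjects)))
    stopf("`high_motion_subjects` must index subjects 1..%d", n_subjects)
  if (sigma_z <= 0 || sigma_voxel < 0) stopf("`sigma_z` must be > 0 and `sigma_voxel` >= 0")

  marg <- utils::modifyList(list(
    aaq_mean = 39.89, aaq_sd = 11.03,
    caps_mean = 25.27, caps_sd = 11.0,
    bdi_mean = 25.15, bdi_sd = 13.62,
    des_mean = 17.08, des_sd = 23.89,
    age_mean = 40.36, age_sd = 11.10,
    female_p = 0.42), marginals)

  # Residual variance of the planted z field left for the subject-level
  # mediator component must be positive once voxel jitter and finite-scan
  # measurement noise are budgeted.
  t_ret <- n_volumes - 4L
  var_meas <- 1 / max(band_bin_count(t_ret, tr, 0.01, 0.1), 8L)
  var_eta <- sigma_z^2 * (1 - a_true^2) - sigma_voxel^2 - var_meas
  if (var_eta <= 0)
    stopf("planted z variance budget is infeasible: sigma_z^2*(1-a_true^2) must exceed sigma_voxel^2 + measurement variance (%.4f)",
          sigma_voxel^2 + var_meas)

  structure(list(
    n_subjects = as.integer(n_subjects), n_volumes = as.integer(n_volumes),
    tr = as.numeric(tr), grid = grid, voxel_size = as.numeric(voxel_size),
    seed_region = seed_region, target_region = target_region,
    noise_region = noise_region,
    a_true = a_true, b_true = b_true, c_prime_true = c_prime_true,
    noise_sd = noise_sd, spike_prob = spike_prob,
    motion_jitter = motion_jitter,
    high_motion_subjects = as.integer(high_motion_subjects),
    rng_seed = as.integer(rng_seed),
    z0 = z0, sigma_z = sigma_z, sigma_voxel = sigma_voxel,
    var_eta = var_eta, var_meas = var_meas,
    # standardized covariate effects on the outcome (depression, dissociation)
    bdi_effect = 0.3, des_effect = 0.15,
    marginals = marg,
    # analysis settings the generator calibrates against (default pipeline)
    fwhm = 4, band = c(0.01, 0.1), signal_band = c(0.01, 0.08)
  ), class = "cohort_spec")
}

# Default boxes, scaled with the grid; their x ranges are disjoint by
# construction, which keeps the three regions disjoint at any grid size.
# The seed spans >= 3 slices along y (the anterior-posterior axis) so the
# thirds partition is defined.
default_regions <- function(grid) {
  span <- function(lo, hi, n) {
    a <- max(1L, round(lo * n)); b <- min(n, max(a, round(hi * n))); a:b
  }
  seed_y <- span(0.25, 0.65, grid[2])
  if (length(seed_y) < 3L) seed_y <- seq_len(min(grid[2], 3L))
  list(
    seed   = region_from_box(grid, span(0.45, 0.55, grid[1]), seed_y,
                             span(0.40, 0.60, grid[3])),
    target = region_from_box(grid, span(0.70, 0.90, grid[1]),
                             span(0.70, 0.90, grid[2]), span(0.40, 0.60, grid[3])),
    noise  = region_from_box(grid, span(0.10, 0.30, grid[1]),
                             span(0.10, 0.30, grid[2]), span(0.65, 0.90, grid[3]))
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n=%d subjects, %d volumes @ TR %gs, grid %s (voxel %s mm)\n",
    x$n_subjects, x$n_volumes, x$tr, paste(x$grid, collapse = "x"),
    paste(signif(x$voxel_size, 3), collapse = "x")))
  cat(sprintf("  regions: seed %d, target %d, noise %d voxels\n",
              length(x$seed_region), length(x$target_region), length(x$noise_region)))
  cat(sprintf("  planted paths: a=%.2f, b=%.2f, c'=%.2f; rng_seed=%d\n",
              x$a_true, x$b_true, x$c_prime_true, x$rng_seed))
  invisible(x)
}
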