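# Planted-model calibration shared by the behavioural and image generators.
#
# All planted paths are standardized: a_true is the across-subject correlation
# between the predictor and the target-voxel Fisher-z connectivity measured
# after the default cleaning pipeline; b_true and c_prime_true are the
# standardized outcome paths of the latent subject-level mediator.
latent_model <- function(spec) {
  beta <- spec$a_true * spec$sigma_z          # slope of planted z on x (std)
  var_lat <- beta^2 + spec$var_eta            # latent mediator variance (z scale)
  corr_mx <- if (var_lat > 0) beta / sqrt(var_lat) else 0
  g_b <- spec$bdi_effect; g_d <- spec$des_effect
  var_e <- 1 - (spec$b_true^2 + spec$c_prime_true^2 +
                  2 * spec$b_true * spec$c_prime_true * corr_mx) - g_b^2 - g_d^2
  if (var_e <= 0.01)
    stopf("planted outcome model leaves no residual variance (b, c', covariate effects too large)")
  list(beta = beta, sigma_lat = sqrt(var_lat), corr_mx = corr_mx, var_e = var_e,
       sigma_eta = sqrt(spec$var_eta), sigma_meas = sqrt(spec$var_meas))
}

# Fraction of spatially white noise variance surviving the default Gaussian
# smoothing at an interior voxel (product over axes of the kernel's sum of
# squares). Voxel private noise is generated inside the analysis band, so the
# temporal retention factor of the band-pass stage is 1 by construction.
noise_retention <- function(spec) {
  sig <- fwhm_to_sigma(spec$fwhm) / spec$voxel_size
  prod(vapply(sig, function(s) sum(gauss_kernel_1d(s)^2), numeric(1)))
}

#' Generate a synthetic behavioural table
#'
#' Draws per-subject scores with marginals calibrated to a trauma-exposed
#' clinical sample: acceptance (AAQ-II), symptom severity (CAPS-5, generated
#' from the planted mediation model), depression (BDI-II), dissociation
#' (DES-II), age (truncated to 18-65) and sex. Deterministic given
#' `spec$rng_seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with columns `id`, `age`, `sex` (1 = female), `aaq`, `caps`,
#'   `bdi`, `des`. The subject-level latent mediator (Fisher-z scale) is
#'   attached as attribute `"mediator_latent"`.
#' @export
gen_behavior <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("`spec` must be a cohort_spec")
  mg <- spec$marginals
  n <- spec$n_subjects
  lm_ <- latent_model(spec)
  set.seed(substream_seed(spec$rng_seed, 1L))
  age <- mg$age_mean + mg$age_sd * rnorm(n)
  while (any(bad <- age < 18 | age > 65))
    age[bad] <- mg$age_mean + mg$age_sd * rnorm(sum(bad))
  sex <- rbinom(n, 1, mg$female_p)
  aaq <- mg$aaq_mean + mg$aaq_sd * rnorm(n)
  bdi <- mg$bdi_mean + mg$bdi_sd * rnorm(n)
  des <- mg$des_mean + mg$des_sd * rnorm(n)
  x_std <- (aaq - mg$aaq_mean) / mg$aaq_sd
  set.seed(substream_seed(spec$rng_seed, 2L))
  eta <- lm_$sigma_eta * rnorm(n)
  e_y <- sqrt(lm_$var_e) * rnorm(n)
  mu <- spec$z0 + lm_$beta * x_std + eta          # latent mediator, z scale
  m_std <- (mu - spec$z0) / lm_$sigma_lat
  y_std <- spec$b_true * m_std + spec$c_prime_true * x_std +
    spec$bdi_effect * (bdi - mg$bdi_mean) / mg$bdi_sd +
    spec$des_effect * (des - mg$des_mean) / mg$des_sd + e_y
  caps <- mg$caps_mean + mg$caps_sd * y_std
  out <- tibble(id = sprintf("sub%03d", seq_len(n)), age = age, sex = sex,
                aaq = aaq, caps = caps, bdi = bdi, des = des)
  attr(out, "mediator_latent") <- mu
  out
}

#' Generate a synthetic head-motion trace
#'
#' A slow random-walk jitter on all six rigid-body parameters plus occasional
#' single-volume spikes sized to push framewise displacement above 0.5 mm.
#' Spikes alternate in sign so consecutive spiked volumes still register
#' large displacements. Deterministic given `spec$rng_seed` and the subject.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Subject number (1-based).
#' @return T x 6 matrix: translations (mm), rotations (radians).
#' @export
gen_motion <- function(spec, subject_index) {
  if (!inherits(spec, "cohort_spec")) stopf("`spec` must be a cohort_spec")
  if (!is_count(subject_index) || subject_index < 1 || subject_index > spec$n_subjects)
    stopf("`subject_index` must be in 1..%d", spec$n_subjects)
  T <- spec$n_volumes
  sp <- if (subject_index %in% spec$high_motion_subjects) 0.5 else spec$spike_prob
  set.seed(substream_seed(spec$rng_seed, 1000L + subject_index))
  steps <- cbind(matrix(rnorm(3 * (T - 1), 0, spec$motion_jitter), T - 1, 3),
                 matrix(rnorm(3 * (T - 1), 0, spec$motion_jitter / 100), T - 1, 3))
  m <- rbind(0, apply(steps, 2, cumsum))
  spikes <- which(runif(T) < sp)
  spikes <- spikes[spikes >= 2]
  if (length(spikes)) {
    axis <- sample(1:3, length(spikes), replace = TRUE)
    # large enough to push FD over 0.5 mm, small enough never to trip the
    # 1.5 mm absolute-translation criterion on top of the jitter walk
    size <- runif(length(spikes), 0.6, 1.0) * (-1)^(seq_along(spikes))
    for (k in seq_along(spikes)) m[spikes[k], axis[k]] <- m[spikes[k], axis[k]] + size[k]
  }
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Generate a complete synthetic cohort
#'
#' Builds a cohort with known planted mediation structure. At
#' `level = "latent"` only the behavioural table, the planted per-voxel
#' Fisher-z field and the masks are returned; `"zmap"` adds measurement noise
#' to give per-subject connectivity maps directly (fast path for large
#' simulation studies); `"image"` additionally synthesizes the 4D volumes and
#' motion traces, so the full preprocessing and connectivity pipeline can be
#' exercised.
#'
#' Image model per subject: every seed voxel carries a shared band-limited
#' (0.01-0.08 Hz) latent signal plus private in-band noise; target voxels
#' couple to the latent signal with weights calibrated so the post-pipeline
#' Fisher-z equals the planted field; a rank-3 structured confound loads
#' strongly on noise-region voxels and weakly on all others (the CompCor
#' target); all other voxels carry private noise only.
#'
#' @param spec A [cohort_spec()].
#' @param level `"latent"`, `"zmap"` or `"image"`.
#' @return A `cohort` list: `behavior`, `zeta` (n x V planted z field over the
#'   full grid), `z` (n x V observed maps; zmap/image levels), `volumes` and
#'   `motion` (image level), `masks` (linear indices), and `spec`.
#' @export
gen_cohort <- function(spec, level = c("zmap", "latent", "image")) {
  if (!inherits(spec, "cohort_spec")) stopf("`spec` must be a cohort_spec")
  level <- match.arg(level)
  n <- spec$n_subjects
  V <- prod(spec$grid)
  lm_ <- latent_model(spec)
  beh <- gen_behavior(spec)
  mu <- attr(beh, "mediator_latent")
  nt <- length(spec$target_region)

  # planted per-voxel z field: subject latent plus voxel-specific jitter
  set.seed(substream_seed(spec$rng_seed, 3L))
  eps_v <- matrix(rnorm(n * nt, 0, spec$sigma_voxel), n, nt)
  zeta <- matrix(0, n, V)
  zeta[, spec$target_region] <- mu + eps_v
  # seed voxels correlate with their own mean at a level set by the noise
  kappa <- noise_retention(spec)
  r_seed <- 1 / sqrt(1 + kappa * spec$noise_sd^2)
  zeta[, spec$seed_region] <- atanh(r_seed)

  masks <- list(seed = spec$seed_region, target = spec$target_region,
                noise = spec$noise_region, brain = seq_len(V))
  out <- list(behavior = beh, zeta = zeta, masks = masks, spec = spec,
              level = level)

  if (level %in% c("zmap", "image")) {
    set.seed(substream_seed(spec$rng_seed, 4L))
    out$z <- zeta + matrix(rnorm(n * V, 0, lm_$sigma_meas), n, V)
  }
  if (level == "image") {
    out$volumes <- lapply(seq_len(n), function(i) gen_subject_volume(out, i))
    out$motion <- lapply(seq_len(n), function(i) gen_motion(spec, i))
  }
  out
}

#' Synthesize one subject's 4D volume
#'
#' Builds the functional image of subject `i` from a cohort generated at any
#' level (volumes can thus be streamed one at a time for large cohorts
#' without holding the whole 4D dataset in memory).
#'
#' @param cohort Result of [gen_cohort()].
#' @param i Subject index.
#' @return A [vol4d()].
#' @export
gen_subject_volume <- function(cohort, i) {
  spec <- cohort$spec
  T <- spec$n_volumes
  V <- prod(spec$grid)
  kappa <- noise_retention(spec)
  sigma_eff <- spec$noise_sd * sqrt(kappa)
  set.seed(substream_seed(spec$rng_seed, 5000L + i))
  s <- band_noise(T, 1, spec$tr, spec$signal_band[1], spec$signal_band[2])
  g <- matrix(rnorm(T * 3), T, 3)                      # broad-band confound
  noise <- band_noise(T, V, spec$tr, spec$band[1], spec$band[2]) * spec$noise_sd
  load_brain <- matrix(rnorm(V * 3, 0, 0.3 * spec$noise_sd), V, 3)
  load_noise <- matrix(rnorm(length(spec$noise_region) * 3, 0, spec$noise_sd),
                       length(spec$noise_region), 3)
  dat <- noise + g %*% t(load_brain)
  # noise-region voxels: confound dominated, small private noise
  dat[, spec$noise_region] <- 0.3 * noise[, spec$noise_region] +
    g %*% t(load_noise)
  # seed voxels share the latent signal
  dat[, spec$seed_region] <- dat[, spec$seed_region] + as.vector(s)
  # target voxels: coupling weight chosen so the post-pipeline correlation
  # with the seed mean equals tanh(zeta)
  w <- sigma_eff * sinh(cohort$zeta[i, spec$target_region])
  dat[, spec$target_region] <- dat[, spec$target_region] + s %*% t(w)
  new_vol4d(array(t(dat), dim = c(spec$grid, T)), spec$voxel_size, spec$tr)
}

#' Interior voxels of a region
#'
#' Returns the voxels of a region whose six face neighbours all lie inside the
#' region. Spatial smoothing dilutes planted coupling at region boundaries, so
#' parameter-recovery evaluations read the planted effect at the region core.
#'
#' @param region Linear voxel indices.
#' @param grid Length-3 grid dimensions.
#' @return Linear indices of the core (possibly empty).
#' @export
region_core <- function(region, grid) {
  region <- check_region(as.integer(region), grid, "region")
  inside <- array(FALSE, grid); inside[region] <- TRUE
  co <- voxel_coords(region, grid)
  keep <- rep(TRUE, length(region))
  for (d in 1:3) for (s in c(-1L, 1L)) {
    nb <- co; nb[, d] <- nb[, d] + s
    ok <- nb[, d] >= 1L & nb[, d] <= grid[d]
    lin <- nb[, 1] + (nb[, 2] - 1L) * grid[1] + (nb[, 3] - 1L) * grid[1] * grid[2]
    valid <- ok
    valid[ok] <- inside[lin[ok]]
    keep <- keep & valid
  }
  region[keep]
}

#' Write a label mask volume for a cohort
#'
#' Integer labels: 1/2/3 = seed head/body/tail (thirds along the
#' anterior-posterior axis), 10 = noise mask, 20 = remaining brain voxels.
#'
#' @param cohort Result of [gen_cohort()].
#' @return 3D integer array.
#' @export
cohort_label_mask <- function(cohort) {
  spec <- cohort$spec
  lab <- array(20L, spec$grid)
  parts <- partition_seed(spec$seed_region, spec$grid)
  lab[parts$head] <- 1L; lab[parts$body] <- 2L; lab[parts$tail] <- 3L
  lab[spec$noise_region] <- 10L
  lab
}
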