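#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end analysis with the study
#' defaults; the configuration round-trips losslessly through YAML.
#'
#' @param mode `"synthetic"` (inputs generated from `spec`) or `"real"`
#'   (inputs read from `paths`).
#' @param spec A [cohort_spec()] (synthetic mode).
#' @param paths Named list for real mode: `behavior` (TSV), `volumes` (named
#'   character vector of NIfTI paths keyed by subject id), `motion` (named
#'   vector of motion files), `label_mask` (NIfTI integer labels: 1/2/3 seed
#'   head/body/tail, 10 noise, 20 brain).
#' @param seed_label Which subregion seed drives the mediation (`"head"`,
#'   `"body"` or `"tail"`; default `"body"`).
#' @param discard_k,compcor_k,fwhm,band,fd_thr Preprocessing settings.
#' @param B,n_perm,alpha_primary,connectivity,flavor Inference settings.
#' @param rng_seed Seed for all stochastic stages.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "real"), spec = cohort_spec(),
                       paths = list(), seed_label = "body",
                       discard_k = 4, compcor_k = 5, fwhm = 4,
                       band = c(0.01, 0.1), fd_thr = 0.5,
                       B = 10000, n_perm = 1000, alpha_primary = 0.001,
                       connectivity = 18, flavor = "bc", rng_seed = 1,
                       out_dir = tempfile("rsfcmed_run_")) {
  mode <- match.arg(mode)
  if (!seed_label %in% c("head", "body", "tail"))
    stopf("`seed_label` must be head, body or tail")
  structure(list(mode = mode, spec = spec, paths = paths,
                 seed_label = seed_label, discard_k = discard_k,
                 compcor_k = compcor_k, fwhm = fwhm, band = band,
                 fd_thr = fd_thr, B = B, n_perm = n_perm,
                 alpha_primary = alpha_primary, connectivity = connectivity,
                 flavor = flavor, rng_seed = rng_seed, out_dir = out_dir),
            class = "run_config")
}

config_to_yaml <- function(config, path) {
  x <- unclass(config)
  x$spec <- if (!is.null(x$spec)) unclass(x$spec) else NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  spec <- if (!is.null(x$spec))
    do.call(cohort_spec, x$spec[c("n_subjects", "n_volumes", "tr", "grid",
                                  "voxel_size", "seed_region", "target_region",
                                  "noise_region", "a_true", "b_true",
                                  "c_prime_true", "noise_sd", "spike_prob",
                                  "motion_jitter", "high_motion_subjects",
                                  "rng_seed", "z0", "sigma_z", "sigma_voxel")])
  args <- x[setdiff(names(x), "spec")]
  args$spec <- spec
  do.call(run_config, args)
}

#' Preprocess one subject
#'
#' The post-realignment cleaning chain in study order: discard initial
#' volumes, motion QC, nuisance regression (Friston-24, scrubbing spikes,
#' CompCor, linear trend, intercept), Gaussian smoothing, band-pass.
#'
#' @param v A [vol4d()] volume.
#' @param motion T x 6 motion matrix aligned with `v`.
#' @param noise_mask Linear indices (or logical array) of the noise tissue.
#' @param subject_id Id copied into the QC row.
#' @param discard_k,compcor_k,fwhm,band,fd_thr Stage settings.
#' @return List: `volume` (cleaned; NULL if excluded), `qc` (one-row tibble),
#'   `fd`, `nuisance`.
#' @export
preprocess_subject <- function(v, motion, noise_mask, subject_id = NA_character_,
                               discard_k = 4, compcor_k = 5, fwhm = 4,
                               band = c(0.01, 0.1), fd_thr = 0.5) {
  d <- discard_initial(v, motion, k = discard_k)
  fd <- compute_fd(d$motion)
  qc <- motion_qc(d$motion, fd, fd_thr = fd_thr, subject_id = subject_id)
  if (qc$excluded) return(list(volume = NULL, qc = qc, fd = fd, nuisance = NULL))
  cc <- compcor(d$volume, noise_mask, k = compcor_k)
  design <- build_nuisance(d$motion, fd, cc, fd_thr = fd_thr)
  out <- regress_out(d$volume, design)
  out <- smooth_gaussian(out, fwhm = fwhm)
  out <- bandpass_filter(out, lo = band[1], hi = band[2])
  list(volume = out, qc = qc, fd = fd, nuisance = design)
}

#' Run the full analysis pipeline
#'
#' Synthetic mode: generates the cohort, preprocesses every subject, drops
#' excluded subjects, computes the chosen subregion's Fisher-z connectivity
#' maps, runs voxel-wise bootstrap mediation with cluster-extent permutation
#' correction, and writes all artifacts (behavioural TSV, QC TSV, z-maps,
#' mediation maps, cluster table, label map, provenance JSON, config YAML)
#' into `config$out_dir`. Real mode reads the same inputs from files, joining
#' image and behavioural data by subject id.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `qc`, `clusters` (tibble), `fwe`, `maps`,
#'   `included` ids and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stopf("`config` must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$mode == "synthetic") {
    spec <- config$spec
    cohort <- gen_cohort(spec, level = "latent")
    behavior <- cohort$behavior
    grid <- spec$grid
    voxel_size <- spec$voxel_size
    label_mask <- cohort_label_mask(cohort)
    get_subject <- function(i) list(volume = gen_subject_volume(cohort, i),
                                    motion = gen_motion(spec, i))
    ids <- behavior$id
    write_volume(label_mask, file.path(config$out_dir, "label_mask.nii.gz"))
  } else {
    p <- config$paths
    for (f in c("behavior", "label_mask"))
      if (is.null(p[[f]]) || !file.exists(p[[f]])) stopf("real mode input missing: %s", f)
    behavior <- read_behavior(p$behavior)
    ids <- as.character(behavior$id)
    missing_ids <- setdiff(ids, intersect(names(p$volumes), names(p$motion)))
    if (length(missing_ids))
      stopf("no imaging input for subject id(s): %s", paste(missing_ids, collapse = ", "))
    lab_arr <- read_volume(p$label_mask)
    if (inherits(lab_arr, "vol4d")) stopf("label mask must be a 3D image")
    label_mask <- array(as.integer(round(lab_arr)), dim = dim(lab_arr))
    grid <- dim(label_mask)
    voxel_size <- config$spec$voxel_size
    get_subject <- function(i) {
      v <- read_volume(p$volumes[[ids[i]]])
      list(volume = v, motion = read_motion(p$motion[[ids[i]]]))
    }
  }
  seed_all <- which(label_mask %in% 1:3)
  noise_mask <- which(label_mask == 10L)
  brain_mask <- which(label_mask != 10L & label_mask != 0L)
  parts <- partition_seed(seed_all, grid)
  seed_voxels <- parts[[config$seed_label]]

  qc_rows <- list(); zmaps <- list()
  for (i in seq_along(ids)) {
    subj <- get_subject(i)
    pre <- preprocess_subject(subj$volume, subj$motion, noise_mask,
                              subject_id = ids[i], discard_k = config$discard_k,
                              compcor_k = config$compcor_k, fwhm = config$fwhm,
                              band = config$band, fd_thr = config$fd_thr)
    qc_rows[[i]] <- pre$qc
    if (!pre$qc$excluded) {
      z <- seed_connectivity(pre$volume, seed_voxels, brain_mask,
                             subject_id = ids[i], seed_label = config$seed_label)
      zmaps[[ids[i]]] <- z
      write_volume(unclass(z), file.path(config$out_dir,
                                         sprintf("%s_%s_z.nii.gz", ids[i], config$seed_label)))
    }
  }
  qc <- dplyr::bind_rows(qc_rows)
  qc_out <- dplyr::mutate(qc, reasons = vapply(.data$reasons, paste,
                                               character(1), collapse = ";"))
  readr::write_tsv(qc_out, file.path(config$out_dir, "qc_report.tsv"))
  write_behavior(behavior, file.path(config$out_dir, "behavior.tsv"))

  included <- names(zmaps)
  if (length(included) <= 7L)
    stopf("only %d subject(s) survive motion QC; too few for the mediation model",
          length(included))
  beh_in <- behavior[match(included, behavior$id), ]
  Mmat <- do.call(rbind, lapply(zmaps, function(z) as.numeric(z)[brain_mask]))
  input <- mediation_input(beh_in, Mmat, grid = grid, mask = brain_mask)
  fwe <- cluster_fwe(input, B = config$B, n_perm = config$n_perm,
                     alpha_primary = config$alpha_primary,
                     connectivity = config$connectivity,
                     rng_seed = config$rng_seed, flavor = config$flavor,
                     voxel_size = voxel_size)
  maps <- fwe$maps
  for (nm in c("a", "b", "ab", "c_prime", "p_a", "p_b", "p_ab", "p_c_prime"))
    write_volume(map_array(maps, nm),
                 file.path(config$out_dir, sprintf("mediation_%s.nii.gz", nm)))
  write_volume(fwe$label_map, file.path(config$out_dir, "cluster_labels.nii.gz"))
  readr::write_tsv(fwe$clusters, file.path(config$out_dir, "cluster_table.tsv"))
  config_to_yaml(config, file.path(config$out_dir, "config.yaml"))

  provenance <- list(
    config_hash = rlang::hash(unclass(config)[setdiff(names(unclass(config)), "out_dir")]),
    rng_seed = config$rng_seed, B = config$B, n_perm = config$n_perm,
    flavor = config$flavor, n_included = length(included),
    excluded = qc$subject_id[qc$excluded],
    package_version = as.character(utils::packageVersion("rsfcmed")),
    r_version = R.version.string)
  jsonlite::write_json(provenance, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(qc = qc, clusters = fwe$clusters, fwe = fwe, maps = maps,
                 included = included, out_dir = config$out_dir))
}
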