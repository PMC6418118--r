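# Config-driven pipeline stages. A pipeline config is a validated named
# list, round-trippable through YAML or JSON, from which every stage derives
# its sub-seeds; each run writes its artifacts plus a manifest JSON
# recording the config and seeds for provenance.

PIPELINE_SCHEMA_VERSION <- 1L

#' Build a pipeline configuration
#'
#' @param seed Global integer seed; every stochastic stage derives its own
#'   stream from it.
#' @param session Named list of [session_config()] overrides (e.g. `n_main`,
#'   `n_training`, `start_delta`).
#' @param observer Named list of [observer_spec()] fields for simulated
#'   sessions (default a moderate pure observer).
#' @param recovery Named list: `n_observers`.
#' @param cohort Named list of [cohort_spec()] overrides.
#' @param inference Named list: `n_perm`, `alpha`, `min_extent`,
#'   `var_smooth_sigma`, and TFCE fields `E`, `H`, `n_steps`, `connectivity`.
#' @return A validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, session = list(), observer = list(),
                            recovery = list(), cohort = list(),
                            inference = list()) {
  cfg <- list(schema_version = PIPELINE_SCHEMA_VERSION, seed = as.integer(seed),
              session = session, observer = observer, recovery = recovery,
              cohort = cohort, inference = inference)
  validate_pipeline_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks field names and printed-range constraints (e.g. lapse within
#' `[0, 0.1]`, thresholds within `[0, 300]` ms), raising an error naming the
#' offending field.
#'
#' @param cfg A named list as produced by [pipeline_config()] or read from
#'   file.
#' @return The config, classed `pipeline_config`, invisibly usable onward.
#' @export
validate_pipeline_config <- function(cfg) {
  need <- c("schema_version", "seed")
  for (f in need) {
    if (is.null(cfg[[f]])) {
      abort(sprintf("Config field `%s` is missing.", f),
            class = "psivox_config_error")
    }
  }
  check_range <- function(value, field, lo, hi) {
    if (!is.null(value) && (value < lo || value > hi)) {
      abort(sprintf("Config field `%s` = %g outside [%g, %g].",
                    field, value, lo, hi),
            class = "psivox_config_error")
    }
  }
  check_range(cfg$observer$lam, "observer.lam", 0, 0.1)
  check_range(cfg$observer$alpha, "observer.alpha", 0, 300)
  check_range(cfg$observer$beta, "observer.beta", -2, 2)
  check_range(cfg$observer$pi_vol, "observer.pi_vol", 0, 1)
  check_range(cfg$session$p_single, "session.p_single", 0, 1)
  check_range(cfg$inference$alpha, "inference.alpha", 0, 1)
  check_range(cfg$cohort$mask_fraction, "cohort.mask_fraction", 0.01, 0.05)
  # stage constructors re-validate everything else
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read or write a pipeline config (YAML or JSON, by extension)
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @param cfg A `pipeline_config` (for writing).
#' @return `read_pipeline_config()` returns the validated config;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  bare <- unclass(cfg)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(bare, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(bare, path)
  }
  invisible(path)
}

cfg_session <- function(cfg) {
  do.call(session_config, cfg$session %||% list())
}

cfg_observer <- function(cfg) {
  fields <- cfg$observer %||% list()
  if (is.null(fields$alpha)) fields$alpha <- 150
  if (is.null(fields$beta)) fields$beta <- -1
  do.call(observer_spec, fields)
}

write_manifest <- function(out_dir, stage, cfg, extra = list()) {
  manifest <- c(list(stage = stage, schema_version = cfg$schema_version,
                     seed = cfg$seed,
                     package_version = as.character(utils::packageVersion("psivox")),
                     config = unclass(cfg)),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate one adaptive session and write its artifacts
#'
#' Writes `trials.csv` (the trial log), `posterior.json`, `estimates.json`,
#' `function_curve.csv` (plot-ready fitted function), the
#' (threshold x slope) marginal raster `posterior_alpha_beta.csv`, and
#' `manifest.json` into `out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress the log line.
#' @return The `psy_session`, invisibly.
#' @export
run_simulate_session <- function(cfg, out_dir, quiet = FALSE) {
  cfg <- validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- cfg_session(cfg)
  ses <- run_session(make_observer(cfg_observer(cfg)), scfg,
                     seed = derive_seed(cfg$seed, "simulate-session"))
  write_trials(ses, file.path(out_dir, "trials.csv"))
  psy_to_json(ses$posterior, file.path(out_dir, "posterior.json"))
  psy_to_json(ses$estimate, file.path(out_dir, "estimates.json"))
  curve <- tibble(delta_ms = seq(0, max(scfg$candidates), by = 1))
  curve$p_first <- psy_prob(curve$delta_ms, params = ses$estimate)
  readr::write_csv(curve, file.path(out_dir, "function_curve.csv"))
  readr::write_csv(marginal_alpha_beta(ses$posterior),
                   file.path(out_dir, "posterior_alpha_beta.csv"))
  write_manifest(out_dir, "simulate-session", cfg,
                 list(n_trials = nrow(ses$trials),
                      n_estimation_trials = ses$n_estimation_trials,
                      estimates = list(alpha = ses$estimate$alpha,
                                       beta = ses$estimate$beta,
                                       lam = ses$estimate$lam)))
  if (!quiet) {
    message(sprintf("simulate-session: seed %d, %d trials (%d estimation), beta %.3f",
                    cfg$seed, nrow(ses$trials), ses$n_estimation_trials,
                    ses$estimate$beta))
  }
  invisible(ses)
}

#' Run a parameter-recovery study and write its report
#'
#' Writes `recovery.csv` (one row per observer, true vs estimated) and
#' `recovery_summary.csv` (correlations, RMSEs, coverage) plus a manifest.
#'
#' @inheritParams run_simulate_session
#' @return The `psy_recovery` tibble, invisibly.
#' @export
run_recovery_study <- function(cfg, out_dir, quiet = FALSE) {
  cfg <- validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_obs <- cfg$recovery$n_observers %||% 200L
  rec <- recovery_study(n_obs, cfg_session(cfg),
                        seed = derive_seed(cfg$seed, "recovery"))
  readr::write_csv(rec, file.path(out_dir, "recovery.csv"))
  readr::write_csv(glance(rec), file.path(out_dir, "recovery_summary.csv"))
  write_manifest(out_dir, "recovery-study", cfg,
                 list(n_observers = n_obs))
  if (!quiet) {
    message(sprintf("recovery-study: %d observers, slope r = %.3f",
                    n_obs, glance(rec)$r_beta))
  }
  invisible(rec)
}

#' Generate a synthetic cohort and write it to disk
#'
#' @inheritParams run_simulate_session
#' @return The `skeleton_cohort`, invisibly.
#' @export
run_make_cohort <- function(cfg, out_dir, quiet = FALSE) {
  cfg <- validate_pipeline_config(cfg)
  spec <- do.call(cohort_spec, cfg$cohort %||% list())
  cohort <- make_cohort(spec, seed = derive_seed(cfg$seed, "cohort"))
  write_cohort(cohort, out_dir)
  write_manifest(out_dir, "make-cohort", cfg,
                 list(n_subjects = spec$n_subjects,
                      n_mask_voxels = ncol(cohort$data)))
  if (!quiet) {
    message(sprintf("make-cohort: %d subjects, %d mask voxels",
                    spec$n_subjects, ncol(cohort$data)))
  }
  invisible(cohort)
}

#' Run the voxelwise analysis end-to-end and write its artifacts
#'
#' Reads a cohort from `cohort_dir` (or generates one from the config when
#' `cohort_dir` is `NULL`), runs both correlation directions, and writes
#' `tstat_<dir>.nii`, `tfce_<dir>.nii`, `pcorr_<dir>.nii`, `clusters.csv`
#' (header `cluster_id,n_voxels,peak_i,peak_j,peak_k,peak_p_corr,direction`),
#' a human-readable `report.txt`, and `manifest.json`.
#'
#' @inheritParams run_simulate_session
#' @param cohort_dir Optional directory from [write_cohort()].
#' @return The `voxel_ptest_pair`, invisibly.
#' @export
run_voxelwise <- function(cfg, out_dir, cohort_dir = NULL, quiet = FALSE) {
  cfg <- validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (is.null(cohort_dir)) {
    make_cohort(do.call(cohort_spec, cfg$cohort %||% list()),
                seed = derive_seed(cfg$seed, "cohort"))
  } else {
    read_cohort(cohort_dir)
  }
  inf <- cfg$inference %||% list()
  tcfg <- tfce_config(E = inf$E %||% 0.5, H = inf$H %||% 2,
                      n_steps = inf$n_steps %||% 100L,
                      connectivity = inf$connectivity %||% 26L)
  pair <- run_both_directions(cohort, design_matrix(cohort$covariates),
                              n_perm = inf$n_perm %||% 5000L, tfce = tcfg,
                              var_smooth_sigma = inf$var_smooth_sigma %||% 5,
                              seed = derive_seed(cfg$seed, "voxelwise"))
  alpha <- inf$alpha %||% 0.05
  min_extent <- inf$min_extent %||% 100L
  shape <- dim(cohort$mask)
  idx <- which(cohort$mask)
  to_vol <- function(v) { a <- array(0, shape); a[idx] <- v; a }
  for (d in c("negative", "positive")) {
    res <- pair[[d]]
    for (nm in c("t", "tfce", "p_corr")) {
      fn <- c(t = "tstat", tfce = "tfce", p_corr = "pcorr")[[nm]]
      RNifti::writeNifti(RNifti::asNifti(to_vol(res[[nm]]),
                                         pixdim = cohort$voxel_size),
                         file.path(out_dir, sprintf("%s_%s.nii", fn, d)))
    }
  }
  clusters <- tidy(pair, alpha = alpha, min_extent = min_extent,
                   connectivity = tcfg$connectivity)
  readr::write_csv(clusters[, c("cluster_id", "n_voxels", "peak_i", "peak_j",
                                "peak_k", "peak_p_corr", "direction")],
                   file.path(out_dir, "clusters.csv"))
  report <- c(
    sprintf("Voxelwise slope-diffusivity analysis (%d subjects, %d mask voxels)",
            nrow(cohort$data), ncol(cohort$data)),
    sprintf("Permutations: %d; alpha = %g; extent > %d voxels; TFCE E=%g H=%g",
            pair$negative$n_perm, alpha, min_extent, tcfg$E, tcfg$H),
    "",
    vapply(c("negative", "positive"), function(d) {
      k <- sum(clusters$direction == d)
      if (k == 0) sprintf("%s direction: no significant clusters", d)
      else sprintf("%s direction: %d cluster(s), largest %d voxels (peak p = %.4g)",
                   d, k, max(clusters$n_voxels[clusters$direction == d]),
                   min(clusters$peak_p_corr[clusters$direction == d]))
    }, character(1)))
  writeLines(report, file.path(out_dir, "report.txt"))
  write_manifest(out_dir, "voxelwise", cfg,
                 list(n_clusters_negative = sum(clusters$direction == "negative"),
                      n_clusters_positive = sum(clusters$direction == "positive")))
  if (!quiet) message(paste(report, collapse = "\n"))
  invisible(pair)
}
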