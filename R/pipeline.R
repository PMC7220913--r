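# End-to-end orchestration: train (time 1) -> internal retest validation
# (time 2, time 3) -> external validation, with a reproducibility manifest.

#' Run configuration with study defaults
#'
#' All stage parameters with their published defaults: discard 7 initial
#' volumes; FD scrub threshold 0.5 mm; minimum retention 0.80; mean-FD limit
#' 0.15 mm; motion limits 2 mm / 2 degrees; Gf outlier cutoff 2 SD; WM
#' probability threshold 0.90; group coverage 0.80; subcortical removal
#' threshold 0.25; band 0.01-0.10 Hz; K = 128 nodes; edge-selection p 0.01;
#' 20-fold CV repeated 50 times; 5000 permutations. Synthetic-world
#' parameters come from [synthetic_spec()].
#'
#' @param ... Overrides for any default (unknown names are an error).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    n_discard = 7, fd_threshold = 0.5, min_retention = 0.80,
    max_mean_fd = 0.15, max_translation_mm = 2, max_rotation_deg = 2,
    outlier_k_sd = 2, wm_threshold = 0.90, coverage = 0.80,
    subcortical_threshold = 0.25, low_hz = 0.01, high_hz = 0.10,
    n_nodes = 128, p_threshold = 0.01, k_folds = 20, kfold_repeats = 50,
    n_permutations = 5000, alpha_motion = 0.05, variant = "glm",
    # synthetic world
    n_participants = 326, n_pos_edges = 20, n_neg_edges = 20,
    effect_r = 0.4, gf_mean = 65, gf_sd = 7,
    reliability_time2 = 0.7, reliability_time3 = 0.6,
    external_scale = 15, external_offset = 100, external_noise_sd = 0.5,
    n_external = 53, fd_spike_rate = 0.02,
    seed = 1L,
    run_kfold = TRUE, run_permutation = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config parameter(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with config overrides.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::fromJSON(path))
}

#' Synthetic-world spec from a run configuration
#' @param cfg A [run_config()].
#' @return A [synthetic_spec()].
#' @export
config_spec <- function(cfg) {
  synthetic_spec(
    n_participants = cfg$n_participants, n_nodes = cfg$n_nodes,
    n_pos_edges = cfg$n_pos_edges, n_neg_edges = cfg$n_neg_edges,
    effect_r = cfg$effect_r, gf_mean = cfg$gf_mean, gf_sd = cfg$gf_sd,
    retest_reliability = cfg$reliability_time2,
    external_scale = cfg$external_scale,
    external_offset = cfg$external_offset,
    external_noise_sd = cfg$external_noise_sd,
    n_external = cfg$n_external, fd_spike_rate = cfg$fd_spike_rate,
    seed = cfg$seed
  )
}

write_manifest <- function(cfg, out_dir, extra = list()) {
  manifest <- c(list(
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("wmcpm")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  ), extra)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
}

predictions_df <- function(cohort, result, session) {
  data.frame(id = cohort$participants$id, session = session,
             observed = result$observed, predicted = result$predicted,
             stringsAsFactors = FALSE)
}

#' Run the internal-validation pipeline on a synthetic cohort
#'
#' Generates the time-1 cohort plus time-2 and time-3 retest sessions with
#' decreasing edge reliability, runs LOOCV (with optional repeated k-fold CV
#' and a permutation test) on time 1, applies each fold's model to the
#' held-out participant's time-2 and time-3 edges, extracts consensus
#' features, and writes predictions (CSV), masks (JSON) and a summary plus a
#' provenance manifest to `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a result bundle: per-session `prediction_result`s,
#'   consensus mask, k-fold summary, permutation result, and the summary
#'   list.
#' @export
run_internal <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  gen <- generate_cohort(config_spec(config))
  cohort1 <- gen$cohort
  cohort2 <- generate_retest(cohort1, gen$truth, config$reliability_time2,
                             seed = config$seed + 1L, session = "time2")
  cohort3 <- generate_retest(cohort1, gen$truth, config$reliability_time3,
                             seed = config$seed + 2L, session = "time3")
  res1 <- cpm_loocv(cohort1, config$p_threshold, config$variant,
                    config$alpha_motion)
  res2 <- cpm_loocv(cohort1, config$p_threshold, config$variant,
                    config$alpha_motion, test_edges = cohort2$edges)
  res3 <- cpm_loocv(cohort1, config$p_threshold, config$variant,
                    config$alpha_motion, test_edges = cohort3$edges)
  consensus <- suppressWarnings(consensus_features(res1$fold_masks))
  kfold <- if (isTRUE(config$run_kfold)) {
    cpm_kfold(cohort1, config$k_folds, config$kfold_repeats,
              seed = config$seed + 3L, p_threshold = config$p_threshold,
              variant = config$variant, alpha_motion = config$alpha_motion)
  }
  perm <- if (isTRUE(config$run_permutation)) {
    permutation_test(cohort1, B = config$n_permutations,
                     seed = config$seed + 4L,
                     p_threshold = config$p_threshold,
                     variant = config$variant,
                     alpha_motion = config$alpha_motion)
  }
  summary <- list(
    n = nrow(cohort1$participants),
    r_time1 = res1$r_pred_obs, p_time1 = res1$p_parametric,
    r_time2 = res2$r_pred_obs, p_time2 = res2$p_parametric,
    r_time3 = res3$r_pred_obs, p_time3 = res3$p_parametric,
    n_consensus_pos = length(consensus$positive_edges),
    n_consensus_neg = length(consensus$negative_edges),
    kfold_mean_r = if (!is.null(kfold)) kfold$mean_r,
    kfold_sd_r = if (!is.null(kfold)) kfold$sd_r,
    p_permutation = if (!is.null(perm)) perm$p_permutation,
    seed = config$seed
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rbind(predictions_df(cohort1, res1, "time1"),
                           predictions_df(cohort1, res2, "time2"),
                           predictions_df(cohort1, res3, "time3")),
                     file.path(out_dir, "predictions_internal.csv"),
                     row.names = FALSE)
    write_feature_mask(consensus, file.path(out_dir, "consensus_mask.json"))
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               file.path(out_dir, "summary_internal.json"))
    write_manifest(config, out_dir, list(stage = "internal"))
  }
  invisible(list(cohorts = list(time1 = cohort1, time2 = cohort2,
                                time3 = cohort3),
                 truth = gen$truth,
                 results = list(time1 = res1, time2 = res2, time3 = res3),
                 consensus = consensus, kfold = kfold, permutation = perm,
                 summary = summary))
}

#' Run the external-validation pipeline
#'
#' Defines consensus features by LOOCV on the training cohort, fits a single
#' model on the full training cohort at those features, and applies it to a
#' newly generated external cohort whose score is an affine re-scaling of the
#' latent trait. Evaluation is parametric only (non-overlapping samples).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @param internal Optionally, a [run_internal()] bundle to reuse (avoids
#'   re-running the training LOOCV).
#' @return Invisibly, a bundle: the external `prediction_result`, model,
#'   consensus mask and summary. An empty consensus is an error.
#' @export
run_external <- function(config = run_config(), out_dir = NULL,
                         internal = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(internal)) {
    cfg_no_extras <- config
    cfg_no_extras$run_kfold <- FALSE
    cfg_no_extras$run_permutation <- FALSE
    internal <- run_internal(cfg_no_extras, out_dir = NULL)
  }
  consensus <- internal$consensus
  if (!length(consensus$positive_edges) && !length(consensus$negative_edges)) {
    stop("empty consensus feature set: external validation cannot proceed",
         call. = FALSE)
  }
  model <- fit_consensus_model(internal$cohorts$time1, consensus,
                               config$variant)
  external <- generate_external(config_spec(config), internal$truth,
                                seed = config$seed + 10L)
  res <- apply_cpm(model, external)
  summary <- list(n_external = nrow(external$participants),
                  r_external = res$r_pred_obs,
                  p_external = res$p_parametric,
                  n_consensus_pos = length(consensus$positive_edges),
                  n_consensus_neg = length(consensus$negative_edges),
                  seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(predictions_df(external, res, "external"),
                     file.path(out_dir, "predictions_external.csv"),
                     row.names = FALSE)
    write_feature_mask(consensus, file.path(out_dir, "consensus_mask.json"))
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "summary_external.json"))
    write_manifest(config, out_dir, list(stage = "external"))
  }
  invisible(list(result = res, model = model, consensus = consensus,
                 external = external, summary = summary))
}
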