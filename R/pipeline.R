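# Reproducible end-to-end pipeline: simulate -> calibrate -> qc -> moisture
# -> preprocess -> model, with every stage's inputs/outputs persisted as CSV
# and a manifest recording stage order, seed, and file checksums.

#' Build a pipeline configuration
#'
#' @param seed master seed, shared with the generator.
#' @param generator a [generator_config()]; defaults to
#'   `generator_config(seed = seed)`.
#' @param detection_ratio detection-inclusion cut-off.
#' @param improvement_threshold exposure-time stopping threshold (%).
#' @param exposure_times_s timed-analysis intervals (s).
#' @param n_rep repeat exposures for the repeatability stage.
#' @param calibration_n pairs per element for the calibration stage.
#' @param calibration_noise_cv instrument noise in the calibration pairs.
#' @param zero_threshold zero-fraction filter threshold.
#' @param r_threshold correlation filter threshold.
#' @param alpha moisture-test significance level.
#' @param train_fraction stratified-split training fraction.
#' @param k_folds CV folds for forest tuning.
#' @param mtry_grid,ntree_grid forest tuning grids.
#' @param nmds_k NMDS dimensionality.
#' @param stages stages to run, a subset of
#'   `c("simulate","calibrate","qc","moisture","preprocess","model")`
#'   (prerequisites of a requested stage are run implicitly).
#' @return object of class `sep_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            generator = NULL,
                            detection_ratio = 1 / 3,
                            improvement_threshold = 33,
                            exposure_times_s = c(15, 30, 45, 60, 75, 90),
                            n_rep = 5L,
                            calibration_n = 6L,
                            calibration_noise_cv = 0.05,
                            zero_threshold = 0.8,
                            r_threshold = 0.8,
                            alpha = 0.05,
                            train_fraction = 0.8,
                            k_folds = 5L,
                            mtry_grid = c(1, 3, 5, 7),
                            ntree_grid = c(100, 300, 600),
                            nmds_k = 2L,
                            stages = c("simulate", "calibrate", "qc",
                                       "moisture", "preprocess", "model")) {
  if (is.null(generator)) generator <- generator_config(seed = seed)
  known <- c("simulate", "calibrate", "qc", "moisture", "preprocess", "model")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stopifnot(detection_ratio > 0, improvement_threshold > 0,
            zero_threshold > 0, zero_threshold <= 1,
            r_threshold > 0, r_threshold <= 1,
            alpha > 0, alpha < 1,
            train_fraction > 0, train_fraction <= 1)
  cfg <- list(seed = as.integer(seed), generator = generator,
              detection_ratio = detection_ratio,
              improvement_threshold = improvement_threshold,
              exposure_times_s = exposure_times_s, n_rep = n_rep,
              calibration_n = calibration_n,
              calibration_noise_cv = calibration_noise_cv,
              zero_threshold = zero_threshold, r_threshold = r_threshold,
              alpha = alpha, train_fraction = train_fraction,
              k_folds = k_folds, mtry_grid = mtry_grid,
              ntree_grid = ntree_grid, nmds_k = nmds_k,
              stages = intersect(known, stages))
  class(cfg) <- "sep_pipeline_config"
  cfg
}

.write_stage_csv <- function(obj, out_dir, name) {
  path <- file.path(out_dir, name)
  write.csv(as.data.frame(obj), path, row.names = FALSE, na = "NA")
  path
}

#' Run the pipeline
#'
#' Executes the configured stages in order and writes each stage's outputs
#' to `out_dir`, plus `manifest.json` (stage order, seed, per-file MD5
#' checksums) and the resolved configuration (`config.yaml`). Identical
#' configuration and seed reproduce bit-identical data files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "sep_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- config$generator
  stages <- config$stages
  # implicit prerequisites: everything up to the last requested data stage
  order_all <- c("simulate", "calibrate", "qc", "moisture", "preprocess",
                 "model")
  need <- order_all[seq_len(max(match(stages, order_all)))]
  need <- union(setdiff(need, "moisture"),
                intersect(stages, "moisture"))
  need <- order_all[order_all %in% need]
  files <- character(0)
  res <- list()

  # --- simulate ---------------------------------------------------------
  profile_raw <- generate_profile_table(gen, apply_bias = TRUE)
  pairs <- lapply(setNames(gen$element_roster, gen$element_roster),
                  function(el) {
    if (is.na(gen$bias_slope[[el]])) return(NULL)
    generate_paired_calibration_set(gen, el, n = config$calibration_n,
                                    noise_cv = config$calibration_noise_cv)
  })
  repeats <- generate_repeat_exposures(gen, n_rep = config$n_rep)
  exposure <- generate_exposure_series(gen, config$exposure_times_s)
  res$profile_raw <- profile_raw
  if ("simulate" %in% need) {
    files <- c(files, .write_stage_csv(profile_raw, out_dir,
                                       "profile_raw.csv"))
    files <- c(files, .write_stage_csv(repeats, out_dir,
                                       "repeat_exposures.csv"))
    files <- c(files, .write_stage_csv(exposure, out_dir,
                                       "exposure_series.csv"))
  }

  # --- calibrate --------------------------------------------------------
  profile <- profile_raw
  if ("calibrate" %in% need) {
    factors <- fit_correction_factors(pairs)
    profile <- suppressWarnings(apply_correction(profile_raw, factors))
    res$factors <- factors
    res$profile <- profile
    files <- c(files, .write_stage_csv(factors, out_dir, "factors.csv"))
    files <- c(files, .write_stage_csv(profile, out_dir,
                                       "profile_corrected.csv"))
  }

  # --- qc ---------------------------------------------------------------
  roster <- profile_elements(profile)
  if ("qc" %in% need) {
    det <- detection_filter(profile, ratio = config$detection_ratio)
    roster <- det$roster
    exp_rep <- exposure_time_report(exposure, config$improvement_threshold)
    repsum <- repeatability_summary(repeats)
    res$detection <- det
    res$exposure_time <- exp_rep
    res$repeatability <- repsum
    files <- c(files, .write_stage_csv(det$summary, out_dir,
                                       "detection_summary.csv"))
    files <- c(files, .write_stage_csv(exp_rep, out_dir,
                                       "exposure_time.csv"))
    files <- c(files, .write_stage_csv(repsum, out_dir,
                                       "repeatability.csv"))
  }

  # --- moisture ---------------------------------------------------------
  if ("moisture" %in% need) {
    moist_pairs <- generate_paired_treatment_table(gen)
    moist <- moisture_comparison_table(moist_pairs, alpha = config$alpha)
    res$moisture <- moist
    files <- c(files, .write_stage_csv(moist_pairs, out_dir,
                                       "moisture_pairs.csv"))
    files <- c(files, .write_stage_csv(moist, out_dir, "moisture_tests.csv"))
  }

  # --- preprocess -------------------------------------------------------
  if ("preprocess" %in% need) {
    keep <- intersect(profile_elements(profile), roster)
    prof_roster <- .drop_elements(profile,
                                  setdiff(profile_elements(profile), keep))
    prep <- preprocess_profile(prof_roster,
                               zero_threshold = config$zero_threshold,
                               r_threshold = config$r_threshold)
    res$preprocessed <- prep
    files <- c(files, .write_stage_csv(prep$table, out_dir,
                                       "profile_preprocessed.csv"))
    files <- c(files, .write_stage_csv(prep$report$scaling_params, out_dir,
                                       "scaling_params.csv"))
  }

  # --- model ------------------------------------------------------------
  if ("model" %in% need) {
    tab <- res$preprocessed$table
    split <- stratified_split(tab, config$train_fraction,
                              seed = .stream_seed(config$seed, 11))
    rf <- tune_random_forest(split$train,
                             mtry_grid = config$mtry_grid,
                             ntree_grid = config$ntree_grid,
                             k_folds = config$k_folds,
                             seed = .stream_seed(config$seed, 12))
    rf_eval <- evaluate_classifier(rf, split$test)
    lda <- fit_lda(split$train)
    lda_eval <- evaluate_classifier(lda, split$test)
    pca <- pca_profile(tab)
    nmds <- nmds_profile(tab, k = config$nmds_k,
                         seed = .stream_seed(config$seed, 13))
    cda <- cda_profile(tab)
    report <- list(
      seed = config$seed,
      n_train = nrow(split$train), n_test = nrow(split$test),
      tuning_grid = rf$grid, best = rf$best,
      rf_cv_accuracy = rf$cv_accuracy,
      rf_resubstitution_accuracy = rf$resub_accuracy,
      rf_test_accuracy = rf_eval$accuracy,
      rf_misclassified = rf_eval$misclassified,
      rf_importance = rf$model$importance,
      lda_training_accuracy = lda$training_accuracy,
      lda_test_accuracy = lda_eval$accuracy,
      nmds_stress = nmds$stress,
      pca_variance_explained = pca$variance_explained,
      cda_eigenvalues = cda$eigenvalues)
    res$split <- split
    res$rf <- rf
    res$rf_eval <- rf_eval
    res$lda <- lda
    res$lda_eval <- lda_eval
    res$pca <- pca
    res$nmds <- nmds
    res$cda <- cda
    res$model_report <- report
    path <- file.path(out_dir, "model_report.json")
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- c(files, path)
    files <- c(files, .write_stage_csv(
      as.data.frame.matrix(rf_eval$confusion), out_dir, "confusion.csv"))
    files <- c(files, .write_stage_csv(nmds$coordinates, out_dir,
                                       "nmds_coordinates.csv"))
    files <- c(files, .write_stage_csv(cda$scores, out_dir,
                                       "cda_scores.csv"))
  }

  # --- manifest + resolved config --------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(.config_to_list(config), cfg_path)
  manifest <- list(
    package = "sepxrf",
    version = as.character(utils::packageVersion("sepxrf")),
    seed = config$seed,
    stages = need,
    files = lapply(setNames(files, basename(files)), function(f) {
      unname(tools::md5sum(f))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

.config_to_list <- function(config) {
  out <- unclass(config)
  gen <- unclass(out$generator)
  gen$site_effects <- apply(gen$site_effects, 1, as.list, simplify = FALSE)
  gen$collection_effects <- apply(gen$collection_effects, 1, as.list,
                                  simplify = FALSE)
  gen$group_defs <- split(gen$group_defs, seq_len(nrow(gen$group_defs)))
  gen$group_defs <- lapply(gen$group_defs, as.list)
  out$generator <- gen
  out
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `calibrate`, `qc`, `moisture`, `preprocess`,
#' `classify`, and `run-all` run the pipeline up to (and including) the
#' named stage. Options: `--config <yaml>` (generator settings),
#' `--seed <int>`, `--out <dir>`.
#'
#' @param args character vector of command-line arguments (default: the
#'   trailing `commandArgs()`).
#' @return invisibly, the [run_pipeline()] result.
#' @export
sep_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    stop("usage: sep_cli <simulate|calibrate|qc|moisture|preprocess|",
         "classify|run-all> [--config file.yaml] [--seed N] [--out dir]")
  }
  cmd <- args[[1L]]
  opt <- list(seed = 1L, out = "sepxrf-run", config = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (!key %in% names(opt)) stop("unknown option: ", args[[i]])
    opt[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  seed <- as.integer(opt$seed)
  gen <- if (!is.null(opt$config)) read_generator_config(opt$config) else NULL
  stage_map <- list(
    simulate = "simulate",
    calibrate = c("simulate", "calibrate"),
    qc = c("simulate", "calibrate", "qc"),
    moisture = c("simulate", "moisture"),
    preprocess = c("simulate", "calibrate", "qc", "preprocess"),
    classify = c("simulate", "calibrate", "qc", "preprocess", "model"),
    `run-all` = c("simulate", "calibrate", "qc", "moisture", "preprocess",
                  "model"))
  if (!cmd %in% names(stage_map)) stop("unknown subcommand: ", cmd)
  cfg <- pipeline_config(seed = seed, generator = gen,
                         stages = stage_map[[cmd]])
  message("sepxrf ", as.character(utils::packageVersion("sepxrf")),
          " | stage(s): ", paste(stage_map[[cmd]], collapse = ", "),
          " | seed: ", seed, " | out: ", opt$out)
  invisible(run_pipeline(cfg, opt$out))
}
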