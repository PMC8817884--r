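# End-to-end pipeline: simulate -> extract-features -> compare-indices ->
# build-samples -> train -> evaluate, driven by one flat validated config.

#' Default pipeline configuration
#'
#' One flat named list holding every tunable of the pipeline. Unknown keys
#' are rejected by [validate_config()].
#'
#' @param ... overrides of the defaults.
#' @return a validated `RunConfig` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    # cohort
    n_subjects = 12L, master_seed = 1L,
    # preprocess
    fs = 125, epoch_len = 500L, epoch_overlap = 0L,
    band_lo = 0.5, band_hi = 47, filter_order = 4L,
    # features
    sampen_m = 2L, sampen_r = 0.2, pe_m = 4L, pe_tau = 1L,
    we_wavelet = "db4", we_levels = 5L, bma_den_variant = "printed",
    # samples / split
    periods_per_sample = 12L, sample_stride = 1L,
    split_train = 8L, split_val = 2L, split_test = 2L,
    align_tolerance = 5,
    # network / training
    lr = 0.01, momentum = 0.9, weight_decay = 0.003,
    d_k = 9L, attention = TRUE, residual = TRUE,
    head = "linear", batch_size = 16L, checkpoint_every = 30L,
    accuracy_tol = 10, periods = 3L, iters_per_period = 600L,
    folds = 0L   # 0 = single split; > 1 = k-fold CV on the training split
  )
  over <- list(...)
  validate_config(utils::modifyList(cfg, over, keep.null = FALSE), names(over))
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and checks basic value constraints.
#'
#' @param cfg named list.
#' @param extra_keys keys the caller supplied (checked against the schema).
#' @return the validated config, classed `RunConfig`.
#' @export
validate_config <- function(cfg, extra_keys = names(cfg)) {
  known <- names(default_config_template())
  unknown <- setdiff(extra_keys, known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (cfg$n_subjects < 1) stopf("config n_subjects must be >= 1")
  if (cfg$split_train + cfg$split_val + cfg$split_test != cfg$n_subjects)
    stopf("config split sizes (%d+%d+%d) must sum to n_subjects (%d)",
          cfg$split_train, cfg$split_val, cfg$split_test, cfg$n_subjects)
  if (!(cfg$band_lo > 0 && cfg$band_lo < cfg$band_hi &&
        cfg$band_hi < cfg$fs / 2))
    stopf("config band must satisfy 0 < band_lo < band_hi < fs/2")
  if (!cfg$head %in% c("linear", "softmax"))
    stopf("config head must be 'linear' or 'softmax'")
  structure(cfg, class = "RunConfig")
}

default_config_template <- function() {
  # key schema only (avoids recursion with default_config)
  list(n_subjects = 0L, master_seed = 0L, fs = 0, epoch_len = 0L,
       epoch_overlap = 0L, band_lo = 0, band_hi = 0, filter_order = 0L,
       sampen_m = 0L, sampen_r = 0, pe_m = 0L, pe_tau = 0L,
       we_wavelet = "", we_levels = 0L, bma_den_variant = "",
       periods_per_sample = 0L, sample_stride = 0L, split_train = 0L,
       split_val = 0L, split_test = 0L, align_tolerance = 0,
       lr = 0, momentum = 0, weight_decay = 0,
       d_k = 0L, attention = TRUE, residual = TRUE, head = "",
       batch_size = 0L, checkpoint_every = 0L, accuracy_tol = 0,
       periods = 0L, iters_per_period = 0L, folds = 0L)
}

#' Load a YAML pipeline configuration
#'
#' Reads a flat YAML document, overlays it on the defaults and validates.
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(default_config, y)
}

write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in order on a seeded synthetic cohort,
#' writing every artifact (resolved config, feature table, index-comparison
#' report, per-split sample stores, training log, metrics report) into
#' `out_dir`. Each artifact's first comment line carries the config hash.
#' Re-running with an identical config and seed reproduces the artifacts.
#'
#' @param config a [default_config()] result.
#' @param out_dir output directory (created if missing).
#' @param stages subset of
#'   `c("simulate", "extract-features", "compare-indices", "build-samples",
#'   "train", "evaluate")`; later stages reuse in-memory results of earlier
#'   ones, so the requested stages must form a prefix-closed chain within
#'   one call.
#' @param quiet suppress progress messages.
#' @return invisible list with the in-memory results of each completed
#'   stage (`cohort`, `features`, `comparison`, `splits`, `train`,
#'   `metrics`, `paths`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         stages = c("simulate", "extract-features",
                                    "compare-indices", "build-samples",
                                    "train", "evaluate"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  all_stages <- c("simulate", "extract-features", "compare-indices",
                  "build-samples", "train", "evaluate")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  hash <- config_hash(config)
  write_config(config, file.path(out_dir, "config.yaml"))
  stamp <- function(path) {
    txt <- readLines(path)
    writeLines(c(sprintf("# config_hash=%s", hash), txt), path)
  }
  res <- list(paths = list(config = file.path(out_dir, "config.yaml")),
              config_hash = hash)

  spec <- generator_spec(n_subjects = config$n_subjects, fs = config$fs,
                         seed = config$master_seed)
  cohort <- NULL; features <- NULL; reference <- NULL; truth <- NULL

  if ("simulate" %in% stages) {
    say("simulating %d-subject cohort (seed %d)", config$n_subjects,
        config$master_seed)
    cohort <- simulate_cohort(spec)
    res$cohort <- cohort
  }

  if ("extract-features" %in% stages) {
    if (is.null(cohort)) stopf("extract-features requires the simulate stage")
    say("filtering, epoching and extracting features")
    params <- entropy_params(sampen_m = config$sampen_m,
                             sampen_r = config$sampen_r,
                             sampen_N = config$epoch_len,
                             pe_m = config$pe_m, pe_tau = config$pe_tau,
                             we_wavelet = config$we_wavelet,
                             we_levels = config$we_levels)
    bands <- spectral_bands(config$bma_den_variant)
    tabs <- lapply(cohort, function(sub) {
      rec <- bandpass_filter(sub$recording, config$band_lo, config$band_hi,
                             config$filter_order)
      es <- epoch_signal(rec, config$epoch_len, config$epoch_overlap)
      extract_features(es, sub$profile, params, bands)
    })
    features <- do.call(rbind, c(tabs, make.row.names = FALSE))
    fpath <- file.path(out_dir, "features.tsv")
    write_features(features, fpath); stamp(fpath)
    res$features <- features
    res$paths$features <- fpath
  }

  reference <- lapply(cohort %||% list(), function(sub) sub$reference)
  truth <- lapply(cohort %||% list(), function(sub) sub$trajectory)

  if ("compare-indices" %in% stages) {
    if (is.null(features)) stopf("compare-indices requires extract-features")
    say("comparing indices against the reference depth")
    comparison <- index_comparison(features, reference,
                                   tolerance = config$align_tolerance)
    cpath <- file.path(out_dir, "index_comparison.tsv")
    write_cor_report(comparison, cpath); stamp(cpath)
    res$comparison <- comparison
    res$paths$comparison <- cpath
  }

  splits <- NULL
  if ("build-samples" %in% stages) {
    if (is.null(features)) stopf("build-samples requires extract-features")
    say("splitting cohort %d/%d/%d and building 24x24 samples",
        config$split_train, config$split_val, config$split_test)
    ids <- unique(features$subject_id)
    cs <- split_cohort(ids, c(config$split_train, config$split_val,
                              config$split_test),
                       seed = config$master_seed)
    std <- fit_standardizer(
      features[features$subject_id %in% cs$train, , drop = FALSE])
    ft_std <- apply_standardizer(features, std)
    mk <- function(ids_part) {
      if (!length(ids_part)) return(NULL)
      build_samples(ft_std[ft_std$subject_id %in% ids_part, , drop = FALSE],
                    reference, config$periods_per_sample,
                    config$sample_stride, config$align_tolerance)
    }
    splits <- list(split = cs, standardizer = std,
                   train = mk(cs$train), validation = mk(cs$validation),
                   test = mk(cs$test), features_std = ft_std)
    for (part in c("train", "validation", "test")) {
      if (is.null(splits[[part]])) next
      sp <- file.path(out_dir, sprintf("samples_%s.tsv", part))
      write_samples(splits[[part]], sp); stamp(sp)
      res$paths[[paste0("samples_", part)]] <- sp
    }
    res$splits <- splits
  }

  trained <- NULL
  if ("train" %in% stages) {
    if (is.null(splits)) stopf("train requires build-samples")
    ncfg <- network_config(lr = config$lr, momentum = config$momentum,
                           weight_decay = config$weight_decay,
                           d_k = config$d_k,
                           attention = config$attention,
                           residual = config$residual, head = config$head,
                           batch_size = config$batch_size,
                           checkpoint_every = config$checkpoint_every,
                           accuracy_tol = config$accuracy_tol,
                           seed = config$master_seed)
    schedule <- list(periods = config$periods,
                     iters_per_period = config$iters_per_period)
    if (config$folds > 1L) {
      say("training with %d-fold subject-level cross-validation", config$folds)
      cv <- train_model(splits$train, ncfg, folds = config$folds,
                        schedule = schedule)
      trained <- cv$folds[[cv$best]]
      res$cv <- cv
    } else {
      say("training (%d x %d iterations)", config$periods,
          config$iters_per_period)
      trained <- train_network(splits$train, ncfg, val = splits$validation,
                               schedule = schedule)
    }
    lpath <- file.path(out_dir, "training_log.tsv")
    utils::write.table(trained$log, lpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stamp(lpath)
    res$train <- trained
    res$paths$training_log <- lpath
  }

  if ("evaluate" %in% stages) {
    if (is.null(trained)) stopf("evaluate requires train")
    say("evaluating on the held-out test subjects")
    test <- splits$test %||% splits$validation
    pred <- predict_network(trained$model, test$x)
    report <- phase_report(test$y, pred, test$phase,
                           tol = config$accuracy_tol)
    mpath <- file.path(out_dir, "metrics_report.tsv")
    write_metrics_report(report, mpath); stamp(mpath)
    res$metrics <- report
    res$predictions <- data.frame(subject_id = test$subject_id,
                                  time = test$time, phase = test$phase,
                                  observed = test$y, predicted = pred)
    res$paths$metrics <- mpath
  }

  invisible(res)
}
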