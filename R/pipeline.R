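#' End-to-end run configuration
#'
#' Bundles every knob of the pipeline (cohort synthesis, oracle physics,
#' representation, dataset assembly, autoencoder, surrogate, evaluation)
#' with one master seed that fans out deterministically to per-stage seeds,
#' so a run is reproducible from its config alone.
#'
#' @param n_geometries synthetic cohort size.
#' @param seed master integer seed.
#' @param cohort a [cohort_config()].
#' @param oracle an [oracle_params()].
#' @param ae_m,ae_grid,ae_epochs,ae_corpus_max autoencoder code size, raster
#'   grid, training epochs and training-corpus cap.
#' @param window_mm raster window, mm.
#' @param surrogate a [surrogate_config()].
#' @param mpd_threshold MPD filter threshold, mmHg.
#' @param n_subsets,test_index dataset split layout.
#' @param n_samples field samples per section.
#' @param measured use the field-sampling + averaging path for reference
#'   profiles (the full compact-representation pipeline).
#' @param out_dir optional output directory for run artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_geometries = 40L, seed = 1L,
                       cohort = cohort_config(), oracle = oracle_params(),
                       ae_m = 4L, ae_grid = 68L, ae_epochs = 1200L,
                       ae_corpus_max = 500L, window_mm = 50,
                       surrogate = surrogate_config(m = ae_m),
                       mpd_threshold = 120, n_subsets = 11L,
                       test_index = n_subsets, n_samples = 64L,
                       measured = TRUE, out_dir = NULL) {
  if (surrogate$m != ae_m) abort("configuration error: surrogate m must match ae_m")
  structure(list(n_geometries = as.integer(n_geometries), seed = as.integer(seed),
                 cohort = cohort, oracle = oracle, ae_m = as.integer(ae_m),
                 ae_grid = as.integer(ae_grid), ae_epochs = as.integer(ae_epochs),
                 ae_corpus_max = as.integer(ae_corpus_max),
                 window_mm = window_mm, surrogate = surrogate,
                 mpd_threshold = mpd_threshold, n_subsets = as.integer(n_subsets),
                 test_index = as.integer(test_index),
                 n_samples = as.integer(n_samples), measured = isTRUE(measured),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full surrogate pipeline
#'
#' Executes synthesis, oracle solution, representation, dataset assembly
#' (+/-25% flow augmentation, MPD filter, stratified geometry-grouped
#' split), autoencoder training, surrogate training on all non-test
#' subsets, and test-subset evaluation. Stages log their timing. When
#' `config$out_dir` is set, writes a manifest, config echo, model
#' checkpoints and the metrics table there.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return list with `cases`, `records` (filtered, with features/targets),
#'   `split`, `ae`, `model`, `test_metrics` (per-case metrics on the test
#'   subset), `report` (a [cohort_report()]), and bookkeeping counts
#'   (`n_baseline`, `n_augmented`, `n_retained`, `n_excluded`).
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    if (verbose) {
      message(sprintf("[%s] %.1fs", name, as.numeric(Sys.time() - t0, units = "secs")))
    }
    res
  }

  cases <- t_stage("synth", {
    params <- sample_cohort_params(config$n_geometries, config$cohort,
                                   seed = derive_seed(config$seed, "cohort"))
    cs <- lapply(seq_len(nrow(params)), function(i) build_case(params[i, ]))
    names(cs) <- params$geometry_id
    cs
  })

  records <- t_stage("oracle", {
    base <- build_cohort_records(cases, config$cohort, config$oracle,
                                 seed = derive_seed(config$seed, "flows"),
                                 measured = config$measured,
                                 n_samples = config$n_samples)
    augment_flows(base, cases, config$oracle,
                  seed = derive_seed(config$seed, "augment"),
                  measured = config$measured, n_samples = config$n_samples)
  })
  n_baseline <- sum(records$flow_condition == "baseline")
  n_augmented <- nrow(records)

  records <- t_stage("filter", filter_mpd(records, config$mpd_threshold))
  n_excluded <- attr(records, "n_excluded")

  split <- t_stage("split", split_datasets(records, config$n_subsets,
                                           config$test_index,
                                           seed = derive_seed(config$seed, "split")))

  ae <- t_stage("train-ae", {
    train_ids <- split$geometry_id[split$subset != attr(split, "test_index")]
    # spread the corpus across training geometries (every 4th section each),
    # then subsample evenly to the configured cap
    n_geo <- max(1L, min(length(train_ids), ceiling(config$ae_corpus_max / 30)))
    gsel <- train_ids[unique(round(seq(1, length(train_ids), length.out = n_geo)))]
    imgs <- list()
    for (id in gsel) {
      secs <- cases[[id]]$sections
      take <- seq(1, length(secs), by = 4)
      imgs <- c(imgs, lapply(secs[take], function(s) {
        rasterize_section(s, grid_size = config$ae_grid, window_mm = config$window_mm)
      }))
    }
    if (length(imgs) > config$ae_corpus_max) {
      imgs <- imgs[unique(round(seq(1, length(imgs),
                                    length.out = config$ae_corpus_max)))]
    }
    train_autoencoder(imgs,
                      m = config$ae_m,
                      seed = derive_seed(config$seed, "ae"),
                      epochs = config$ae_epochs)
  })

  records <- t_stage("features", build_feature_set(records, cases, ae,
                                                   window_mm = config$window_mm))

  model <- t_stage("train", {
    train_rec <- dplyr::semi_join(
      records,
      dplyr::filter(as_tibble(split), .data$subset != attr(split, "test_index")),
      by = "geometry_id")
    cfg <- config$surrogate
    cfg$seed <- derive_seed(config$seed, "surrogate")
    train_surrogate(train_rec, cfg)
  })

  eval_out <- t_stage("evaluate", {
    test_rec <- dplyr::semi_join(
      records,
      dplyr::filter(as_tibble(split), .data$subset == attr(split, "test_index")),
      by = "geometry_id")
    preds <- predict(model, test_rec$features)
    metrics <- purrr::map2_dfr(preds, test_rec$profile, case_metrics)
    metrics$geometry_id <- test_rec$geometry_id
    metrics$flow_condition <- test_rec$flow_condition
    report <- cohort_report(metrics, cohort_mpd = records$mpd,
                            seed = derive_seed(config$seed, "report"))
    list(metrics = metrics, report = report, test_records = test_rec,
         predictions = preds)
  })

  out <- list(cases = cases, records = records, split = split, ae = ae,
              model = model, test_metrics = eval_out$metrics,
              report = eval_out$report, predictions = eval_out$predictions,
              test_records = eval_out$test_records,
              n_baseline = n_baseline, n_augmented = n_augmented,
              n_retained = nrow(records), n_excluded = n_excluded,
              config = config)

  if (!is.null(config$out_dir)) t_stage("write", write_run_artifacts(out, config$out_dir))
  out
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  cfg_echo <- rapply(unclass(cfg), unclass, how = "replace")
  jsonlite::write_json(
    list(schema_version = BUNDLE_SCHEMA_VERSION, config = cfg_echo,
         r_version = as.character(getRversion()),
         counts = run[c("n_baseline", "n_augmented", "n_retained", "n_excluded")]),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- run$records[, c("geometry_id", "flow_condition", "flow_rate",
                              "flow_source", "mpd", "tpg", "peak_wss")]
  manifest <- dplyr::left_join(manifest, as_tibble(run$split), by = "geometry_id")
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write.csv(run$test_metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write_model_json(run$ae, file.path(out_dir, "autoencoder.json"))
  write_model_json(run$model, file.path(out_dir, "surrogate.json"))
  invisible(out_dir)
}
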