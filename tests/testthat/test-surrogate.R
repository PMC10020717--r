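test_that("training reduces the loss and is bitwise reproducible", {
  run <- fx_mini_run()
  model <- run$model
  expect_lt(tail(model$loss_history, 1), model$loss_history[1])

  train <- run$records[run$records$geometry_id %in%
                         run$split$geometry_id[run$split$subset != 6], ]
  cfg <- surrogate_config(lstm_hidden = 8L, fc_size = 4L, epochs = 3L, seed = 31L)
  m1 <- train_surrogate(train, cfg)
  m2 <- train_surrogate(train, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params$fw_Wx, m2$params$fw_Wx)
})

test_that("prediction preserves sequence length for any N", {
  run <- fx_mini_run()
  model <- run$model
  d <- 5L + model$config$m
  for (n in c(110L, 120L, 130L)) {
    X <- matrix(rnorm(n * d), n, d)
    out <- predict(model, X)
    expect_equal(nrow(out), n)
    expect_true(all(c("pressure_mmHg", "wss_Pa") %in% names(out)))
  }
  X <- run$records$features[[1]]
  expect_identical(predict(model, X), predict(model, X))
  expect_error(predict(model, X[, 1:4]), "width mismatch")
})

test_that("the trained surrogate orders stenosis severity like the oracle", {
  run <- fx_mini_run()
  recs <- run$records
  sev <- recs[which.max(recs$mpd), ]
  mild <- recs[which.min(recs$mpd), ]
  p_sev <- predict(run$model, sev$features[[1]])
  p_mild <- predict(run$model, mild$features[[1]])
  tpg_sev <- suppressWarnings(compute_tpg(p_sev$pressure_mmHg))
  tpg_mild <- suppressWarnings(compute_tpg(p_mild$pressure_mmHg))
  expect_gt(tpg_sev, tpg_mild)
})

test_that("cross-validation rotates over non-test subsets without leakage", {
  run <- fx_mini_run()
  cfg <- surrogate_config(lstm_hidden = 8L, fc_size = 4L, epochs = 2L, seed = 5L)
  cv <- cross_validate(run$records, run$split, cfg)
  expect_equal(nrow(cv), 5)       # 6 subsets, one reserved for testing
  expect_true(all(cv$n_val > 0))
  expect_false(attr(run$split, "test_index") %in% cv$subset)
  cv2 <- cross_validate(run$records, run$split, cfg)
  expect_equal(attr(cv, "mean_rmse"), attr(cv2, "mean_rmse"))
})

test_that("grid search selects the minimum mean RMSE with size tie-breaks", {
  run <- fx_mini_run()
  grid <- list(
    surrogate_config(lstm_hidden = 8L, fc_size = 4L, epochs = 2L, seed = 5L),
    surrogate_config(lstm_hidden = 12L, fc_size = 6L, epochs = 2L, seed = 5L)
  )
  gs <- grid_search(run$records, run$split, grid)
  expect_equal(nrow(gs$results), 2)
  best_rmse <- gs$results$mean_rmse[gs$results$config == gs$best_index]
  expect_equal(best_rmse, min(gs$results$mean_rmse))
  # single-config grid returns that config
  gs1 <- grid_search(run$records, run$split, grid[1])
  expect_equal(gs1$best_index, 1)
  expect_error(grid_search(run$records, run$split, list()), "empty")
  # the searched dimensions include the published optimum sizes
  big <- surrogate_config(lstm_hidden = 900L, fc_size = 200L, m = 4L)
  expect_equal(big$lstm_hidden, 900L)
  expect_equal(big$fc_size, 200L)
})

test_that("model checkpoints round-trip through JSON", {
  run <- fx_mini_run()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(run$model, path)
  back <- read_model_json(path)
  X <- run$records$features[[1]]
  expect_equal(predict(back, X)$pressure_mmHg, predict(run$model, X)$pressure_mmHg,
               tolerance = 1e-9)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model_json(run$ae, path2)
  ae2 <- read_model_json(path2)
  img <- fx_shape_corpus()[[1]]
  expect_equal(encode(ae2, img), encode(run$ae, img), tolerance = 1e-12)
  expect_error(read_model_json(withr::local_tempfile()), "missing")
})

test_that("local perturbation sensitivity is zero for constant features", {
  run <- fx_mini_run()
  X <- run$records$features[[1]]
  sd_raw <- run$model$stats$features$sd_raw
  if (any(sd_raw < 1e-12)) {
    j <- which(sd_raw < 1e-12)[1]
    expect_equal(perturb_sensitivity(run$model, X, 20L, j),
                 c(pressure = 0, wss = 0))
  }
  # a real perturbation changes the output
  s <- perturb_sensitivity(run$model, X, 20L, 5L)
  expect_gte(s[["pressure"]], 0)
  expect_warning(perturb_sensitivity(run$model, X, 2L, 5L, window_halfwidth = 5L),
                 "clipped")
  expect_error(perturb_sensitivity(run$model, X, 10000L, 1L), "range")
})

test_that("sensitivity maps carry regions and plot", {
  run <- fx_mini_run()
  rec <- run$records[1, ]
  X <- rec$features[[1]]
  regions <- run$cases[[rec$geometry_id]]$centerline$region
  sm <- sensitivity_map(run$model, X, point_indices = c(15L, 60L),
                        feature_indices = c(4L, 5L), regions = regions)
  expect_equal(nrow(sm), 4)
  expect_true(all(sm$drmse_p >= 0))
  expect_s3_class(ggplot2::autoplot(sm), "gg")
})
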