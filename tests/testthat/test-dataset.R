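test_that("flow assignment passes observed rates and models AVA dependence", {
  obs <- assign_flow(0.8, "observed", rate = 420)
  expect_equal(obs$flow_rate, 420)
  expect_equal(obs$flow_source, "observed")
  expect_error(assign_flow(0.8, "observed", rate = -3), "positive")

  expect_identical(assign_flow(0.7, "modelled", seed = 8L),
                   assign_flow(0.7, "modelled", seed = 8L))

  small <- vapply(1:2000, function(i) assign_flow(0.5, "modelled", seed = i)$flow_rate,
                  numeric(1))
  large <- vapply(1:2000, function(i) assign_flow(1.5, "modelled", seed = 10000L + i)$flow_rate,
                  numeric(1))
  expect_gt(mean(large), mean(small))
  trunc <- cohort_config()$flow_model$trunc
  expect_true(all(small >= trunc[1] & small <= trunc[2]))
})

test_that("flow augmentation triples records at 0.75x / 1.25x rates", {
  cases <- list()
  for (s in 1:3) cases[[sprintf("G%03d", s)]] <- build_case(sample_geometry_params(seed = 300L + s))
  base <- build_cohort_records(cases, seed = 1L, measured = FALSE)
  aug <- augment_flows(base, cases, measured = FALSE)
  expect_equal(nrow(aug), 3 * nrow(base))
  for (id in names(cases)) {
    sub <- aug[aug$geometry_id == id, ]
    q0 <- sub$flow_rate[sub$flow_condition == "baseline"]
    expect_equal(sub$flow_rate[sub$flow_condition == "minus25"], 0.75 * q0)
    expect_equal(sub$flow_rate[sub$flow_condition == "plus25"], 1.25 * q0)
    # oracle MPD is monotone in flow at fixed geometry
    expect_lt(sub$mpd[sub$flow_condition == "minus25"], q0_mpd <- sub$mpd[sub$flow_condition == "baseline"])
    expect_gt(sub$mpd[sub$flow_condition == "plus25"], q0_mpd)
    expect_true(all(sub$mpd >= 0))
  }
  expect_error(augment_flows(aug, cases), "baseline")
  dup <- dplyr::bind_rows(base, base[1, ])
  expect_error(augment_flows(dup, cases), "duplicate")
})

test_that("the MPD filter is boundary-inclusive and order-preserving", {
  recs <- tibble::tibble(geometry_id = sprintf("G%d", 1:4),
                         mpd = c(50, 120, 121, 200))
  kept <- filter_mpd(recs, 120)
  expect_equal(kept$mpd, c(50, 120))
  expect_equal(attr(kept, "n_excluded"), 2L)
  empty <- filter_mpd(recs[0, ], 120)
  expect_equal(nrow(empty), 0)
  # property: retained set is exactly {mpd <= threshold}
  set.seed(1)
  rnd <- tibble::tibble(geometry_id = as.character(1:200), mpd = runif(200, 0, 200))
  out <- filter_mpd(rnd, 120)
  expect_setequal(out$geometry_id, rnd$geometry_id[rnd$mpd <= 120])
  expect_lte(max(out$mpd), 120)
})

test_that("the stratified split groups geometries and spans the MPD range", {
  set.seed(42)
  n_geom <- 88L
  base_mpd <- runif(n_geom, 2, 118)
  recs <- dplyr::bind_rows(lapply(seq_len(n_geom), function(i) {
    tibble::tibble(geometry_id = sprintf("G%03d", i),
                   flow_condition = c("baseline", "minus25", "plus25"),
                   mpd = base_mpd[i] * c(1, 0.6, 1.5))
  }))
  recs <- filter_mpd(recs, 120)
  split <- split_datasets(recs, n_subsets = 11L, test_index = 11L, seed = 3L)
  expect_equal(sort(unique(split$subset)), 1:11)
  expect_setequal(split$geometry_id, sprintf("G%03d", 1:88))
  expect_equal(anyDuplicated(split$geometry_id), 0L)
  expect_equal(unname(table(split$subset)), rep(8L, 11), ignore_attr = TRUE)
  # every subset spans >= 60% of the global baseline-MPD range
  key <- stats::setNames(base_mpd, sprintf("G%03d", seq_len(n_geom)))
  global <- diff(range(key))
  for (k in 1:11) {
    ids <- split$geometry_id[split$subset == k]
    expect_gte(diff(range(key[ids])), 0.6 * global)
  }
  expect_error(split_datasets(recs[1:12, ], n_subsets = 11L), "fewer geometries")
})

test_that("feature sequences have width 5 + m with correct flow normalization", {
  run <- fx_mini_run()
  rec <- run$records[1, ]
  X <- rec$features[[1]]
  expect_equal(ncol(X), 9)
  expect_equal(nrow(X), nrow(run$cases[[rec$geometry_id]]$centerline))
  # Q/A in m/s: 400 ml/s over 400 mm^2 is 1 m/s
  case <- run$cases[[rec$geometry_id]]
  X2 <- build_features(list(flow_rate = 400), case, run$ae)
  i400 <- which.min(abs(case$centerline$area - 400))
  expect_equal(X2[i400, "qa"], 400 / case$centerline$area[i400], ignore_attr = TRUE)
  # changing only flow changes only the qa column
  X3 <- build_features(list(flow_rate = 500), case, run$ae)
  expect_equal(X2[, -5], X3[, -5])
  expect_true(all(X2[, 5] != X3[, 5]))
  # pose normalization: inlet at origin, first tangent along +z
  expect_equal(unname(X2[1, 1:3]), c(0, 0, 0))
  t1 <- X2[2, 1:3] - X2[1, 1:3]
  expect_equal(unname(t1 / sqrt(sum(t1^2)))[3], 1, tolerance = 1e-9)
})

test_that("standardization round-trips and guards constant columns", {
  set.seed(9)
  seqs <- lapply(1:5, function(i) cbind(rnorm(20, 5, 2), runif(20), 7))
  expect_warning(st <- feature_stats(seqs), "zero-variance")
  scaled <- scale_seqs(seqs, st)
  stacked <- do.call(rbind, scaled)
  expect_equal(colMeans(stacked)[1:2], c(0, 0), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(apply(stacked, 2, sd)[1:2], c(1, 1), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(stacked[, 3], rep(0, 100))       # centered but unscaled
  back <- unscale_seqs(scaled, st)
  expect_equal(back, seqs, tolerance = 1e-10)
})
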