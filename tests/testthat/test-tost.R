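test_that("metric formulas match hand-computed examples exactly", {
  expect_equal(rmse_pressure(c(1, 2, 3), c(1, 2, 7)), sqrt(16 / 3))
  expect_equal(rmse_pressure(c(5, 5), c(5, 5)), 0)
  expect_equal(rmse_pressure(c(3, 4, 5), c(1, 2, 3)), 2) # constant offset
  expect_equal(nrmse_pressure(c(100, 64, 80), c(100, 60, 80)),
               sqrt((0 + (4 / 40)^2 + 0) / 3))
  expect_equal(nrmse_wss(c(10, 45, 20), c(10, 50, 20)), sqrt((5 / 50)^2 / 3))
  expect_error(rmse_pressure(1:3, 1:4), "mismatch")
  expect_error(nrmse_pressure(c(1, 1), c(1, 1)), "undefined")
  expect_error(nrmse_wss(c(0, 0), c(0, 0)), "undefined")
})

test_that("metric implementations agree with brute-force summation", {
  # independent oracle: elementwise loops, no shared code
  brute_rmse <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
    sqrt(s / length(a))
  }
  brute_nrmse_p <- function(a, b) {
    den <- b[1] - min(b)
    s <- 0
    for (i in seq_along(a)) s <- s + ((a[i] - b[i]) / den)^2
    sqrt(s / length(a))
  }
  brute_nrmse_w <- function(a, b) {
    den <- max(b)
    s <- 0
    for (i in seq_along(a)) s <- s + ((a[i] - b[i]) / den)^2
    sqrt(s / length(a))
  }
  set.seed(17)
  for (k in 1:1000) {
    n <- sample(5:60, 1)
    ref <- c(130, 130 - cumsum(runif(n - 1, -2, 3)))
    pred <- ref + rnorm(n, 0, 2)
    wref <- abs(rnorm(n, 10, 5)) + 0.1
    wpred <- wref + rnorm(n)
    expect_equal(rmse_pressure(pred, ref), brute_rmse(pred, ref), tolerance = 1e-12)
    if (ref[1] > min(ref)) {
      expect_equal(nrmse_pressure(pred, ref), brute_nrmse_p(pred, ref), tolerance = 1e-12)
    }
    expect_equal(nrmse_wss(wpred, wref), brute_nrmse_w(wpred, wref), tolerance = 1e-12)
  }
})

test_that("NRMSE summand form equals RMSE over the per-case denominator", {
  set.seed(3)
  ref <- c(130, 130 - cumsum(runif(40, -1, 2)))
  pred <- ref + rnorm(41)
  expect_equal(nrmse_pressure(pred, ref),
               rmse_pressure(pred, ref) / (ref[1] - min(ref)), tolerance = 1e-12)
  # shift invariance: adding a constant to both profiles changes nothing
  expect_equal(nrmse_pressure(pred + 13, ref + 13), nrmse_pressure(pred, ref),
               tolerance = 1e-12)
})

test_that("signed-rank test matches wilcox.test away from ties and zeros", {
  set.seed(11)
  for (k in 1:25) {
    x <- rnorm(sample(8:20, 1)) + runif(1, -0.5, 0.5)
    ours <- signed_rank_test(x, alternative = "greater")
    ref <- wilcox.test(x, alternative = "greater", exact = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    ours2 <- signed_rank_test(x, alternative = "less")
    ref2 <- wilcox.test(x, alternative = "less", exact = TRUE)
    expect_equal(ours2$p.value, ref2$p.value, tolerance = 1e-12)
  }
})

test_that("perfect agreement yields equivalence with the exact 2^-n tail", {
  res <- tost_tpg(rep(30, 23), rep(30, 23), epsilon = 5)
  expect_true(res$equivalent)
  expect_equal(res$p_lower, 2^-23, tolerance = 1e-12)
  expect_equal(res$p_upper, 2^-23, tolerance = 1e-12)
  expect_equal(res$theta, 0)
})

test_that("a constant 10 mmHg bias defeats the 5 mmHg margin", {
  ref <- seq(20, 110, length.out = 23)
  res <- tost_tpg(ref, ref - 10, epsilon = 5)
  expect_false(res$equivalent)
  expect_gt(res$p_upper, 0.05)   # H2_0 (Theta > epsilon) not rejected
  expect_lt(res$p_lower, 0.05)
  # and the equivalence flag is exactly the conjunction of the two tests
  expect_identical(res$equivalent, res$p_lower < res$alpha && res$p_upper < res$alpha)
})

test_that("TOST is monotone in the equivalence margin", {
  set.seed(7)
  for (k in 1:100) {
    n <- sample(8:23, 1)
    ref <- runif(n, 10, 100)
    pred <- ref + rnorm(n, mean = runif(1, -4, 4), sd = runif(1, 0.5, 4))
    eps1 <- runif(1, 1, 6)
    eps2 <- eps1 + runif(1, 0.5, 6)
    r1 <- tost_tpg(ref, pred, epsilon = eps1)
    r2 <- tost_tpg(ref, pred, epsilon = eps2)
    if (r1$equivalent) expect_true(r2$equivalent)
    expect_lte(r2$p_lower, r1$p_lower + 1e-12)
    expect_lte(r2$p_upper, r1$p_upper + 1e-12)
  }
})

test_that("type-I error at the margin stays near the nominal level", {
  set.seed(2024)
  n <- 23
  alpha <- 0.05
  rejections <- vapply(1:2000, function(k) {
    d <- 5 + rnorm(n, 0, 3)  # true median difference exactly at +epsilon
    # the relevant one-sided test: H2_0 rejected (claiming Theta < epsilon)
    signed_rank_test(d - 5, alternative = "less")$p.value < alpha
  }, logical(1))
  expect_lte(mean(rejections), alpha + 0.02)
})

test_that("tost input contracts are enforced", {
  expect_error(tost_tpg(1:10, 1:9), "unpaired")
  expect_error(tost_tpg(1:5, 1:5), "at least 6")
  expect_error(tost_tpg(1:10, 1:10, epsilon = 0), "positive")
})

test_that("Monte-Carlo Lilliefors agrees with the analytic approximation", {
  skip_if_not_installed("nortest")
  set.seed(5)
  x_norm <- rnorm(30)
  x_skew <- rexp(30)
  for (x in list(x_norm, x_skew)) {
    ours <- lilliefors_test(x, nsim = 4000, seed = 1)
    ref <- nortest::lillie.test(x)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_lt(abs(ours$p.value - ref$p.value), 0.05)
  }
})

test_that("cohort report summarizes medians, IQRs and correlations", {
  set.seed(8)
  n <- 23
  mpd <- runif(n, 5, 110)
  metrics <- tibble::tibble(
    rmse_p = 0.05 * mpd,                    # perfectly linear in MPD
    nrmse_p = runif(n, 0.02, 0.1),
    rmse_wss = abs(rnorm(n, 5, 2)),
    nrmse_wss = runif(n, 0.02, 0.1),
    mpd_ref = mpd,
    peak_wss_ref = runif(n, 20, 300),
    tpg_ref = mpd * 0.8,
    tpg_pred = mpd * 0.8 + rnorm(n, 0, 1)
  )
  rep <- cohort_report(metrics, cohort_mpd = c(mpd, runif(40, 5, 110)), seed = 1)
  expect_equal(rep$correlations$r[1], 1.0, tolerance = 1e-9)
  med <- rep$summary$median[rep$summary$metric == "rmse_p"]
  expect_equal(med, median(0.05 * mpd))
  expect_true(all(c("summary", "correlations", "tost", "normality") %in% names(rep)))
  # hand quantile example: median 2.5, IQR from linear-interpolation quantiles
  m2 <- metrics
  m2$rmse_p <- rep_len(c(1, 2, 3, 4), n)
  sm <- cohort_report(m2, seed = 1)$summary
  v <- rep_len(c(1, 2, 3, 4), n)
  expect_equal(sm$median[sm$metric == "rmse_p"], median(v))
  expect_equal(sm$iqr[sm$metric == "rmse_p"],
               unname(diff(quantile(v, c(0.25, 0.75)))))
})

test_that("identical distributions pass the rank-sum comparison most of the time", {
  set.seed(31)
  pass <- vapply(1:500, function(k) {
    a <- runif(23, 0, 120)
    b <- runif(200, 0, 120)
    suppressWarnings(wilcox.test(a, b)$p.value) > 0.05
  }, logical(1))
  expect_gte(mean(pass), 0.94)
})
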