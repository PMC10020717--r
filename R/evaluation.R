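#' Accuracy metrics between predicted and reference profiles
#'
#' `rmse_pressure()` is the root-mean-square of pointwise pressure
#' differences (mmHg). `nrmse_pressure()` divides each pointwise residual
#' by the reference maximum pressure drop (inlet minus infimum) inside the
#' sum before root-mean-squaring; since the denominator is constant per
#' case this equals RMSE / MPD, but the summand form is implemented as
#' printed and tested for the equality. `nrmse_wss()` normalizes residuals
#' by the reference supremum WSS.
#'
#' @param pred,ref numeric sequences (or `hemodynamic_profile` tibbles) of
#'   equal length; `ref` is the ground-truth (CFD-role) profile.
#' @return scalar metric: mmHg for RMSE, dimensionless fraction for NRMSE.
#' @export
#' @examples
#' rmse_pressure(c(1, 2, 3), c(1, 2, 7)) # sqrt(16/3)
rmse_pressure <- function(pred, ref) {
  p <- profile_pressure(pred); r <- profile_pressure(ref)
  check_paired(p, r)
  rms(p - r)
}

#' @rdname rmse_pressure
#' @export
rmse_wss <- function(pred, ref) {
  p <- profile_wss(pred); r <- profile_wss(ref)
  check_paired(p, r)
  rms(p - r)
}

#' @rdname rmse_pressure
#' @export
nrmse_pressure <- function(pred, ref) {
  p <- profile_pressure(pred); r <- profile_pressure(ref)
  check_paired(p, r)
  denom <- r[1] - min(r)
  if (denom <= 0) abort("undefined metric: reference profile has no pressure drop")
  sqrt(mean(((p - r) / denom)^2))
}

#' @rdname rmse_pressure
#' @export
nrmse_wss <- function(pred, ref) {
  p <- profile_wss(pred); r <- profile_wss(ref)
  check_paired(p, r)
  denom <- max(r)
  if (denom <= 0) abort("undefined metric: reference WSS is identically zero")
  sqrt(mean(((p - r) / denom)^2))
}

check_paired <- function(p, r) {
  if (length(p) != length(r)) abort("sequence length mismatch")
  if (length(p) < 1) abort("empty sequences")
  invisible(TRUE)
}

#' Wilcoxon signed-rank test with exact tied/zero-aware null
#'
#' One-sample signed-rank test of location against `mu`. Zero differences
#' are handled by Pratt's method (they receive ranks but are excluded from
#' the statistic). For n <= `exact_max` the p-value uses the exact sign-flip
#' permutation distribution of the statistic, computed by dynamic
#' programming over the (possibly tied) ranks, which remains exact under
#' ties and zeros; above that a normal approximation with tie correction is
#' used.
#'
#' @param x numeric sample (paired differences).
#' @param mu null location.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param exact_max largest n for which the exact null is enumerated.
#' @return list with `statistic` (W+, sum of positive signed ranks),
#'   `p.value`, `n`, `method`.
#' @export
signed_rank_test <- function(x, mu = 0, alternative = c("greater", "less", "two.sided"),
                             exact_max = 25L) {
  alternative <- match.arg(alternative)
  d <- x - mu
  n <- length(d)
  if (n < 1) abort("empty sample")
  r <- rank(abs(d))            # Pratt: zeros are ranked too
  nonzero <- d != 0
  w_obs <- sum(r[nonzero & d > 0])
  ranks <- r[nonzero]

  if (n <= exact_max) {
    # exact sign-flip null of W+ over the nonzero ranks (ties doubled to
    # integer grid: ranks are multiples of 1/2)
    ir <- as.integer(round(2 * ranks))
    tot <- sum(ir)
    dp <- numeric(tot + 1L)
    dp[1] <- 1
    for (rk in ir) {
      shifted <- c(numeric(rk), dp[seq_len(tot + 1L - rk)])
      dp <- (dp + shifted) / 2
    }
    w2 <- as.integer(round(2 * w_obs))
    p_ge <- sum(dp[(w2 + 1L):(tot + 1L)])
    p_le <- sum(dp[seq_len(w2 + 1L)])
    method <- "exact sign-flip"
  } else {
    mu_w <- sum(ranks) / 2
    sig <- sqrt(sum(ranks^2) / 4)
    p_ge <- pnorm((w_obs - 0.5 - mu_w) / sig, lower.tail = FALSE)
    p_le <- pnorm((w_obs + 0.5 - mu_w) / sig)
    method <- "normal approximation"
  }
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  list(statistic = w_obs, p.value = min(1, max(0, p)), n = n, method = method)
}

#' TOST equivalence test for transvalvular pressure gradients
#'
#' Two one-sided tests on paired TPG values from the reference (CFD-role)
#' and predicted (surrogate) methods. With paired differences
#' `d = ref - pred` and median difference Theta, the null hypotheses
#' `Theta < theta0 - epsilon` and `Theta > theta0 + epsilon` are each
#' tested with a one-sided Wilcoxon signed-rank test (TPG values are
#' typically not normally distributed); equivalence within `epsilon` is
#' declared iff both are rejected at level `alpha`. The default margin of
#' 5 mmHg corresponds to the accuracy of clinical catheter-based pressure
#' measurements.
#'
#' @param tpg_ref,tpg_pred paired TPG samples, mmHg (n >= 6).
#' @param epsilon equivalence margin, mmHg.
#' @param alpha significance level.
#' @param theta0 reference difference (default 0).
#' @return object of class `equivalence_result`: `theta` (median paired
#'   difference), `theta0`, `epsilon`, `alpha`, `p_lower`, `p_upper`,
#'   `equivalent`, `mu_ref`, `mu_pred`, `n`.
#' @export
tost_tpg <- function(tpg_ref, tpg_pred, epsilon = 5, alpha = 0.05, theta0 = 0) {
  if (length(tpg_ref) != length(tpg_pred)) abort("unpaired samples")
  n <- length(tpg_ref)
  if (n < 6) abort("insufficient sample: need at least 6 pairs")
  if (epsilon <= 0) abort("epsilon must be positive")
  d <- tpg_ref - tpg_pred
  # H1_0: Theta < theta0 - epsilon, rejected when the shifted differences
  # are located above zero
  p_lower <- signed_rank_test(d - (theta0 - epsilon), alternative = "greater")$p.value
  # H2_0: Theta > theta0 + epsilon, rejected when located below zero
  p_upper <- signed_rank_test(d - (theta0 + epsilon), alternative = "less")$p.value
  structure(list(theta = median(d), theta0 = theta0, epsilon = epsilon,
                 alpha = alpha, p_lower = p_lower, p_upper = p_upper,
                 equivalent = (p_lower < alpha) && (p_upper < alpha),
                 mu_ref = median(tpg_ref), mu_pred = median(tpg_pred), n = n),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat("TOST equivalence, margin +/-", x$epsilon, "mmHg, alpha", x$alpha, "\n")
  cat("  medians ref/pred:", round(x$mu_ref, 2), "/", round(x$mu_pred, 2),
      "mmHg; median difference", round(x$theta, 3), "\n")
  cat("  one-sided p:", format(x$p_lower, digits = 3), "(lower),",
      format(x$p_upper, digits = 3), "(upper)\n")
  cat("  =>", if (x$equivalent) "equivalent" else "NOT equivalent",
      "within the margin\n")
  invisible(x)
}

#' @method tidy equivalence_result
#' @export
tidy.equivalence_result <- function(x, ...) {
  tibble(theta = x$theta, theta0 = x$theta0, epsilon = x$epsilon,
         alpha = x$alpha, p_lower = x$p_lower, p_upper = x$p_upper,
         equivalent = x$equivalent, mu_ref = x$mu_ref, mu_pred = x$mu_pred,
         n = x$n)
}

#' @method glance equivalence_result
#' @export
glance.equivalence_result <- function(x, ...) tidy(x)

#' Lilliefors normality test with Monte-Carlo critical values
#'
#' Kolmogorov-Smirnov distance against a normal with estimated mean and SD;
#' the p-value comes from a seeded parametric bootstrap (default 10^4
#' replicates) that re-estimates the parameters in each replicate.
#'
#' @param x numeric sample (n >= 5).
#' @param nsim bootstrap replicates.
#' @param seed integer seed.
#' @return list with `statistic` (D), `p.value`, `n`, `nsim`.
#' @export
lilliefors_test <- function(x, nsim = 10000L, seed = 1L) {
  n <- length(x)
  if (n < 5) abort("need at least 5 observations")
  lillie_d <- function(v) {
    m <- mean(v); s <- sd(v)
    Fv <- pnorm(sort(v), m, s)
    i <- seq_len(length(v))
    max(max(i / length(v) - Fv), max(Fv - (i - 1) / length(v)))
  }
  d_obs <- lillie_d(x)
  d_null <- with_seed(seed, {
    vapply(seq_len(nsim), function(k) lillie_d(rnorm(n)), numeric(1))
  })
  list(statistic = d_obs,
       p.value = (1 + sum(d_null >= d_obs)) / (nsim + 1),
       n = n, nsim = nsim)
}

#' Per-case accuracy metrics
#'
#' @param pred predicted `hemodynamic_profile` (surrogate).
#' @param ref reference profile (oracle / measured representation).
#' @return one-row tibble: `rmse_p`, `nrmse_p`, `rmse_wss`, `nrmse_wss`,
#'   `mpd_ref`, `peak_wss_ref`, `tpg_ref`, `tpg_pred`.
#' @export
case_metrics <- function(pred, ref) {
  tibble(
    rmse_p = rmse_pressure(pred, ref),
    nrmse_p = nrmse_pressure(pred, ref),
    rmse_wss = rmse_wss(pred, ref),
    nrmse_wss = nrmse_wss(pred, ref),
    mpd_ref = compute_mpd(ref),
    peak_wss_ref = max(profile_wss(ref)),
    tpg_ref = compute_tpg(ref),
    tpg_pred = compute_tpg(profile_pressure(pred))
  )
}

#' Cohort-level evaluation report
#'
#' Summarizes per-case metrics: medians and IQRs (linear-interpolation
#' quantiles), Pearson correlations of absolute RMSE against reference MPD
#' and peak WSS, a Wilcoxon rank-sum comparison of the test-subset MPD
#' distribution against the full cohort, a Lilliefors normality test of the
#' WSS RMSE, and the TOST TPG equivalence test.
#'
#' @param metrics tibble of [case_metrics()] rows (>= 3 cases).
#' @param cohort_mpd optional full-cohort MPD values for the rank-sum
#'   comparison.
#' @param epsilon,alpha TOST margin and level.
#' @param seed seed for the Lilliefors bootstrap.
#' @return object of class `eval_report`: list with `summary` (median/IQR
#'   per metric), `correlations`, `tost`, `normality`, `ranksum`.
#' @export
cohort_report <- function(metrics, cohort_mpd = NULL, epsilon = 5,
                          alpha = 0.05, seed = 1L) {
  if (nrow(metrics) < 3) abort("need at least 3 cases")
  num_cols <- c("rmse_p", "nrmse_p", "rmse_wss", "nrmse_wss", "mpd_ref",
                "peak_wss_ref", "tpg_ref", "tpg_pred")
  summary <- purrr::map_dfr(num_cols, function(cn) {
    v <- metrics[[cn]]
    tibble(metric = cn, median = median(v),
           iqr = unname(diff(quantile(v, c(0.25, 0.75), type = 7))))
  })
  cor_safe <- function(a, b) {
    if (sd(a) < 1e-12 || sd(b) < 1e-12) {
      return(tibble(r = NA_real_, p = NA_real_, note = "undefined (constant input)"))
    }
    ct <- cor.test(a, b, method = "pearson")
    tibble(r = unname(ct$estimate), p = ct$p.value, note = "")
  }
  correlations <- dplyr::bind_rows(
    dplyr::mutate(cor_safe(metrics$rmse_p, metrics$mpd_ref),
                  pair = "rmse_p ~ mpd_ref", .before = 1),
    dplyr::mutate(cor_safe(metrics$rmse_wss, metrics$peak_wss_ref),
                  pair = "rmse_wss ~ peak_wss_ref", .before = 1)
  )
  tost <- tost_tpg(metrics$tpg_ref, metrics$tpg_pred, epsilon = epsilon,
                   alpha = alpha)
  normality <- lilliefors_test(metrics$rmse_wss, seed = seed)
  ranksum <- NULL
  if (!is.null(cohort_mpd)) {
    rs <- suppressWarnings(wilcox.test(metrics$mpd_ref, cohort_mpd))
    ranksum <- list(statistic = unname(rs$statistic), p.value = rs$p.value)
  }
  structure(list(summary = summary, correlations = correlations, tost = tost,
                 normality = normality, ranksum = ranksum,
                 n_cases = nrow(metrics)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$n_cases, "test cases\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat("correlations:\n")
  print(as.data.frame(x$correlations), row.names = FALSE)
  print(x$tost)
  cat("WSS RMSE normality (Lilliefors, MC): D =",
      format(x$normality$statistic, digits = 3), ", p =",
      format(x$normality$p.value, digits = 3), "\n")
  if (!is.null(x$ranksum)) {
    cat("test vs cohort MPD rank-sum p =", format(x$ranksum$p.value, digits = 3), "\n")
  }
  invisible(x)
}

#' Local feature-perturbation sensitivity
#'
#' Perturbs one input feature by +1 and -1 training-set standard deviation
#' over a window of centerline points around `point_index`, re-predicts,
#' and reports the mean output RMSE (per channel) between perturbed and
#' unperturbed predictions. Constant features (zero raw SD) yield zero by
#' definition.
#'
#' @param model trained `aorta_surrogate`.
#' @param features raw feature matrix for one case.
#' @param point_index centerline point at the window center.
#' @param feature_index which feature column to perturb.
#' @param window_halfwidth half-width in points (default 3, i.e. 6 mm at
#'   2 mm spacing).
#' @return named numeric: `pressure` (mmHg), `wss` (Pa).
#' @export
perturb_sensitivity <- function(model, features, point_index, feature_index,
                                window_halfwidth = 3L) {
  n <- nrow(features)
  if (point_index < 1 || point_index > n) abort("point_index out of range")
  if (feature_index < 1 || feature_index > ncol(features)) abort("feature_index out of range")
  lo <- point_index - window_halfwidth
  hi <- point_index + window_halfwidth
  if (lo < 1 || hi > n) {
    warn("perturbation window clipped at the sequence boundary")
    lo <- max(1, lo); hi <- min(n, hi)
  }
  sd_raw <- model$stats$features$sd_raw[feature_index]
  if (sd_raw < 1e-12) return(c(pressure = 0, wss = 0))
  base <- predict(model, features)
  deltas <- vapply(c(1, -1), function(sgn) {
    pert <- features
    pert[lo:hi, feature_index] <- pert[lo:hi, feature_index] + sgn * sd_raw
    pp <- predict(model, pert)
    c(rms(pp$pressure_mmHg - base$pressure_mmHg), rms(pp$wss_Pa - base$wss_Pa))
  }, numeric(2))
  c(pressure = mean(deltas[1, ]), wss = mean(deltas[2, ]))
}

#' Sensitivity map over points and features
#'
#' Applies [perturb_sensitivity()] over a grid of centerline points and
#' feature columns.
#'
#' @inheritParams perturb_sensitivity
#' @param point_indices centerline points to probe (default: every 5th
#'   interior point).
#' @param feature_indices feature columns to probe (default: all).
#' @param regions optional character vector labelling each centerline point
#'   (attached to the output for region-wise summaries).
#' @return tibble of class `sensitivity_map`: `point`, `feature`,
#'   `drmse_p`, `drmse_wss`, and `region` if supplied.
#' @export
sensitivity_map <- function(model, features, point_indices = NULL,
                            feature_indices = NULL, window_halfwidth = 3L,
                            regions = NULL) {
  n <- nrow(features)
  point_indices <- point_indices %||%
    seq(window_halfwidth + 1L, n - window_halfwidth, by = 5L)
  feature_indices <- feature_indices %||% seq_len(ncol(features))
  grid <- expand.grid(point = point_indices, feature = feature_indices)
  vals <- purrr::map2(grid$point, grid$feature, function(p, f) {
    perturb_sensitivity(model, features, p, f, window_halfwidth)
  })
  out <- tibble(
    point = grid$point,
    feature = colnames(features)[grid$feature] %||% as.character(grid$feature),
    drmse_p = vapply(vals, `[[`, numeric(1), "pressure"),
    drmse_wss = vapply(vals, `[[`, numeric(1), "wss")
  )
  if (!is.null(regions)) out$region <- regions[out$point]
  class(out) <- c("sensitivity_map", class(out))
  out
}
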