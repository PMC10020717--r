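#' Assign a peak-systolic flow rate to a geometry
#'
#' `"observed"` mode passes a supplied rate through unchanged. `"modelled"`
#' mode draws from a truncated normal whose mean shifts with the valve
#' orifice area: `mu_Q = intercept + slope * AVA` (ml/s), SD
#' `sd_frac * mu_Q`, truncated to `trunc`. The randomness avoids a
#' deterministic geometry-to-flow relationship that would hurt
#' generalization.
#'
#' @param ava aortic valve area, cm^2.
#' @param mode `"modelled"` or `"observed"`.
#' @param rate supplied rate for observed mode, ml/s.
#' @param flow_model list with `intercept`, `slope`, `sd_frac`, `trunc`
#'   (see [cohort_config()]).
#' @param seed integer seed (modelled mode).
#' @return list with `flow_rate` (ml/s) and `flow_source`.
#' @export
assign_flow <- function(ava, mode = c("modelled", "observed"), rate = NULL,
                        flow_model = cohort_config()$flow_model, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "observed") {
    if (is.null(rate) || !is.finite(rate) || rate <= 0) {
      abort("observed mode requires a positive flow rate")
    }
    return(list(flow_rate = rate, flow_source = "observed"))
  }
  mu <- flow_model$intercept + flow_model$slope * ava
  q <- with_seed(seed, rtruncnorm(1, mu, flow_model$sd_frac * mu,
                                  flow_model$trunc[1], flow_model$trunc[2]))
  list(flow_rate = q, flow_source = "modelled")
}

#' Solve one case record (geometry + flow condition)
#'
#' Runs the physics oracle, optionally passes the solution through the
#' field-sampling + averaging pipeline (the measured compact
#' representation), and derives the summary scalars MPD, TPG and peak WSS.
#'
#' @param case a `case_geometry`.
#' @param flow_rate ml/s.
#' @param flow_condition `"baseline"`, `"minus25"` or `"plus25"`.
#' @param flow_source `"observed"` or `"modelled"`.
#' @param oracle an [oracle_params()].
#' @param seed seed for field sampling.
#' @param measured if `TRUE` (default) the stored profile is the
#'   field-sampled + averaged representation; otherwise the exact oracle
#'   profile.
#' @param n_samples field samples per section.
#' @return one-row tibble: `geometry_id`, `flow_condition`, `flow_rate`,
#'   `flow_source`, `profile` (list column), `mpd`, `tpg`, `peak_wss`.
#' @export
solve_case_record <- function(case, flow_rate, flow_condition = "baseline",
                              flow_source = "modelled",
                              oracle = oracle_params(), seed = 1L,
                              measured = TRUE, n_samples = 64L) {
  prof <- solve_profile(case, flow_rate, oracle)
  if (measured) {
    fs <- sample_fields(case, prof, oracle, seed = seed, n_samples = n_samples)
    prof <- build_profile(case, fs)
  }
  tibble(
    geometry_id = case$label,
    flow_condition = flow_condition,
    flow_rate = flow_rate,
    flow_source = flow_source,
    profile = list(prof),
    mpd = compute_mpd(prof),
    tpg = compute_tpg(prof),
    peak_wss = max(prof$wss_Pa)
  )
}

#' Build baseline case records for a cohort of geometries
#'
#' @param cases named list of `case_geometry` objects (names become
#'   `geometry_id`).
#' @param config a [cohort_config()] supplying the flow model.
#' @param oracle an [oracle_params()].
#' @param seed integer seed driving flow draws and field sampling.
#' @param measured see [solve_case_record()].
#' @param n_samples field samples per section.
#' @return tibble of baseline case records.
#' @export
build_cohort_records <- function(cases, config = cohort_config(),
                                 oracle = oracle_params(), seed = 1L,
                                 measured = TRUE, n_samples = 64L) {
  stopifnot(length(names(cases)) == length(cases))
  recs <- purrr::imap(cases, function(case, id) {
    fl <- assign_flow(case$params$ava, "modelled", flow_model = config$flow_model,
                      seed = derive_seed(seed, paste0("flow-", id)))
    rec <- solve_case_record(case, fl$flow_rate, "baseline", fl$flow_source,
                             oracle, seed = derive_seed(seed, paste0("fields-", id)),
                             measured = measured, n_samples = n_samples)
    rec$geometry_id <- id
    rec
  })
  dplyr::bind_rows(recs)
}

#' Augment baseline records with +/-25% flow variants
#'
#' Each baseline record gains a 0.75x and a 1.25x flow variant whose
#' profiles are re-solved by the oracle, tripling the record count.
#'
#' @param records baseline case records (all `flow_condition == "baseline"`).
#' @param cases named list of `case_geometry` objects keyed by
#'   `geometry_id`.
#' @inheritParams build_cohort_records
#' @return tibble with 3x the input rows (baseline, minus25, plus25 per
#'   geometry).
#' @export
augment_flows <- function(records, cases, oracle = oracle_params(), seed = 1L,
                          measured = TRUE, n_samples = 64L) {
  if (any(records$flow_condition != "baseline")) {
    abort("augment_flows expects baseline records only")
  }
  if (anyDuplicated(records$geometry_id)) abort("duplicate geometry_ids in records")
  out <- purrr::pmap(
    list(records$geometry_id, records$flow_rate, records$flow_source),
    function(id, q, src) {
      case <- cases[[id]]
      if (is.null(case)) abort(paste("no case geometry for", id))
      variants <- purrr::map2(
        c("minus25", "plus25"), c(0.75, 1.25),
        function(cond, fac) {
          rec <- solve_case_record(case, q * fac, cond, src, oracle,
                                   seed = derive_seed(seed, paste0(cond, "-", id)),
                                   measured = measured, n_samples = n_samples)
          rec$geometry_id <- id
          rec
        }
      )
      dplyr::bind_rows(variants)
    }
  )
  dplyr::bind_rows(records, dplyr::bind_rows(out)) |>
    dplyr::arrange(.data$geometry_id,
                   factor(.data$flow_condition, c("baseline", "minus25", "plus25")))
}

#' Filter records by maximum pressure drop
#'
#' Retains records with `mpd <= threshold` (boundary inclusive: cases are
#' removed for an MPD in excess of the bound), preserving order. The number
#' excluded is attached as attribute `n_excluded`.
#'
#' @param records case-record tibble with an `mpd` column.
#' @param threshold mmHg (default 120).
#' @return the retained records.
#' @export
filter_mpd <- function(records, threshold = 120) {
  if (threshold <= 0) abort("threshold must be positive")
  keep <- records$mpd <= threshold
  out <- records[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Stratified geometry-grouped dataset split
#'
#' Geometries (never individual flow variants) are sorted by their baseline
#' MPD and dealt round-robin into `n_subsets` subsets, with seeded
#' tie-shuffling. This guarantees that every subset covers the whole
#' retained MPD range and that all flow variants of a geometry share a
#' subset, so test data stays fully unseen during training.
#'
#' @param records filtered case records.
#' @param n_subsets number of subsets (default 11: 1 test + 10 CV folds).
#' @param test_index which subset is the test set.
#' @param seed integer seed for tie-shuffling.
#' @return object of class `dataset_split`: tibble (`geometry_id`,
#'   `subset`) with attributes `test_index` and `n_subsets`.
#' @export
split_datasets <- function(records, n_subsets = 11L, test_index = n_subsets,
                           seed = 1L) {
  if (n_subsets < 2) abort("need at least two subsets")
  if (test_index < 1 || test_index > n_subsets) abort("test_index out of range")
  per_geom <- records |>
    dplyr::group_by(.data$geometry_id) |>
    dplyr::summarise(
      mpd_key = if (any(.data$flow_condition == "baseline"))
        .data$mpd[.data$flow_condition == "baseline"][1]
      else median(.data$mpd),
      .groups = "drop"
    )
  if (nrow(per_geom) < n_subsets) abort("fewer geometries than subsets")
  ord <- with_seed(seed, order(per_geom$mpd_key, runif(nrow(per_geom))))
  per_geom <- per_geom[ord, ]
  per_geom$subset <- rep_len(seq_len(n_subsets), nrow(per_geom))
  out <- per_geom[, c("geometry_id", "subset")]
  attr(out, "test_index") <- as.integer(test_index)
  attr(out, "n_subsets") <- as.integer(n_subsets)
  class(out) <- c("dataset_split", class(out))
  out
}

#' Pose-normalize centerline coordinates
#'
#' Translates the inlet to the origin, aligns the initial tangent with +z
#' and rotates about z so the curve centroid lies in the x-z half-plane
#' (x > 0). Gives synthetic cases a canonical pose.
#'
#' @param centerline tibble with columns x, y, z.
#' @return n x 3 matrix of normalized coordinates, mm.
#' @export
pose_normalize <- function(centerline) {
  P <- as.matrix(centerline[, c("x", "y", "z")])
  P <- sweep(P, 2, P[1, ])
  t1 <- P[2, ] - P[1, ]
  R1 <- rotation_between(t1, c(0, 0, 1))
  P <- P %*% t(R1)
  centroid <- colMeans(P)
  phi <- atan2(centroid[2], centroid[1])
  if (is.finite(phi) && (abs(centroid[1]) > 1e-9 || abs(centroid[2]) > 1e-9)) {
    Rz <- matrix(c(cos(-phi), -sin(-phi), 0, sin(-phi), cos(-phi), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    P <- P %*% t(Rz)
  }
  P
}

#' Shape codes for every cross-section of a case
#'
#' Rasterizes each cross-section boundary and encodes it with a trained
#' shape autoencoder. Codes depend only on geometry, so they are computed
#' once per geometry and shared across flow variants.
#'
#' @param case a `case_geometry`.
#' @param ae a trained [train_autoencoder()] model.
#' @param window_mm raster window, mm.
#' @return n x m matrix of shape codes.
#' @export
shape_code_matrix <- function(case, ae, window_mm = 50) {
  imgs <- t(vapply(case$sections, function(sec) {
    as.numeric(rasterize_section(sec, grid_size = ae$grid_size, window_mm = window_mm))
  }, numeric(ae$grid_size^2)))
  encode(ae, imgs)
}

#' Build the per-point input feature sequence for one record
#'
#' Rows are `[x, y, z, area, Q/A, code_1..code_m]`: pose-normalized
#' centerline coordinates (mm), cross-section area (mm^2), area-normalized
#' flow rate (m/s; ml/s over mm^2), and the m-dimensional encoded
#' cross-section shape.
#'
#' @param record one case-record row (needs `flow_rate`).
#' @param case the matching `case_geometry`.
#' @param ae trained shape autoencoder (or a precomputed code matrix via
#'   `codes`).
#' @param codes optional precomputed n x m shape-code matrix.
#' @param window_mm raster window, mm.
#' @return n x (5 + m) feature matrix.
#' @export
build_features <- function(record, case, ae = NULL, codes = NULL, window_mm = 50) {
  if (is.null(codes)) {
    if (is.null(ae)) abort("either a trained autoencoder or precomputed codes are required")
    codes <- shape_code_matrix(case, ae, window_mm = window_mm)
  }
  P <- pose_normalize(case$centerline)
  area <- case$centerline$area
  qa <- record$flow_rate / area    # (ml/s) / mm^2 = m/s
  X <- cbind(P, area, qa, codes)
  colnames(X) <- c("x", "y", "z", "area", "qa", paste0("code", seq_len(ncol(codes))))
  X
}

#' Build feature/target sequences for a set of records
#'
#' @param records case-record tibble (profiles as list column).
#' @param cases named list of geometries keyed by `geometry_id`.
#' @param ae trained shape autoencoder.
#' @param window_mm raster window, mm.
#' @return the records with list columns `features` (n x (5+m) matrices)
#'   and `targets` (n x 2 matrices: pressure mmHg, WSS Pa).
#' @export
build_feature_set <- function(records, cases, ae, window_mm = 50) {
  ids <- unique(records$geometry_id)
  code_cache <- lapply(ids, function(id) shape_code_matrix(cases[[id]], ae, window_mm))
  names(code_cache) <- ids
  records$features <- purrr::pmap(
    list(records$geometry_id, records$flow_rate),
    function(id, q) {
      build_features(list(flow_rate = q), cases[[id]], codes = code_cache[[id]])
    }
  )
  records$targets <- purrr::map(records$profile, function(p) {
    cbind(pressure = p$pressure_mmHg, wss = p$wss_Pa)
  })
  records
}

#' Fit / apply per-feature standardization
#'
#' `feature_stats()` fits per-column mean and SD over the stacked rows of a
#' list of sequence matrices (training subsets only); zero-variance columns
#' get unit scale with a warning (raw SDs are kept for perturbation
#' analysis). `scale_seqs()` and `unscale_seqs()` apply and invert the
#' transform.
#'
#' @param seqs list of numeric matrices with identical column counts.
#' @param stats result of `feature_stats()`.
#' @return `feature_stats()`: list with `mean`, `sd` (guarded), `sd_raw`.
#' @export
feature_stats <- function(seqs) {
  X <- do.call(rbind, seqs)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sd_raw <- sdev
  if (any(sdev < 1e-12)) {
    warn("zero-variance feature column(s); leaving them unscaled")
    sdev[sdev < 1e-12] <- 1
  }
  list(mean = mu, sd = sdev, sd_raw = sd_raw)
}

#' @rdname feature_stats
#' @export
scale_seqs <- function(seqs, stats) {
  lapply(seqs, function(X) sweep(sweep(X, 2, stats$mean), 2, stats$sd, "/"))
}

#' @rdname feature_stats
#' @export
unscale_seqs <- function(seqs, stats) {
  lapply(seqs, function(X) sweep(sweep(X, 2, stats$sd, "*"), 2, stats$mean, "+"))
}
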