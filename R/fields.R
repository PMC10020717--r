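#' Sample synthetic per-section field values
#'
#' Emulates the 3D CFD fields that the centerline representation averages:
#' per-section static-pressure samples whose mean equals the profile value
#' with a spread proportional to the local dynamic pressure, and per-segment
#' wall WSS samples with a von-Mises-shaped circumferential asymmetry
#' downstream of the vena contracta (jet impingement). In the valve region
#' samples lie on the leaflet-bounded orifice boundary only. Deterministic
#' given the seed.
#'
#' @param case a `case_geometry`.
#' @param profile the matching oracle `hemodynamic_profile`.
#' @param params an [oracle_params()]; `sample_noise_frac` scales the spread.
#' @param seed integer seed.
#' @param n_samples samples per section/segment (at least 8).
#' @return object of class `field_samples`: list with tibbles `pressure`
#'   (`section`, `x`, `y`, `z`, `value_mmHg`) and `wss`
#'   (`segment`, `angle`, `value_pa`), plus the seed; attribute `flow_rate`.
#' @export
sample_fields <- function(case, profile, params = oracle_params(), seed = 1L,
                          n_samples = 64L) {
  n <- nrow(case$centerline)
  if (nrow(profile) != n) abort("profile length does not match case centerline")
  if (n_samples < 8L) abort("need at least 8 samples per section")
  kin <- oracle_kinematics(case, attr(profile, "flow_rate") %||% 300, params)
  q_dyn_mmhg <- pa_to_mmhg(0.5 * params$rho * kin$v^2)

  s_vc <- NA_real_
  l_rec <- params$recovery_length * 1e-3
  if (any(kin$valve)) {
    iv <- which(kin$valve)
    s_vc <- kin$s[iv[which.min(case$centerline$area[iv])]]
  }

  with_seed(seed, {
    # pressure: random interior points of each section
    m <- n * n_samples
    sec_idx <- rep(seq_len(n), each = n_samples)
    u_r <- sqrt(runif(m))
    u_t <- runif(m, 0, 2 * pi)
    noise <- rnorm(m)
    r_scale <- sqrt(case$centerline$area[sec_idx] / pi)
    p_val <- profile$pressure_mmHg[sec_idx] +
      params$sample_noise_frac * q_dyn_mmhg[sec_idx] * noise
    origin <- do.call(rbind, lapply(case$sections, `[[`, "origin"))
    e1 <- do.call(rbind, lapply(case$sections, `[[`, "e1"))
    e2 <- do.call(rbind, lapply(case$sections, `[[`, "e2"))
    px <- origin[sec_idx, 1] + u_r * r_scale * (cos(u_t) * e1[sec_idx, 1] + sin(u_t) * e2[sec_idx, 1])
    py <- origin[sec_idx, 2] + u_r * r_scale * (cos(u_t) * e1[sec_idx, 2] + sin(u_t) * e2[sec_idx, 2])
    pz <- origin[sec_idx, 3] + u_r * r_scale * (cos(u_t) * e1[sec_idx, 3] + sin(u_t) * e2[sec_idx, 3])
    pressure <- tibble(section = sec_idx, x = px, y = py, z = pz, value_mmHg = p_val)

    # WSS: equally spaced circumferential wall samples per segment, with a
    # jet-impingement asymmetry downstream of the vena contracta whose
    # sample mean is exactly the profile value at zero noise
    nseg <- n - 1L
    seg_idx <- rep(seq_len(nseg), each = n_samples)
    ang <- rep(seq(0, 2 * pi, length.out = n_samples + 1L)[-(n_samples + 1L)], times = nseg)
    kappa <- rep(0, nseg)
    if (is.finite(s_vc)) {
      downstream <- kin$s[seq_len(nseg)] >= s_vc & !kin$valve[seq_len(nseg)]
      kappa[downstream] <- 2 * exp(-(kin$s[seq_len(nseg)][downstream] - s_vc) / l_rec)
    }
    w_raw <- exp(kappa[seg_idx] * cos(ang))
    # normalize per segment so the circumferential mean is exactly 1
    w_norm <- w_raw / stats::ave(w_raw, seg_idx, FUN = mean)
    w_noise <- rnorm(length(seg_idx))
    w_val <- abs(profile$wss_Pa[seg_idx] * w_norm +
                   params$sample_noise_frac * profile$wss_Pa[seg_idx] * w_noise)
    wss <- tibble(segment = seg_idx, angle = ang, value_pa = w_val)
  })

  out <- list(pressure = pressure, wss = wss, seed = as.integer(seed))
  attr(out, "flow_rate") <- attr(profile, "flow_rate")
  class(out) <- "field_samples"
  out
}

#' @export
print.field_samples <- function(x, ...) {
  cat("<field_samples>", dplyr::n_distinct(x$pressure$section), "sections,",
      dplyr::n_distinct(x$wss$segment), "segments, seed", x$seed, "\n")
  invisible(x)
}
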