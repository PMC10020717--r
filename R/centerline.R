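#' Resample a 3D curve at fixed arc-length spacing
#'
#' Places points at arc lengths 0, spacing, 2*spacing, ... along a finely
#' sampled polyline, giving `floor(L / spacing) + 1` points. The discrete
#' aortic centerline uses 2 mm point spacing.
#'
#' @param curve matrix or data frame with three columns (x, y, z) giving an
#'   ordered, finely sampled path in mm.
#' @param spacing arc-length step in mm.
#' @return tibble of class `centerline` with columns `x`, `y`, `z`, `s`
#'   (arc length, mm); attribute `spacing`.
#' @export
#' @examples
#' curve <- cbind(seq(0, 240, by = 0.5), 0, 0)
#' nrow(resample_centerline(curve, 2)) # 121
resample_centerline <- function(curve, spacing = 2) {
  pts <- as.matrix(as.data.frame(curve)[, 1:3])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 2) abort("curve must contain at least two points")
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 1e-12)
  pts <- pts[keep, , drop = FALSE]
  seg <- seg[seg > 1e-12]
  s_cum <- c(0, cumsum(seg))
  L <- s_cum[length(s_cum)]
  if (L < 2 * spacing) abort("curve shorter than twice the requested spacing")
  s_new <- seq(0, by = spacing, length.out = floor(L / spacing) + 1L)
  out <- tibble(
    x = approx(s_cum, pts[, 1], xout = s_new)$y,
    y = approx(s_cum, pts[, 2], xout = s_new)$y,
    z = approx(s_cum, pts[, 3], xout = s_new)$y,
    s = s_new
  )
  attr(out, "spacing") <- spacing
  class(out) <- c("centerline", class(out))
  out
}

#' Centerline-orthogonal section planes
#'
#' One plane per centerline point. Normals are local tangents (central
#' differences, one-sided at the ends); in-plane axes follow a
#' rotation-minimizing frame (double-reflection transport), so cross-section
#' orientation varies continuously along the arch without twist flips.
#'
#' @param centerline tibble from [resample_centerline()] (columns x, y, z).
#' @return tibble with per-point unit vectors: normal (`nx`, `ny`, `nz`) and
#'   in-plane axes (`e1x` ... `e2z`).
#' @export
section_planes <- function(centerline) {
  P <- as.matrix(centerline[, c("x", "y", "z")])
  n <- nrow(P)
  if (n < 2) abort("centerline needs at least two points")
  d <- rbind(P[2, ] - P[1, ],
             P[seq(3, length.out = max(0, n - 2)), , drop = FALSE] -
               P[seq(1, length.out = max(0, n - 2)), , drop = FALSE],
             P[n, ] - P[n - 1, ])
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-12)) abort("degenerate tangent: duplicate consecutive points")
  t_ <- d / len

  e1 <- matrix(0, n, 3)
  ref <- if (abs(t_[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * t_[1, ]) * t_[1, ]
  e1[1, ] <- v / sqrt(sum(v^2))
  for (i in seq_len(n - 1)) {
    # double-reflection rotation-minimizing frame transport
    v1 <- P[i + 1, ] - P[i, ]
    c1 <- sum(v1 * v1)
    rL <- e1[i, ] - (2 / c1) * sum(v1 * e1[i, ]) * v1
    tL <- t_[i, ] - (2 / c1) * sum(v1 * t_[i, ]) * v1
    v2 <- t_[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    e_next <- if (c2 < 1e-14) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthogonalize against the tangent
    e_next <- e_next - sum(e_next * t_[i + 1, ]) * t_[i + 1, ]
    e1[i + 1, ] <- e_next / sqrt(sum(e_next^2))
  }
  e2 <- cbind(t_[, 2] * e1[, 3] - t_[, 3] * e1[, 2],
              t_[, 3] * e1[, 1] - t_[, 1] * e1[, 3],
              t_[, 1] * e1[, 2] - t_[, 2] * e1[, 1])
  tibble(nx = t_[, 1], ny = t_[, 2], nz = t_[, 3],
         e1x = e1[, 1], e1y = e1[, 2], e1z = e1[, 3],
         e2x = e2[, 1], e2y = e2[, 2], e2z = e2[, 3])
}

#' Average pressure samples on one cross-section
#'
#' Arithmetic mean of the static-pressure samples on the section plane. In
#' the valve region only orifice-interior samples are generated, so the rule
#' that only the leaflet-bounded area contributes is honoured by
#' construction.
#'
#' @param samples a `field_samples` object from [sample_fields()].
#' @param section_index 1-based centerline point index.
#' @return scalar mean pressure, mmHg.
#' @export
average_pressure <- function(samples, section_index) {
  vals <- samples$pressure$value_mmHg[samples$pressure$section == section_index]
  if (length(vals) == 0) abort(paste("no pressure samples for section", section_index))
  mean(vals)
}

#' Average wall-shear-stress samples on one vessel segment
#'
#' WSS is averaged over the vessel segment between two adjacent
#' cross-sections (not on the section planes); magnitudes are used, so the
#' result is non-negative.
#'
#' @param samples a `field_samples` object.
#' @param segment_index 1-based segment index (segment i spans sections i and
#'   i + 1).
#' @return scalar mean WSS, Pa.
#' @export
average_wss <- function(samples, segment_index) {
  vals <- samples$wss$value_pa[samples$wss$segment == segment_index]
  if (length(vals) == 0) abort(paste("no WSS samples for segment", segment_index))
  mean(abs(vals))
}

#' Assemble a centerline profile from field samples
#'
#' Averages pressure per cross-section and WSS per inter-section segment and
#' assembles the compact centerline-based representation. The WSS of segment
#' (i, i+1) is assigned to point i; the last point repeats the last segment,
#' keeping input and output sequences the same length.
#'
#' @param case a `case_geometry`.
#' @param samples a `field_samples` object matching the case.
#' @return a `hemodynamic_profile` tibble (see [solve_profile()]) with
#'   source `"measured"`.
#' @export
build_profile <- function(case, samples) {
  n <- nrow(case$centerline)
  have_p <- unique(samples$pressure$section)
  have_w <- unique(samples$wss$segment)
  miss_p <- setdiff(seq_len(n), have_p)
  miss_w <- setdiff(seq_len(n - 1L), have_w)
  if (length(miss_p) || length(miss_w)) {
    abort(paste0("missing field samples; sections: [",
                 paste(miss_p, collapse = ","), "] segments: [",
                 paste(miss_w, collapse = ","), "]"))
  }
  p <- vapply(seq_len(n), function(i) average_pressure(samples, i), numeric(1))
  w_seg <- vapply(seq_len(n - 1L), function(i) average_wss(samples, i), numeric(1))
  w <- c(w_seg, w_seg[n - 1L])
  new_profile(case, pressure = p, wss = w,
              flow_rate = attr(samples, "flow_rate"), source = "measured")
}
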