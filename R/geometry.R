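#' Cohort configuration for synthetic geometry sampling
#'
#' Defines the sampling distributions for the parametric aorta + valve
#' generator. The `"default"` preset spans healthy to severely stenosed
#' valves (AVA uniform on 0.4--2.0 cm^2). The `"as_cohort"` preset emulates a
#' TAVI-referral aortic-stenosis cohort: AVA from a truncated normal
#' (0.74 +/- 0.17 cm^2, bounded to 0.4--1.1) and a flow model calibrated so
#' that maximum pressure drops span roughly 0--120 mmHg with a median near
#' 40 mmHg.
#'
#' @param preset `"default"` or `"as_cohort"`.
#' @param ... named overrides for any configuration entry.
#' @return a list of class `cohort_config` with entries:
#'   `ava` (sampling spec), diameter and length ranges in mm,
#'   `segment_frac` (centerline length fractions of LVOT, valve, ascending,
#'   arch, descending), `n_leaflets`, and `flow_model`
#'   (`intercept`/`slope` in ml/s per cm^2, `sd_frac`, `trunc`).
#' @export
#' @examples
#' cfg <- cohort_config()
#' cfg$ava$range
cohort_config <- function(preset = c("default", "as_cohort"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    ava = list(dist = "uniform", range = c(0.4, 2.0)),
    lvot_diameter_range = c(20, 26),
    ascending_diameter_range = c(26, 34),
    descending_diameter_range = c(20, 26),
    total_length_range = c(220, 258),
    segment_frac = c(lvot = 0.10, valve = 0.05, ascending = 0.30,
                     arch = 0.25, descending = 0.30),
    n_leaflets = 3L,
    ellipticity_max = 0.12,
    flow_model = list(intercept = 150, slope = 250, sd_frac = 0.15,
                      trunc = c(100, 700))
  )
  if (preset == "as_cohort") {
    cfg$ava <- list(dist = "truncnorm", mean = 0.74, sd = 0.17,
                    range = c(0.4, 1.1))
    cfg$flow_model <- list(intercept = 110, slope = 140, sd_frac = 0.18,
                           trunc = c(80, 600))
  }
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  rng_ok <- function(r) length(r) == 2 && is.finite(r[1]) && is.finite(r[2]) && r[1] <= r[2]
  for (nm in c("lvot_diameter_range", "ascending_diameter_range",
               "descending_diameter_range", "total_length_range")) {
    if (!rng_ok(cfg[[nm]])) abort(paste0("invalid range in cohort config: ", nm))
  }
  if (!rng_ok(cfg$ava$range)) abort("invalid range in cohort config: ava")
  if (cfg$ava$range[1] < 0.3 || cfg$ava$range[2] > 2.5) {
    abort("AVA sampling range must lie within [0.3, 2.5] cm^2")
  }
  if (cfg$n_leaflets < 2) abort("n_leaflets must be >= 2")
  if (abs(sum(cfg$segment_frac) - 1) > 1e-8) abort("segment fractions must sum to 1")
  invisible(cfg)
}

#' Sample parameters for one synthetic aorta + valve geometry
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; identical seeds give identical draws.
#' @return a one-row tibble of class `geometry_params` with columns
#'   `ava` (cm^2), `lvot_diameter`, `ascending_diameter`,
#'   `descending_diameter`, `arch_radius`, `total_length` (all mm),
#'   `n_leaflets` and `seed`.
#' @export
#' @examples
#' sample_geometry_params(cohort_config(), seed = 1)
sample_geometry_params <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  with_seed(seed, {
    ava <- if (config$ava$dist == "uniform") {
      runif(1, config$ava$range[1], config$ava$range[2])
    } else {
      rtruncnorm(1, config$ava$mean, config$ava$sd,
                 config$ava$range[1], config$ava$range[2])
    }
    total_length <- runif(1, config$total_length_range[1], config$total_length_range[2])
    # arch curvature radius defaults to the value matching the arch length
    # fraction (a ~180 degree arch), jittered mildly
    arch_radius <- config$segment_frac[["arch"]] * total_length / pi * runif(1, 0.97, 1.03)
    out <- tibble(
      ava = ava,
      lvot_diameter = runif(1, config$lvot_diameter_range[1], config$lvot_diameter_range[2]),
      ascending_diameter = runif(1, config$ascending_diameter_range[1],
                                 config$ascending_diameter_range[2]),
      descending_diameter = runif(1, config$descending_diameter_range[1],
                                  config$descending_diameter_range[2]),
      arch_radius = arch_radius,
      total_length = total_length,
      n_leaflets = as.integer(config$n_leaflets),
      seed = as.integer(seed)
    )
    class(out) <- c("geometry_params", class(out))
    out
  })
}

#' Sample a cohort of geometry parameter sets
#'
#' @param n number of geometries.
#' @inheritParams sample_geometry_params
#' @return tibble with `n` rows (one [sample_geometry_params()] row each) and
#'   a `geometry_id` column.
#' @export
sample_cohort_params <- function(n, config = cohort_config(), seed = 1L) {
  rows <- purrr::map(seq_len(n), function(i) {
    sample_geometry_params(config, seed = derive_seed(seed, "geometry", i))
  })
  out <- dplyr::bind_rows(rows)
  out$geometry_id <- sprintf("G%03d", seq_len(n))
  out
}

validate_geometry_params <- function(params) {
  stopifnot(is.data.frame(params), nrow(params) == 1)
  need <- c("ava", "lvot_diameter", "ascending_diameter", "descending_diameter",
            "arch_radius", "total_length", "n_leaflets", "seed")
  missing <- setdiff(need, names(params))
  if (length(missing)) abort(paste("geometry params missing:", paste(missing, collapse = ", ")))
  if (params$ava < 0.3 || params$ava > 2.5) abort("ava outside [0.3, 2.5] cm^2")
  if (any(c(params$lvot_diameter, params$ascending_diameter,
            params$descending_diameter, params$arch_radius) <= 0)) {
    abort("all diameters and radii must be positive")
  }
  if (params$n_leaflets < 2) abort("n_leaflets must be >= 2")
  invisible(params)
}

#' Cross-section boundary polygons
#'
#' `tristar_boundary()` builds the leaflet-bounded orifice boundary: an
#' n-fold symmetric lobed polygon scaled exactly to a target area, emulating
#' the star-like fully open stenotic orifice. `ellipse_boundary()` builds a
#' mildly elliptic vessel-wall boundary of exact area.
#'
#' @param area_mm2 target polygon area, mm^2.
#' @param n_leaflets number of leaflets (lobes).
#' @param depth lobe depth (0 = circle).
#' @param n_vertices polygon vertices.
#' @param ellipticity axis-ratio parameter (0 = circle).
#' @param phase in-plane rotation of the major axis, radians.
#' @return an `n_vertices` x 2 matrix of in-plane coordinates, mm.
#' @export
tristar_boundary <- function(area_mm2, n_leaflets = 3L, depth = 0.4, n_vertices = 64L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- 1 + depth * cos(n_leaflets * theta)
  xy <- cbind(r * cos(theta), r * sin(theta))
  xy * sqrt(area_mm2 / polygon_area(xy))
}

#' @rdname tristar_boundary
#' @export
ellipse_boundary <- function(area_mm2, ellipticity = 0, phase = 0, n_vertices = 64L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  # semi-axes a, b with a/b = (1+e)^2 and pi*a*b = area
  r0 <- sqrt(area_mm2 / pi)
  a <- r0 * (1 + ellipticity)
  b <- r0 / (1 + ellipticity)
  xy <- cbind(a * cos(theta + phase), b * sin(theta + phase))
  xy * sqrt(area_mm2 / polygon_area(xy))
}

#' Build a synthetic aorta + valve case geometry
#'
#' Constructs a candy-cane shaped centerline (straight LVOT/valve/ascending
#' limb, ~180 degree arch, straight descending limb), resamples it at 2 mm
#' arc-length spacing, and attaches one cross-section per centerline point.
#' Cross-section area interpolates smoothly between segment diameters and
#' dips to the valve orifice area (`ava`, converted to mm^2) inside the valve
#' region, where the boundary is a leaflet-bounded star-shaped orifice
#' polygon instead of the vessel wall.
#'
#' @param params one-row tibble from [sample_geometry_params()].
#' @param spacing centerline point spacing in mm (default 2).
#' @param n_vertices polygon vertices per cross-section boundary.
#' @return an object of class `case_geometry`: list with `centerline`
#'   (tibble: x, y, z, s, region, area), `sections` (list of cross-sections,
#'   each with `origin`, `normal`, `e1`, `e2`, `boundary2d`, `boundary3d`,
#'   `area`, `region`), `params` and `label`.
#' @export
#' @examples
#' case <- build_case(sample_geometry_params(seed = 7))
#' nrow(case$centerline)
build_case <- function(params, spacing = 2, n_vertices = 64L) {
  validate_geometry_params(params)
  L <- params$total_length
  frac <- c(lvot = 0.10, valve = 0.05, ascending = 0.30, arch = 0.25, descending = 0.30)
  R <- params$arch_radius
  arch_len <- pi * R
  l_lvot <- frac[["lvot"]] * L
  l_valve <- frac[["valve"]] * L
  l_asc <- frac[["ascending"]] * L
  l_desc <- L - l_lvot - l_valve - l_asc - arch_len
  if (l_desc <= 0.05 * L) abort("arch radius too large for total length (no descending limb)")
  # self-intersection guard: arch curvature radius must exceed lumen radius
  max_lumen_r <- max(params$ascending_diameter, params$descending_diameter) / 2
  if (R <= max_lumen_r) abort("geometry error: arch radius smaller than lumen radius (self-intersecting lumen)")

  # per-case shape randomness (out-of-plane arch deviation, diameter
  # jitter, ellipticity), all driven by one seed
  with_seed(derive_seed(params$seed, "jitter"), {
    ph <- runif(3, 0, 2 * pi)
    amp <- runif(1, 0, 0.02)
    ellip <- runif(1, 0, 0.12)
    ellip_phase <- ph[3]
    arch_dev <- runif(1, 2, 5)   # mm, out-of-plane bow of the arch
  })

  limb1 <- l_lvot + l_valve + l_asc
  curve_point <- function(s) {
    # candy cane, nominally in the x-z plane with a mild out-of-plane bow
    y_dev <- if (s > limb1 && s < limb1 + arch_len) {
      arch_dev * sin(pi * (s - limb1) / arch_len)
    } else 0
    if (s <= limb1) return(c(0, 0, s))
    if (s <= limb1 + arch_len) {
      th <- pi - (s - limb1) / R
      return(c(R + R * cos(th), y_dev, limb1 + R * sin(th)))
    }
    c(2 * R, 0, limb1 - (s - limb1 - arch_len))
  }
  fine_s <- seq(0, L, by = 0.25)
  fine <- t(vapply(fine_s, curve_point, numeric(3)))
  cl <- resample_centerline(fine, spacing = spacing)
  s <- cl$s
  bounds <- cumsum(c(l_lvot, l_valve, l_asc, arch_len, l_desc))
  region <- cut(s, breaks = c(-Inf, bounds[1:4], Inf),
                labels = c("LVOT", "valve", "ascending", "arch", "descending"))
  region <- as.character(region)

  # area profile: monotone-cubic interpolation through segment knots, with the
  # valve orifice minimum pinned exactly to ava (1 cm^2 = 100 mm^2)
  a_lvot <- pi * (params$lvot_diameter / 2)^2
  a_asc <- pi * (params$ascending_diameter / 2)^2
  a_desc <- pi * (params$descending_diameter / 2)^2
  a_vmin <- params$ava * 100
  s_v0 <- bounds[1]; s_v1 <- bounds[2]
  # snap the orifice minimum to the sampling grid so the minimum valve-region
  # section area equals ava exactly
  s_vmid <- round((s_v0 + s_v1) / 2 / spacing) * spacing
  knots_s <- c(0, s_v0, s_vmid, s_v1, s_v1 + 0.5 * l_asc, bounds[3],
               bounds[4], L)
  knots_a <- c(a_lvot, a_lvot, a_vmin, 0.9 * a_asc, a_asc, a_asc, a_desc, a_desc)
  afun <- splinefun(knots_s, knots_a, method = "monoH.FC")
  area <- afun(s)
  area[region == "valve" & abs(s - s_vmid) < spacing / 2] <- a_vmin

  # mild, smooth diameter jitter outside the valve
  jitter <- 1 + amp * (sin(2 * pi * s / L + ph[1]) + 0.5 * sin(4 * pi * s / L + ph[2]))
  nonvalve <- region != "valve"
  area[nonvalve] <- area[nonvalve] * jitter[nonvalve]^2

  planes <- section_planes(cl)
  sections <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    if (region[i] == "valve") {
      b2 <- tristar_boundary(area[i], params$n_leaflets, n_vertices = n_vertices)
    } else {
      b2 <- ellipse_boundary(area[i], ellipticity = ellip, phase = ellip_phase,
                             n_vertices = n_vertices)
    }
    origin <- c(cl$x[i], cl$y[i], cl$z[i])
    e1 <- c(planes$e1x[i], planes$e1y[i], planes$e1z[i])
    e2 <- c(planes$e2x[i], planes$e2y[i], planes$e2z[i])
    b3 <- sweep(b2[, 1, drop = FALSE] %*% rbind(e1) + b2[, 2, drop = FALSE] %*% rbind(e2),
                2, origin, "+")
    sections[[i]] <- list(
      origin = origin,
      normal = c(planes$nx[i], planes$ny[i], planes$nz[i]),
      e1 = e1, e2 = e2,
      boundary2d = b2, boundary3d = b3,
      area = area[i], region = region[i], index = i
    )
  }
  cl$region <- region
  cl$area <- area
  structure(
    list(label = sprintf("case-seed%d", params$seed), params = params,
         centerline = cl, sections = sections, spacing = spacing),
    class = "case_geometry"
  )
}

#' @export
print.case_geometry <- function(x, ...) {
  cat("<case_geometry>", x$label, "\n")
  cat("  points:", nrow(x$centerline), " spacing:", x$spacing, "mm\n")
  cat("  AVA:", round(x$params$ava, 3), "cm^2  length:",
      round(x$params$total_length, 1), "mm\n")
  counts <- table(x$centerline$region)
  cat("  regions:", paste(names(counts), counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# Minimal straight-tube geometry used for degenerate-case physics checks.
#' Straight-tube degenerate geometry
#'
#' A uniform straight cylinder with no valve region; useful for analytic
#' checks (no constriction means no transvalvular gradient).
#'
#' @param radius lumen radius, mm.
#' @param length tube length, mm.
#' @param spacing centerline spacing, mm.
#' @param n_vertices boundary polygon vertices.
#' @return a `case_geometry` whose points are all labelled `descending`.
#' @export
synthetic_tube <- function(radius = 12, length = 240, spacing = 2, n_vertices = 64L) {
  fine <- cbind(0, 0, seq(0, length, by = 0.25))
  cl <- resample_centerline(fine, spacing = spacing)
  planes <- section_planes(cl)
  area <- pi * radius^2
  sections <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    b2 <- ellipse_boundary(area, n_vertices = n_vertices)
    origin <- c(cl$x[i], cl$y[i], cl$z[i])
    e1 <- c(planes$e1x[i], planes$e1y[i], planes$e1z[i])
    e2 <- c(planes$e2x[i], planes$e2y[i], planes$e2z[i])
    b3 <- sweep(b2[, 1, drop = FALSE] %*% rbind(e1) + b2[, 2, drop = FALSE] %*% rbind(e2),
                2, origin, "+")
    sections[[i]] <- list(origin = origin,
                          normal = c(planes$nx[i], planes$ny[i], planes$nz[i]),
                          e1 = e1, e2 = e2, boundary2d = b2, boundary3d = b3,
                          area = area, region = "descending", index = i)
  }
  cl$region <- "descending"
  cl$area <- area
  params <- tibble(ava = min(2.5, area / 100), lvot_diameter = 2 * radius,
                   ascending_diameter = 2 * radius, descending_diameter = 2 * radius,
                   arch_radius = 1e6, total_length = length, n_leaflets = 3L, seed = 0L)
  structure(list(label = "tube", params = params, centerline = cl,
                 sections = sections, spacing = spacing),
            class = "case_geometry")
}
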