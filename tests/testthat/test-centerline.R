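test_that("resampling places points at fixed arc-length spacing", {
  curve <- cbind(seq(0, 240, by = 0.1), 0, 0)
  cl <- resample_centerline(curve, spacing = 2)
  expect_equal(nrow(cl), 121)           # floor(240/2) + 1
  expect_equal(diff(cl$s), rep(2, 120))
  expect_equal(cl$x, seq(0, 240, by = 2))

  short <- resample_centerline(cbind(seq(0, 4, by = 0.5), 0, 0), 2)
  expect_equal(nrow(short), 3)
  expect_lt(max(abs(short$y)), 1e-12)

  expect_error(resample_centerline(cbind(c(0, 1), 0, 0), 2), "shorter")
})

test_that("resampled arc length matches curve length and chords stay near spacing", {
  case <- fx_case()
  cl <- case$centerline
  chords <- sqrt(rowSums((as.matrix(cl[-1, c("x", "y", "z")]) -
                            as.matrix(cl[-nrow(cl), c("x", "y", "z")]))^2))
  expect_equal(diff(cl$s), rep(2, nrow(cl) - 1), tolerance = 1e-9)
  expect_true(all(abs(chords - 2) < 0.01))   # chord vs arc on the arch
  expect_lt(abs(sum(chords) - max(cl$s)), 2)
})

test_that("section planes use tangent normals and a twist-free frame", {
  # straight tube: all normals equal the axis
  cl <- resample_centerline(cbind(0, 0, seq(0, 100, by = 0.5)), 2)
  pl <- section_planes(cl)
  expect_equal(nrow(pl), nrow(cl))
  expect_true(all(abs(pl$nz - 1) < 1e-12))

  # planar arc: normals tangent to the circle, frame rotates continuously
  th <- seq(0, pi, length.out = 2000)
  arc <- cbind(50 * cos(th), 50 * sin(th), 0)
  cla <- resample_centerline(arc, 2)
  pla <- section_planes(cla)
  tangents <- as.matrix(pla[, c("nx", "ny", "nz")])
  # analytic tangent at the resampled angles
  th_i <- cla$s / 50
  interior <- 2:(nrow(cla) - 1)   # endpoints use one-sided differences
  expect_lt(max(abs(tangents[interior, 1] + sin(th_i[interior]))), 0.01)
  expect_lt(max(abs(tangents[interior, 2] - cos(th_i[interior]))), 0.01)
  e1 <- as.matrix(pla[, c("e1x", "e1y", "e1z")])
  dots <- rowSums(e1[-1, ] * e1[-nrow(e1), ])
  expect_true(all(dots > 0.99))

  dup <- tibble::tibble(x = c(0, 0, 1), y = 0, z = 0)
  expect_error(section_planes(dup), "degenerate")
})

test_that("averaging is the arithmetic mean and respects the valve rule", {
  s <- fx_samples()
  expect_equal(average_pressure(list(pressure = tibble::tibble(
    section = 1L, value_mmHg = c(100, 110, 120))), 1), 110)
  expect_equal(average_wss(list(wss = tibble::tibble(
    segment = 2L, value_pa = c(12, 12, 12))), 2), 12)
  # magnitudes: mean of mixed-sign samples is positive
  expect_gt(average_wss(list(wss = tibble::tibble(
    segment = 1L, value_pa = c(-3, 3))), 1), 0)
  expect_error(average_pressure(s, 10000), "no pressure samples")

  # valve-region samples lie on the orifice boundary only: every wall sample
  # of a valve segment comes from the star polygon (checked via case areas)
  case <- fx_case()
  valve_secs <- which(case$centerline$region == "valve")
  p_valve <- s$pressure[s$pressure$section == valve_secs[2], ]
  org <- case$sections[[valve_secs[2]]]$origin
  r <- sqrt((p_valve$x - org[1])^2 + (p_valve$y - org[2])^2 + (p_valve$z - org[3])^2)
  expect_true(all(r <= sqrt(case$sections[[valve_secs[2]]]$area / pi) + 1e-9))
})

test_that("zero-noise samples rebuild the oracle profile exactly", {
  case <- fx_case()
  prof <- fx_profile()
  fs0 <- sample_fields(case, prof, oracle_params(sample_noise_frac = 0), seed = 1L)
  rebuilt <- build_profile(case, fs0)
  n <- nrow(case$centerline)
  expect_equal(rebuilt$pressure_mmHg, prof$pressure_mmHg, tolerance = 1e-12)
  # segment i maps to point i; the last point repeats the last segment
  expect_equal(rebuilt$wss_Pa[-n], prof$wss_Pa[-n], tolerance = 1e-12)
  expect_equal(rebuilt$wss_Pa[n], rebuilt$wss_Pa[n - 1])
  expect_equal(nrow(rebuilt), n)
})

test_that("noisy sampled averages recover the oracle within Monte-Carlo bounds", {
  case <- fx_case()
  prof <- fx_profile()
  fs <- fx_samples()
  rebuilt <- build_profile(case, fs)
  # per-section 3-standard-error bound (64 samples)
  kin_q <- abs(fs$pressure$value_mmHg - prof$pressure_mmHg[fs$pressure$section])
  for (i in c(1L, 60L, nrow(case$centerline))) {
    vals <- fs$pressure$value_mmHg[fs$pressure$section == i]
    se <- stats::sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - prof$pressure_mmHg[i]), max(3 * se, 1e-9))
  }
  expect_lt(max(abs(rebuilt$pressure_mmHg - prof$pressure_mmHg)), 1)

  # determinism
  fs2 <- sample_fields(case, prof, oracle_params(), seed = 5L)
  expect_identical(fs$pressure, fs2$pressure)
  expect_identical(fs$wss, fs2$wss)
})

test_that("missing sections are reported by index", {
  case <- fx_case()
  fs <- sample_fields(case, fx_profile(), oracle_params(), seed = 2L)
  fs$pressure <- fs$pressure[fs$pressure$section != 12L, ]
  expect_error(build_profile(case, fs), "12")
})

test_that("rasterization matches analytic occupancy and fixed window", {
  img <- rasterize_section(ellipse_boundary(pi * 100), grid_size = 68, window_mm = 50)
  expect_equal(dim(img), c(68L, 68L))
  expect_equal(mean(img), pi * 100 / 2500, tolerance = 0.08)
  # pixel-count area estimate within 3% for radius >= 5 mm circles
  for (r in c(5, 8, 12)) {
    im <- rasterize_section(ellipse_boundary(pi * r^2), 68, 50)
    est <- sum(im) * (50 / 68)^2
    expect_equal(est, pi * r^2, tolerance = 0.03)
  }
  expect_error(rasterize_section(ellipse_boundary(pi * 26^2), 68, 50), "window")
  expect_error(rasterize_section(matrix(numeric(0), 0, 2), 68, 50), "empty")
})

test_that("rasterization is invariant to the section origin", {
  case <- fx_case()
  sec <- case$sections[[30]]
  moved <- sec
  moved$origin <- sec$origin + c(100, -40, 7)
  expect_identical(rasterize_section(sec), rasterize_section(moved))
})
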