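test_that("parameter sampling is deterministic and respects configured ranges", {
  p1 <- sample_geometry_params(seed = 123L)
  p2 <- sample_geometry_params(seed = 123L)
  expect_identical(p1, p2)

  draws <- vapply(1:1000, function(i) {
    sample_geometry_params(seed = i)$ava
  }, numeric(1))
  expect_true(all(draws >= 0.4 & draws <= 2.0))

  degenerate <- cohort_config(ava = list(dist = "uniform", range = c(0.74, 0.74)))
  expect_equal(sample_geometry_params(degenerate, seed = 9L)$ava, 0.74)
})

test_that("invalid cohort configuration is rejected", {
  expect_error(cohort_config(total_length_range = c(260, 220)), "range")
  expect_error(cohort_config(ava = list(dist = "uniform", range = c(1.5, 0.5))), "range")
  expect_error(cohort_config(n_leaflets = 1), "leaflets")
})

test_that("built cases have 110-130 points, ordered regions, and smooth areas", {
  for (s in c(1L, 10L, 23L)) {
    case <- build_case(sample_geometry_params(seed = s))
    n <- nrow(case$centerline)
    expect_gte(n, 110)
    expect_lte(n, 130)
    # region order along the centerline
    runs <- rle(case$centerline$region)$values
    expect_identical(runs, c("LVOT", "valve", "ascending", "arch", "descending"))
    # valve-region minimum section area equals AVA in mm^2 within 1%
    valve_area <- min(case$centerline$area[case$centerline$region == "valve"])
    expect_equal(valve_area, case$params$ava * 100, tolerance = 0.01)
    # area smoothness outside the valve entrance/exit transition
    a <- case$centerline$area
    rel_step <- abs(diff(a)) / a[-length(a)]
    valve_adjacent <- which(case$centerline$region %in% "valve")
    transition <- unique(pmax(1, pmin(n - 1, c(valve_adjacent - 2, valve_adjacent - 1,
                                               valve_adjacent, valve_adjacent + 1))))
    expect_true(all(rel_step[-transition] < 0.35))
  }
})

test_that("cross-section polygons are planar, centered and area-exact", {
  case <- fx_case()
  sec <- case$sections[[60]]
  # boundary lies in the plane through origin with the section normal
  rel <- sweep(sec$boundary3d, 2, sec$origin)
  expect_lt(max(abs(rel %*% sec$normal)), 1e-9)
  expect_equal(polygon_area_test(sec$boundary2d), sec$area, tolerance = 0.005)
  # valve boundary is the leaflet-bounded orifice (lobed, much smaller)
  vsec <- case$sections[[which(case$centerline$region == "valve")[3]]]
  expect_equal(polygon_area_test(vsec$boundary2d), vsec$area, tolerance = 0.005)
  radii <- sqrt(rowSums(vsec$boundary2d^2))
  expect_gt(max(radii) / min(radii), 1.5) # star-like, not circular
})

test_that("geometry build is deterministic and unit conversion holds", {
  cfg <- cohort_config(ava = list(dist = "uniform", range = c(1.0, 1.0)))
  p <- sample_geometry_params(cfg, seed = 3L)
  c1 <- build_case(p)
  c2 <- build_case(p)
  expect_equal(c1$centerline, c2$centerline)
  expect_equal(min(c1$centerline$area[c1$centerline$region == "valve"]),
               100, tolerance = 0.01)
})

test_that("self-intersecting lumen parameters raise a geometry error", {
  p <- sample_geometry_params(seed = 2L)
  p$arch_radius <- p$ascending_diameter / 2 - 1
  expect_error(build_case(p), "self-intersecting")
})

test_that("STL export round-trips and matches analytic cylinder area", {
  tube <- synthetic_tube(radius = 10, length = 200)
  path <- withr::local_tempfile(fileext = ".stl")
  export_surface(tube, path)
  stl <- read_stl(path)
  expect_gt(nrow(stl$vertices), 0)
  # bounding box of the mesh encloses all section boundaries
  all_b <- do.call(rbind, lapply(tube$sections, `[[`, "boundary3d"))
  expect_true(all(apply(stl$vertices, 2, max) >= apply(all_b, 2, max) - 1e-4))
  expect_true(all(apply(stl$vertices, 2, min) <= apply(all_b, 2, min) + 1e-4))
  # lateral surface ~ 2 pi r L; caps add 2 pi r^2
  expected <- 2 * pi * 10 * 200 + 2 * pi * 100
  expect_equal(stl_area_test(stl), expected, tolerance = 0.05)

  # ascii STL parses too
  path2 <- withr::local_tempfile(fileext = ".stl")
  export_surface(tube, path2, format = "ascii")
  stl2 <- read_stl(path2)
  expect_equal(stl2$n_triangles, stl$n_triangles)
})
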