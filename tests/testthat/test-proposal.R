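scale05 <- periportal::pixel_scale(0.5)

make_portal <- function(R_px = 260, bump_theta = numeric(0), bump_w_um = numeric(0),
                        bump_h_um = numeric(0), dim = c(620, 620), scale = scale05) {
  um <- scale$microns_per_pixel
  R_um <- R_px * um
  sigma <- (bump_w_um / 2) / R_um / 2
  m <- polar_mask(dim, dim / 2, R_px, bump_theta, sigma, bump_h_um / um)
  portal_regions(m, scale)[[1]]
}

test_that("a large smooth disk has no protruding points", {
  portal <- make_portal(R_px = 260)    # 130 um radius: chord depth ~2.4 um
  flags <- flag_contour_points(portal, scale05)
  expect_lt(mean(flags), 0.02)
})

test_that("a narrow outward bump is flagged at its apex, far side stays quiet", {
  portal <- make_portal(R_px = 260, bump_theta = 0, bump_w_um = 20, bump_h_um = 30)
  flags <- flag_contour_points(portal, scale05)
  pts <- portal$contour$points
  th <- atan2(-(pts[, 1] - 310), pts[, 2] - 310)
  apex <- abs(th) < 0.05
  farside <- abs(abs(th) - pi) < 0.5
  expect_true(all(flags[apex]))
  expect_lt(mean(flags[farside]), 0.02)
})

test_that("contours shorter than the chord window are entirely non-protruding", {
  m <- disk_mask(c(64, 64), c(32, 32), 12)   # perimeter ~38 um at 0.5 um/px
  portal <- portal_regions(m, scale05, min_area_um2 = 10)[[1]]
  expect_lt(portal$contour$perimeter_um, 50)
  expect_false(any(flag_contour_points(portal, scale05)))
})

test_that("deepening a bump never turns its apex non-protruding", {
  for (h in c(20, 30, 40)) {
    portal <- make_portal(R_px = 260, bump_theta = 0, bump_w_um = 20, bump_h_um = h)
    flags <- flag_contour_points(portal, scale05)
    pts <- portal$contour$points
    th <- atan2(-(pts[, 1] - 310), pts[, 2] - 310)
    expect_true(any(flags[abs(th) < 0.05]), label = sprintf("apex flagged at h=%g", h))
  }
})

test_that("partition tiles the contour between quiet-run midpoints", {
  portal <- make_portal(R_px = 260)
  ctr <- portal$contour
  n <- nrow(ctr$points)
  flags <- rep(FALSE, n)
  flags[100:160] <- TRUE
  flags[round(n / 2) + (0:80)] <- TRUE
  parts <- partition_segments(flags, ctr, portal_id = 1L)
  expect_length(parts$regions, 2)
  expect_length(parts$segments, 2)
  # the two protruding arcs tile the whole contour (each takes half of the
  # flanking quiet runs)
  total <- sum(vapply(parts$regions, `[[`, numeric(1), "contour_length_um"))
  expect_equal(total, ctr$perimeter_um, tolerance = 2 * 0.5 * 2 / ctr$perimeter_um)
  # quiet segments are the full runs
  seg_total <- sum(vapply(parts$segments, `[[`, numeric(1), "length_um"))
  run_total <- ctr$perimeter_um -
    (periportal:::arc_span_um(ctr, 100L, 160L) +
     periportal:::arc_span_um(ctr, round(n / 2), round(n / 2) + 80L))
  expect_equal(seg_total, run_total, tolerance = 0.02)
  # each region contains its protruding run
  covers <- function(r, i) {
    idx <- periportal:::cyclic_indices(r$start_index, r$end_index, n)
    all(i %in% idx)
  }
  expect_true(any(vapply(parts$regions, covers, logical(1), i = 100:160)))
})

test_that("degenerate flag patterns collapse to single region or segment", {
  portal <- make_portal(R_px = 120)
  ctr <- portal$contour
  n <- nrow(ctr$points)
  all_n <- partition_segments(rep(FALSE, n), ctr)
  expect_length(all_n$regions, 0)
  expect_length(all_n$segments, 1)
  expect_equal(all_n$segments[[1]]$length_um, ctr$perimeter_um)
  all_p <- partition_segments(rep(TRUE, n), ctr)
  expect_length(all_p$regions, 1)
  expect_length(all_p$segments, 0)
  expect_equal(all_p$regions[[1]]$contour_length_um, ctr$perimeter_um)
})

test_that("region polygons recover analytic areas and arc lengths", {
  # half-disk: arc = semicircle of a 20 um radius disk, chord = diameter
  m <- disk_mask(c(128, 128), c(64, 64), 40)
  portal <- portal_regions(m, scale05)[[1]]
  ctr <- portal$contour
  i_start <- which.max(ctr$points[, 2])   # theta = 0
  i_end <- which.min(ctr$points[, 2])     # theta = pi
  region <- list(portal_id = 1L, start_index = i_start, end_index = i_end,
                 contour_length_um = periportal:::arc_span_um(ctr, i_start, i_end))
  region <- build_polygon(region, portal, scale05)
  expect_equal(region$area_um2, pi * 20^2 / 2, tolerance = 0.10)
  expect_equal(region$contour_length_um, pi * 20, tolerance = 0.05)

  # quarter arc of the same disk: length 10*pi um
  i_q <- which.min(ctr$points[, 1])       # theta = pi/2 (top of the disk)
  quarter <- periportal:::arc_span_um(ctr, i_start, i_q)
  expect_equal(quarter, 10 * pi, tolerance = 0.05)
})

test_that("steepness of a semicircular bump arc is one half", {
  m <- disk_mask(c(128, 128), c(64, 64), 40)
  portal <- portal_regions(m, scale05)[[1]]
  ctr <- portal$contour
  i_start <- which.max(ctr$points[, 2])
  i_end <- which.min(ctr$points[, 2])
  region <- list(portal_id = 1L, start_index = i_start, end_index = i_end,
                 contour_length_um = periportal:::arc_span_um(ctr, i_start, i_end))
  region <- build_polygon(region, portal, scale05)
  sh <- shape_features(region, portal, scale05)
  expect_equal(sh$f4, 0.5, tolerance = 0.06)
  # Menger curvature of a 20 um circle arc is 1/20 per um
  expect_equal(sh$f5, 0.05, tolerance = 0.10)
})
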