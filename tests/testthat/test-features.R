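scale05 <- periportal::pixel_scale(0.5)

rect_region <- function() {
  # rectangle polygon; area pinned to 1000 um^2 for easy density arithmetic
  poly <- rbind(c(20, 20), c(20, 120), c(100, 120), c(100, 20))
  list(polygon = poly, arc_points = poly[1:3, ], area_um2 = 1000,
       contour_length_um = 90, pixels = matrix(integer(), 0, 2))
}

test_that("lymphocyte density counts strict-interior centroids per area", {
  r <- rect_region()
  inside5 <- cbind(runif(5, 30, 90), runif(5, 30, 110))
  expect_equal(lymphocyte_density(r, inside5, scale05), 5)
  expect_equal(lymphocyte_density(r, matrix(numeric(), 0, 2), scale05), 0)
  on_edge <- rbind(c(20, 60))              # exactly on the boundary: excluded
  expect_equal(lymphocyte_density(r, on_edge, scale05), 0)
  r$area_um2 <- 0
  expect_error(lymphocyte_density(r, inside5, scale05), "zero area")
})

test_that("enclosing lymphocyte density counts distinct lymphocytes", {
  r <- rect_region()
  cell <- function(centroid, nb) list(centroid = centroid, n_sectors = 6L,
                                      neighbor_idx = nb, enclosed = TRUE)
  one <- list(cell(c(50, 60), 1:6))
  expect_equal(enclosing_lymphocyte_density(r, one, scale05), 6)
  shared <- list(cell(c(50, 60), 1:6), cell(c(70, 80), 4:9))
  expect_equal(enclosing_lymphocyte_density(r, shared, scale05), 9)
  expect_equal(enclosing_lymphocyte_density(r, list(), scale05), 0)
  outside <- list(cell(c(200, 200), 1:6))
  expect_equal(enclosing_lymphocyte_density(r, outside, scale05), 0)
})

arc_region <- function() {
  # straight 70 um arc at row 50, polygon extends below it
  arc <- cbind(50, seq(20, 160, by = 2))
  poly <- rbind(arc, c(95, 160), c(95, 20))
  list(polygon = poly, arc_points = arc, area_um2 = 70 * 22.5,
       contour_length_um = 70, pixels = matrix(integer(), 0, 2))
}

test_that("projected lymphocyte coverage is an interval union over the arc", {
  r <- arc_region()
  full <- cbind(52, 20 + 14 * (0:9) + 7)    # 10 non-overlapping footprints
  expect_equal(projected_lymphocyte_ratio(r, full, scale05), 1)
  onelymph <- cbind(52, 90)
  expect_equal(projected_lymphocyte_ratio(r, onelymph, scale05), 0.1)
  same_point <- rbind(c(52, 90), c(54, 90)) # same projection: union 7, not 14
  expect_equal(projected_lymphocyte_ratio(r, same_point, scale05), 0.1)
  # distance gate: a lymphocyte 15 um below the arc contributes nothing
  far <- cbind(80, 90)
  expect_equal(projected_lymphocyte_ratio(r, far, scale05), 0)
})

test_that("adding a lymphocyte never decreases the coverage ratio", {
  r <- arc_region()
  set.seed(5)
  pts <- cbind(runif(30, 51, 66), runif(30, 25, 155))
  prev <- 0
  for (k in seq_len(nrow(pts))) {
    f3 <- projected_lymphocyte_ratio(r, pts[seq_len(k), , drop = FALSE], scale05)
    expect_gte(f3 + 1e-12, prev)
    expect_lte(f3, 1)
    prev <- f3
  }
})

test_that("contour-length and area ratios use the parent portal", {
  m <- disk_mask(c(128, 128), c(64, 64), 40)
  portal <- portal_regions(m, scale05)[[1]]
  r <- rect_region()
  r$arc_points <- rbind(c(40, 30), c(40, 230))   # 100 um straight arc
  r$contour_length_um <- 100
  portal$perimeter_um <- 1000
  sh <- shape_features(r, portal, scale05)
  expect_equal(sh$f6, 0.1)
  expect_equal(sh$f7, 1000 / (sum(m) * 0.25), tolerance = 1e-9)
})

test_that("co-occurrence textures behave on constant and checkerboard images", {
  img_const <- matrix(0.4, 40, 40)
  px <- cbind(rep(5:34, 30), rep(5:34, each = 30))
  region <- list(pixels = px, area_um2 = nrow(px) * 0.25)
  tx <- texture_features(region, img_const, scale05)
  expect_false(tx$missing)
  expect_equal(tx$f8, 0); expect_equal(tx$f9, 0)
  expect_equal(tx$f10, 1); expect_equal(tx$f11, 1)

  board <- matrix(0, 40, 40)
  board[(row(board) + col(board)) %% 2 == 1] <- 1
  txb <- texture_features(region, board, pixel_scale(1), dists_um = 1)
  pm <- txb$per_matrix
  # 0 degrees, offset 1 px: every pair differs by the full level range
  expect_equal(unname(pm[1, "contrast"]), 31^2)
  expect_equal(unname(pm[1, "dissimilarity"]), 31)
  expect_equal(unname(pm[1, "asm"]), 0.5)
  # 45 degrees: diagonal neighbours share the colour
  expect_equal(unname(pm[2, "contrast"]), 0)
  # energy is sqrt(ASM) per matrix, ASM in (0, 1]
  expect_equal(unname(pm[, "energy"]), unname(sqrt(pm[, "asm"])))
  expect_true(all(pm[, "asm"] > 0 & pm[, "asm"] <= 1))
})

test_that("textures go missing for absent images or tiny regions", {
  region <- list(pixels = cbind(5:10, 5:10), area_um2 = 6)
  expect_true(texture_features(region, NULL, scale05)$missing)
  expect_true(texture_features(region, matrix(0.5, 40, 40), scale05)$missing)
  # a 1-px wide region: the horizontal offsets find no pair, vertical ones do
  col_px <- cbind(5:64, 20)
  tall <- list(pixels = col_px, area_um2 = nrow(col_px) * 0.25)
  tx <- texture_features(tall, matrix(runif(80 * 40), 80, 40), scale05)
  expect_false(tx$missing)
  expect_true(all(is.finite(c(tx$f8, tx$f9, tx$f10, tx$f11))))
})

test_that("bile ductule ratio is the masked area fraction, clipped", {
  px <- cbind(rep(10:29, 20), rep(10:29, each = 20))   # 400 px
  region <- list(pixels = px, area_um2 = 400 * 0.25)
  duct <- matrix(0L, 64, 64)
  duct[10:29, 10:19] <- 1L                              # half of the region
  expect_equal(bile_ductule_ratio(region, duct, scale05), 0.5)
  expect_equal(bile_ductule_ratio(region, matrix(0L, 64, 64), scale05), 0)
  duct[] <- 1L
  expect_equal(bile_ductule_ratio(region, duct, scale05), 1)
})

test_that("non-protruding f13 counts projected enclosing lymphocytes per um", {
  seg <- list(arc_points = cbind(50, seq(20, 60, by = 2)), length_um = 20)
  lymph <- rbind(c(55, 30), c(55, 40), c(47, 50), c(53, 25),  # within 10 um
                 c(80, 40))                                    # 15 um away
  cells <- list(list(centroid = c(60, 40), n_sectors = 6L,
                     neighbor_idx = 1:4, enclosed = TRUE))
  np <- nonprotruding_feature(seg, cells, lymph, scale05)
  expect_equal(np$count_numerator, 4L)
  expect_equal(np$f13, 0.2)
  cells_far <- list(list(centroid = c(60, 40), n_sectors = 6L,
                         neighbor_idx = 5L, enclosed = TRUE))
  expect_equal(nonprotruding_feature(seg, cells_far, lymph, scale05)$count_numerator, 0L)
  expect_equal(nonprotruding_feature(seg, list(), lymph, scale05)$f13, 0)
})
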