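scale05 <- periportal::pixel_scale(0.5)

test_that("portal confirmation requires a nearby bile duct", {
  m <- disk_mask(c(256, 256), c(128, 128), 60)
  portals <- portal_regions(m, scale05)
  expect_length(portals, 1)

  duct_in <- matrix(0L, 256, 256); duct_in[126:130, 126:130] <- 1L
  expect_true(confirm_portals(portals, duct_in, scale05)[[1]]$confirmed)

  # no ducts at all: a central-vein lookalike
  expect_false(confirm_portals(portals, matrix(0L, 256, 256), scale05)[[1]]$confirmed)

  # dot 15 um (30 px) outside the border is inside the 20 um tolerance;
  # verified against the brute-force distance from the dot to the component
  duct_out <- matrix(0L, 256, 256); duct_out[128, 218] <- 1L
  d_brute <- sqrt((218 - 128)^2) - 60       # 30 px = 15 um
  expect_equal(d_brute * 0.5, 15)
  expect_true(confirm_portals(portals, duct_out, scale05)[[1]]$confirmed)
  expect_false(confirm_portals(portals, duct_out, scale05,
                               tolerance_um = 10)[[1]]$confirmed)
})

test_that("DBSCAN matches brute-force density reachability on random sets", {
  set.seed(42)
  for (rep in 1:5) {
    pts <- rbind(matrix(rnorm(30, 0, 8), ncol = 2),
                 matrix(rnorm(30, 60, 8), ncol = 2),
                 matrix(runif(20, -40, 120), ncol = 2))
    eps <- 12; min_pts <- 3
    got <- dbscan_points(pts, eps, min_pts)
    orc <- oracle_dbscan_cores(pts, eps, min_pts)
    # core points: identical partition (up to label renaming)
    core <- orc$core
    expect_true(all(got[core] > 0))
    tab <- table(got[core], orc$comp[core])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    for (i in which(!core)) {
      near_core_cl <- unique(orc$comp[orc$core & orc$d[i, ] <= eps])
      if (got[i] == 0) {
        expect_length(near_core_cl, 0)      # true noise
      } else {
        # border point: assigned to one of its adjacent core clusters
        expect_true(any(got[core & orc$comp %in% near_core_cl] == got[i]))
      }
    }
  }
})

test_that("periportal clustering keeps only clusters touching the portal", {
  m <- disk_mask(c(400, 400), c(200, 200), 100)   # 50 um radius portal
  portal <- portal_regions(m, scale05)[[1]]
  # 10 centroids spaced 10 um (20 px) straddling the border along a radius
  line <- cbind(200, seq(260, 440, by = 20))
  cl <- cluster_periportal_lymphocytes(line, portal, scale05)
  # points beyond the 50 um band are excluded up front, the rest cluster
  expect_length(cl, 1)
  expect_true(cl[[1]]$touches_portal)
  expect_gte(nrow(cl[[1]]$points), 5)

  # two isolated far points: noise under min_pts = 3
  iso <- rbind(c(40, 40), c(360, 360))
  expect_length(cluster_periportal_lymphocytes(iso, portal, scale05), 0)

  # two tight groups, only the one overlapping the portal is returned
  near <- cbind(200 + runif(5, -5, 5), 295 + runif(5, -5, 5))
  far <- cbind(60 + runif(5, -5, 5), 200 + runif(5, -5, 5))   # ~35 um away
  set.seed(7)
  cl2 <- cluster_periportal_lymphocytes(rbind(near, far), portal, scale05,
                                        band_um = 200)
  expect_length(cl2, 1)
  expect_lt(max(abs(colMeans(cl2[[1]]$points) - c(200, 295))), 10)
})

test_that("Delaunay triangulation agrees with the empty-circumcircle oracle", {
  set.seed(3)
  pts <- matrix(runif(24, 0, 100), ncol = 2)
  got <- periportal:::delaunay_triangles(pts)
  got_idx <- lapply(got, function(tr) {
    sort(apply(tr, 1, function(v)
      which.min((pts[, 1] - v[1])^2 + (pts[, 2] - v[2])^2)))
  })
  orc <- oracle_delaunay(pts)
  key <- function(x) paste(x, collapse = "-")
  expect_setequal(vapply(got_idx, key, ""), vapply(orc, key, ""))
})

test_that("boundary refinement fills small triangles and is a superset", {
  m <- disk_mask(c(300, 300), c(150, 150), 80)
  portal <- portal_regions(m, scale05)[[1]]
  # three points straddling the border, pairwise within 20 um (40 px)
  tri <- list(list(points = rbind(c(150, 228), c(140, 246), c(160, 248)),
                   touches_portal = TRUE))
  ref <- refine_portal_boundary(portal, tri, scale05)
  expect_gt(sum(ref$mask), sum(portal$mask))
  expect_true(all(ref$mask[portal$mask == 1L] == 1L))
  # brute-force audit of every retained triangle's longest edge
  for (tr in attr(ref, "triangles")) {
    e <- c(dist(tr)) * 0.5
    expect_lte(max(e), 20)
  }

  # one pairwise distance of 25 um (50 px): triangle discarded, mask unchanged
  far <- list(list(points = rbind(c(150, 228), c(140, 246), c(190, 246)),
                   touches_portal = TRUE))
  ref2 <- refine_portal_boundary(portal, far, scale05)
  expect_identical(ref2$mask, portal$mask)

  # no clusters: identity
  ref3 <- refine_portal_boundary(portal, list(), scale05)
  expect_identical(ref3$mask, portal$mask)
})

test_that("refinement is idempotent up to re-rasterisation", {
  set.seed(9)
  m <- disk_mask(c(300, 300), c(150, 150), 80)
  portal <- portal_regions(m, scale05)[[1]]
  ang <- runif(12, -0.4, 0.4)
  pts <- cbind(150 - (80 + runif(12, 2, 12)) * sin(ang),
               150 + (80 + runif(12, 2, 12)) * cos(ang))
  cl <- list(list(points = pts, touches_portal = TRUE))
  r1 <- refine_portal_boundary(portal, cl, scale05)
  r2 <- refine_portal_boundary(r1, cl, scale05)
  changed <- sum(r1$mask != r2$mask)
  expect_lte(changed, 0.01 * sum(r1$mask))
})
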