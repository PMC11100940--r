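## The 13 heterogeneous infiltration features. f1-f12 describe protruding
## regions; f13 describes non-protruding segments. Densities are reported
## per 1000 um^2 (f1, f2) and per um (f13); these unit conventions keep the
## values O(1) for classifier conditioning and are stamped in the feature
## table metadata.

#' Lymphocyte density of a protruding region (f1)
#'
#' Count of lymphocyte centroids strictly inside the region polygon,
#' divided by the region area, per 1000 um^2.
#'
#' @param region A built region (see [build_polygon()]).
#' @param lymph_centroids n x 2 (row, col) lymphocyte centroids (px).
#' @param scale A [pixel_scale()].
#' @return Numeric density (per 1000 um^2).
#' @export
lymphocyte_density <- function(region, lymph_centroids, scale = pixel_scale()) {
  if (region$area_um2 <= 0) stop("degenerate region: zero area")
  if (!nrow(lymph_centroids)) return(0)
  inside <- points_in_polygon(lymph_centroids, region$polygon) == 1L
  sum(inside) / region$area_um2 * 1000
}

#' Enclosing-lymphocyte density of a protruding region (f2)
#'
#' Distinct lymphocytes that enclose at least one enclosed hepatocyte whose
#' centroid lies in the region, divided by the region area (per 1000 um^2).
#'
#' @param region A built region.
#' @param cells Output of [find_enclosed_hepatocytes()].
#' @param scale A [pixel_scale()].
#' @return Numeric density (per 1000 um^2).
#' @export
enclosing_lymphocyte_density <- function(region, cells, scale = pixel_scale()) {
  if (region$area_um2 <= 0) stop("degenerate region: zero area")
  enc <- Filter(function(c) isTRUE(c$enclosed), cells)
  if (!length(enc)) return(0)
  cent <- do.call(rbind, lapply(enc, `[[`, "centroid"))
  inside <- points_in_polygon(cent, region$polygon) >= 1L
  if (!any(inside)) return(0)
  idx <- unique(unlist(lapply(enc[inside], `[[`, "neighbor_idx")))
  length(idx) / region$area_um2 * 1000
}

interval_union_length <- function(lo, hi) {
  if (!length(lo)) return(0)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  total <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi) cur_hi <- max(cur_hi, hi[i])
    else { total <- total + (cur_hi - cur_lo); cur_lo <- lo[i]; cur_hi <- hi[i] }
  }
  total + (cur_hi - cur_lo)
}

#' Projected lymphocyte boundary coverage (f3)
#'
#' Lymphocytes inside the region whose centroids lie within `max_dist_um`
#' of the region's boundary arc are projected to their nearest arc point;
#' each marks an arc interval of `footprint_um` (one lymphocyte diameter)
#' centred there. f3 is the union length of the marked intervals divided by
#' the arc length, clipped to \[0, 1\].
#'
#' @param region A built region.
#' @param lymph_centroids n x 2 lymphocyte centroids (px).
#' @param scale A [pixel_scale()].
#' @param max_dist_um Projection distance gate (um), default 10.
#' @param footprint_um Marked footprint per lymphocyte (um), default 7.
#' @return Numeric ratio in \[0, 1\].
#' @export
projected_lymphocyte_ratio <- function(region, lymph_centroids,
                                       scale = pixel_scale(),
                                       max_dist_um = 10, footprint_um = 7) {
  scale <- as_pixel_scale(scale)
  L <- region$contour_length_um
  if (L <= 0) stop("degenerate region: zero contour length")
  if (!nrow(lymph_centroids)) return(0)
  inside <- points_in_polygon(lymph_centroids, region$polygon) >= 1L
  pts <- lymph_centroids[inside, , drop = FALSE]
  if (!nrow(pts)) return(0)
  pr <- project_to_polyline(pts, region$arc_points)
  keep <- pr$dist_px * scale$microns_per_pixel <= max_dist_um
  if (!any(keep)) return(0)
  s <- pr$arc_px[keep] * scale$microns_per_pixel
  lo <- pmax(0, s - footprint_um / 2)
  hi <- pmin(L, s + footprint_um / 2)
  min(1, interval_union_length(lo, hi) / L)
}

menger_curvature <- function(a, b, c) {
  # 4 * area / (product of side lengths); 0 for collinear triplets
  ab <- sqrt(sum((a - b)^2)); bc <- sqrt(sum((b - c)^2)); ca <- sqrt(sum((c - a)^2))
  if (ab * bc * ca == 0) return(0)
  area2 <- abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2]))
  2 * area2 / (ab * bc * ca)
}

#' Shape features of a protruding region (f4-f7)
#'
#' f4, steepness: maximum perpendicular distance of the arc points from the
#' closing chord, divided by the chord length (depth over width). f5, mean
#' curvature: discrete Menger curvature averaged over arc points, each
#' evaluated on the triplet of the point and the two arc positions
#' `curvature_step_um` away (1/um). f6: arc length over portal perimeter.
#' f7: region area over portal area.
#'
#' @param region A built region.
#' @param portal The parent `portal_region`.
#' @param scale A [pixel_scale()].
#' @param curvature_step_um Triplet spacing for f5 (um), default 5.
#' @return `list(f4, f5, f6, f7, degenerate)`; f4 is `NA` (and the set is
#'   flagged degenerate) when the chord is shorter than one pixel.
#' @export
shape_features <- function(region, portal, scale = pixel_scale(),
                           curvature_step_um = 5) {
  scale <- as_pixel_scale(scale)
  um <- scale$microns_per_pixel
  pts <- region$arc_points
  m <- nrow(pts)
  p1 <- pts[1, ]; p2 <- pts[m, ]
  chord_px <- sqrt(sum((p2 - p1)^2))
  L <- region$contour_length_um
  portal_area_um2 <- sum(portal$mask) * um^2
  f6 <- L / portal$perimeter_um
  f7 <- region$area_um2 / portal_area_um2
  if (chord_px < 1) {
    return(list(f4 = NA_real_, f5 = NA_real_, f6 = f6, f7 = f7,
                degenerate = TRUE))
  }
  # perpendicular distance to the chord line
  dvec <- (p2 - p1) / chord_px
  rel <- sweep(pts, 2, p1)
  perp <- abs(rel[, 1] * dvec[2] - rel[, 2] * dvec[1])
  f4 <- (max(perp) * um) / (chord_px * um)
  # mean Menger curvature on triplets spaced curvature_step_um apart
  seg <- sqrt(rowSums(diff(pts)^2)) * um
  arc <- c(0, cumsum(seg))
  step <- curvature_step_um
  valid <- which(arc >= step & arc <= L - step)
  if (length(valid)) {
    interp <- function(s) {
      j <- findInterval(s, arc, rightmost.closed = TRUE)
      j <- pmin(pmax(j, 1L), m - 1L)
      t <- (s - arc[j]) / pmax(arc[j + 1L] - arc[j], 1e-12)
      pts[j, , drop = FALSE] + (pts[j + 1L, , drop = FALSE] - pts[j, , drop = FALSE]) * t
    }
    A <- interp(arc[valid] - step) * um
    C <- interp(arc[valid] + step) * um
    B <- pts[valid, , drop = FALSE] * um
    f5 <- mean(vapply(seq_along(valid), function(i)
      menger_curvature(A[i, ], B[i, ], C[i, ]), numeric(1)))
  } else f5 <- 0
  list(f4 = f4, f5 = f5, f6 = f6, f7 = f7, degenerate = FALSE)
}

glcm_offsets <- function(dists_um, scale) {
  out <- list()
  for (d_um in dists_um) {
    d <- max(1L, round(um_to_px(d_um, scale)))
    # angles 0, 45, 90, 135 degrees; (row, col) displacements, y up
    out <- c(out, list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d)))
  }
  out
}

#' Co-occurrence texture features of a protruding region (f8-f11)
#'
#' Region pixels are quantised to `levels` gray levels over the global
#' image range. Symmetric, normalised co-occurrence matrices are built for
#' the offsets given by `dists_um` (in px, rounded, min 1) crossed with the
#' four angles 0/45/90/135 degrees, counting only pixel pairs with both
#' ends inside the region. Per matrix: contrast, dissimilarity, angular
#' second moment, energy = sqrt(ASM); each statistic is then averaged over
#' the matrices (offsets yielding no pair are skipped).
#'
#' @param region A built region with at least `min_px` pixels.
#' @param intensity Grayscale matrix, scene shaped.
#' @param scale A [pixel_scale()].
#' @param levels Number of gray levels, default 32.
#' @param dists_um Offset distances (um), default c(3, 5).
#' @param min_px Minimum region size, default 50.
#' @return `list(f8, f9, f10, f11, per_matrix, missing)`; `missing = TRUE`
#'   (features `NA`) when the intensity image is absent or the region is
#'   too small.
#' @export
texture_features <- function(region, intensity, scale = pixel_scale(),
                             levels = 32L, dists_um = c(3, 5), min_px = 50L) {
  scale <- as_pixel_scale(scale)
  missing_out <- list(f8 = NA_real_, f9 = NA_real_, f10 = NA_real_,
                      f11 = NA_real_, per_matrix = NULL, missing = TRUE)
  if (is.null(intensity) || nrow(region$pixels) < min_px) return(missing_out)
  rng <- range(intensity, finite = TRUE)
  q <- if (diff(rng) > 0) {
    pmin(as.integer(floor((intensity - rng[1]) / diff(rng) * levels)), levels - 1L)
  } else matrix(0L, nrow(intensity), ncol(intensity))
  dim(q) <- dim(intensity)
  nr <- nrow(intensity); nc <- ncol(intensity)
  member <- matrix(FALSE, nr, nc)
  member[region$pixels] <- TRUE
  px <- region$pixels
  stats_rows <- list()
  ii <- matrix(0:(levels - 1L), levels, levels)
  jj <- t(ii)
  for (off in glcm_offsets(dists_um, scale)) {
    r2 <- px[, 1] + off[1]; c2 <- px[, 2] + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    ok[ok] <- member[cbind(r2[ok], c2[ok])]
    if (!any(ok)) next
    gi <- q[px[ok, , drop = FALSE]]
    gj <- q[cbind(r2[ok], c2[ok])]
    counts <- matrix(tabulate(gi * levels + gj + 1L, nbins = levels^2),
                     levels, levels)
    counts <- counts + t(counts)   # symmetric
    P <- counts / sum(counts)
    asm <- sum(P^2)
    stats_rows[[length(stats_rows) + 1L]] <- c(
      contrast = sum(P * (ii - jj)^2),
      dissimilarity = sum(P * abs(ii - jj)),
      asm = asm,
      energy = sqrt(asm))
  }
  if (!length(stats_rows)) return(missing_out)
  S <- do.call(rbind, stats_rows)
  list(f8 = mean(S[, "contrast"]), f9 = mean(S[, "dissimilarity"]),
       f10 = mean(S[, "asm"]), f11 = mean(S[, "energy"]),
       per_matrix = S, missing = FALSE)
}

#' Bile-ductule area ratio of a protruding region (f12)
#'
#' Ductular reaction mimics infiltration at the portal border; a high
#' ductule content argues against true infiltration.
#'
#' @param region A built region.
#' @param bile_ductule_mask Binary matrix.
#' @param scale A [pixel_scale()].
#' @return Ratio of ductule area to region area, clipped to \[0, 1\].
#' @export
bile_ductule_ratio <- function(region, bile_ductule_mask, scale = pixel_scale()) {
  scale <- as_pixel_scale(scale)
  if (region$area_um2 <= 0) stop("degenerate region: zero area")
  if (!nrow(region$pixels)) return(0)
  duct_um2 <- sum(bile_ductule_mask[region$pixels] != 0) *
    scale$microns_per_pixel^2
  min(1, duct_um2 / region$area_um2)
}

#' Projected enclosing-lymphocyte density of a non-protruding segment (f13)
#'
#' Enclosing lymphocytes (neighbours of any enclosed hepatocyte, scene
#' wide) whose centroids lie within `max_dist_um` of the segment arc are
#' projected onto it; f13 is their count divided by the segment length.
#'
#' @param segment A segment from [propose_regions()].
#' @param cells Output of [find_enclosed_hepatocytes()].
#' @param lymph_centroids n x 2 lymphocyte centroids (px).
#' @param scale A [pixel_scale()].
#' @param max_dist_um Projection distance gate (um), default 10.
#' @return `list(f13, count_numerator)`.
#' @export
nonprotruding_feature <- function(segment, cells, lymph_centroids,
                                  scale = pixel_scale(), max_dist_um = 10) {
  scale <- as_pixel_scale(scale)
  if (segment$length_um <= 0) stop("degenerate segment: zero length")
  enc <- Filter(function(c) isTRUE(c$enclosed), cells)
  idx <- unique(unlist(lapply(enc, `[[`, "neighbor_idx")))
  if (!length(idx)) return(list(f13 = 0, count_numerator = 0L))
  pts <- lymph_centroids[idx, , drop = FALSE]
  pr <- project_to_polyline(pts, segment$arc_points)
  cnt <- sum(pr$dist_px * scale$microns_per_pixel <= max_dist_um)
  list(f13 = cnt / segment$length_um, count_numerator = as.integer(cnt))
}

#' Feature table for the proposed regions of one portal
#'
#' Computes f1-f12 for every protruding region and f13 for every
#' non-protruding segment, returning a long data frame with one row per
#' region/segment (`kind` column distinguishing them).
#'
#' @param proposal Output of [propose_regions()].
#' @param portal The parent `portal_region`.
#' @param scene The [scene_masks()] object.
#' @param cells Output of [find_enclosed_hepatocytes()] for this portal.
#' @param scale A [pixel_scale()].
#' @return Data frame with columns `portal_id`, `region_id`, `kind`,
#'   `f1`..`f13`, `count_numerator`, `contour_length_um`, `area_um2`,
#'   `length_um`, `degenerate`, `texture_missing`.
#' @export
region_features <- function(proposal, portal, scene, cells,
                            scale = scene$scale) {
  scale <- as_pixel_scale(scale)
  lymph <- attr(cells, "lymph_centroids")
  if (is.null(lymph)) lymph <- mask_centroids(scene$lymphocyte)
  rows <- list()
  for (r in proposal$regions) {
    if (r$area_um2 <= 0 || r$contour_length_um <= 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        portal_id = portal$id, region_id = r$region_id, kind = "protruding",
        f1 = NA, f2 = NA, f3 = NA, f4 = NA, f5 = NA, f6 = NA, f7 = NA,
        f8 = NA, f9 = NA, f10 = NA, f11 = NA, f12 = NA, f13 = NA,
        count_numerator = NA_integer_,
        contour_length_um = r$contour_length_um, area_um2 = r$area_um2,
        length_um = NA_real_, degenerate = TRUE, texture_missing = TRUE)
      next
    }
    sh <- shape_features(r, portal, scale)
    tx <- texture_features(r, scene$intensity, scale)
    rows[[length(rows) + 1L]] <- data.frame(
      portal_id = portal$id, region_id = r$region_id, kind = "protruding",
      f1 = lymphocyte_density(r, lymph, scale),
      f2 = enclosing_lymphocyte_density(r, cells, scale),
      f3 = projected_lymphocyte_ratio(r, lymph, scale),
      f4 = sh$f4, f5 = sh$f5, f6 = sh$f6, f7 = sh$f7,
      f8 = tx$f8, f9 = tx$f9, f10 = tx$f10, f11 = tx$f11,
      f12 = bile_ductule_ratio(r, scene$bile_ductule, scale),
      f13 = NA_real_, count_numerator = NA_integer_,
      contour_length_um = r$contour_length_um, area_um2 = r$area_um2,
      length_um = NA_real_,
      degenerate = isTRUE(r$degenerate) || isTRUE(sh$degenerate),
      texture_missing = tx$missing)
  }
  for (s in proposal$segments) {
    np <- nonprotruding_feature(s, cells, lymph, scale)
    rows[[length(rows) + 1L]] <- data.frame(
      portal_id = portal$id, region_id = s$segment_id, kind = "non_protruding",
      f1 = NA, f2 = NA, f3 = NA, f4 = NA, f5 = NA, f6 = NA, f7 = NA,
      f8 = NA, f9 = NA, f10 = NA, f11 = NA, f12 = NA,
      f13 = np$f13, count_numerator = np$count_numerator,
      contour_length_um = NA_real_, area_um2 = NA_real_,
      length_um = s$length_um, degenerate = FALSE, texture_missing = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(out, "units") <- c(f1 = "per 1000 um^2", f2 = "per 1000 um^2",
                          f13 = "per um")
  out
}
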