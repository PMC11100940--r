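## Contour extraction and polygon geometry.
##
## Convention: matrices are [row, col]; contour points are (row, col)
## pixel-centre coordinates, 1-based; orientation is normalised so that the
## shoelace signed area in (x = col, y = -row) coordinates is positive
## (counter-clockwise with the y axis pointing up). Arc lengths and areas
## are reported in um and um^2.

#' Label 8-connected components of a binary mask
#'
#' EBImage's `bwlabel` uses 4-connectivity; diagonal-only neighbours are
#' merged here with a union-find pass so that components match the
#' 8-connected definition used throughout the package.
#'
#' @param mask Binary matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask != 0))
  k <- max(lab)
  if (k < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour label pairs
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # (r,c) vs (r+1,c+1)
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # (r,c+1) vs (r+1,c)
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

shoelace_signed_area <- function(points) {
  # signed area in (x = col, y = -row) coordinates; positive = CCW (y up)
  x <- points[, 2]; y <- -points[, 1]
  n <- nrow(points)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

smooth_closed <- function(points, window) {
  # circular moving average; removes the staircase bias of pixel chains
  if (window < 2L || nrow(points) <= window) return(points)
  n <- nrow(points)
  half <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), (-half):half, function(i, d) ((i + d - 1L) %% n) + 1L)
  cbind(rowMeans(matrix(points[idx, 1], n)), rowMeans(matrix(points[idx, 2], n)))
}

new_contour <- function(points, scale) {
  scale <- as_pixel_scale(scale)
  n <- nrow(points)
  if (n < 3L) stop("a contour needs at least 3 points")
  if (shoelace_signed_area(points) < 0) points <- points[n:1, , drop = FALSE]
  dif <- diff(rbind(points, points[1, , drop = FALSE]))
  seg <- sqrt(rowSums(dif^2)) * scale$microns_per_pixel   # n segments, closing last
  structure(list(
    points = points,
    arc_um = c(0, cumsum(seg[-n])),
    perimeter_um = sum(seg),
    scale = scale
  ), class = "portal_contour")
}

#' @export
print.portal_contour <- function(x, ...) {
  cat(sprintf("<contour: %d points, perimeter %.1f um>\n",
              nrow(x$points), x$perimeter_um))
  invisible(x)
}

#' Extract outer contours of mask components
#'
#' One closed outer contour per 8-connected component with area at least
#' `min_area_um2`. Holes are ignored. The raw pixel chain is lightly
#' smoothed with a circular moving average (`smooth_window` px) so that arc
#' lengths approximate the underlying smooth boundary instead of the
#' staircase chain; orientation is normalised counter-clockwise.
#'
#' @param mask Binary matrix.
#' @param scale A [pixel_scale()].
#' @param min_area_um2 Minimum component area to keep (um^2).
#' @param smooth_window Odd window (px) for contour smoothing; 1 disables.
#' @return List of contour objects, each with `points` (n x 2, row/col),
#'   `arc_um` (cumulative arc length at each point, starting at 0),
#'   `perimeter_um`, and `scale`. Empty mask gives an empty list.
#' @export
extract_contours <- function(mask, scale = pixel_scale(), min_area_um2 = 100,
                             smooth_window = 5L) {
  scale <- as_pixel_scale(scale)
  if (!any(mask != 0)) return(list())
  lab <- label_components(mask)
  px_area <- tabulate(lab[lab > 0])
  keep <- which(px_area * scale$microns_per_pixel^2 >= min_area_um2)
  if (!length(keep)) return(list())
  oc <- EBImage::ocontour(lab)
  out <- list()
  for (id in keep) {
    pts <- oc[[id]] + 1  # ocontour is 0-based (dim1, dim2) = (row, col)
    if (is.null(pts) || nrow(pts) < 3L) next
    pts <- smooth_closed(pts, as.integer(smooth_window))
    out[[length(out) + 1L]] <- new_contour(pts, scale)
  }
  out
}

## --- polygon utilities -----------------------------------------------------

#' Point-in-polygon test
#'
#' Thin wrapper around `sp::point.in.polygon` in the package's (row, col)
#' convention. Codes: 0 outside, 1 strictly inside, 2 on an edge, 3 vertex.
#'
#' @param points n x 2 matrix of (row, col) query points.
#' @param polygon m x 2 matrix of (row, col) polygon vertices.
#' @return Integer vector of codes.
#' @keywords internal
points_in_polygon <- function(points, polygon) {
  sp::point.in.polygon(points[, 2], points[, 1], polygon[, 2], polygon[, 1])
}

#' Rasterize a polygon to pixel indices
#'
#' Pixels of a `dim[1]` x `dim[2]` grid whose centres fall inside or on the
#' polygon.
#'
#' @param polygon m x 2 (row, col) vertices.
#' @param dim Grid dimensions c(nrow, ncol).
#' @return Two-column integer matrix of (row, col) pixel coordinates.
#' @keywords internal
rasterize_polygon <- function(polygon, dim) {
  r0 <- max(1L, floor(min(polygon[, 1]))); r1 <- min(dim[1], ceiling(max(polygon[, 1])))
  c0 <- max(1L, floor(min(polygon[, 2]))); c1 <- min(dim[2], ceiling(max(polygon[, 2])))
  if (r1 < r0 || c1 < c0) return(matrix(integer(), 0, 2))
  grid <- cbind(rep(r0:r1, times = c1 - c0 + 1L),
                rep(c0:c1, each = r1 - r0 + 1L))
  grid[points_in_polygon(grid, polygon) > 0, , drop = FALSE]
}

#' Interpolate a point at a given arc-length position on a closed contour
#' @keywords internal
point_at_arc <- function(contour, s_um) {
  per <- contour$perimeter_um
  s <- s_um %% per
  arc_ext <- c(contour$arc_um, per)
  pts_ext <- rbind(contour$points, contour$points[1, , drop = FALSE])
  j <- findInterval(s, arc_ext, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), nrow(contour$points))
  seg_len <- arc_ext[j + 1L] - arc_ext[j]
  t <- ifelse(seg_len > 0, (s - arc_ext[j]) / seg_len, 0)
  pts_ext[j, , drop = FALSE] + (pts_ext[j + 1L, , drop = FALSE] - pts_ext[j, , drop = FALSE]) * t
}

#' Project points onto an open polyline
#'
#' For each query point, the nearest point on the polyline, its distance,
#' and its arc-length position along the polyline.
#'
#' @param points k x 2 (row, col) query points.
#' @param polyline m x 2 (row, col) vertices of an open polyline.
#' @return List with numeric vectors `dist_px` and `arc_px` (both length k).
#' @keywords internal
project_to_polyline <- function(points, polyline) {
  k <- nrow(points); m <- nrow(polyline)
  if (k == 0L) return(list(dist_px = numeric(0), arc_px = numeric(0)))
  if (m < 2L) {
    d <- sqrt((points[, 1] - polyline[1, 1])^2 + (points[, 2] - polyline[1, 2])^2)
    return(list(dist_px = d, arc_px = rep(0, k)))
  }
  A <- polyline[-m, , drop = FALSE]; B <- polyline[-1, , drop = FALSE]
  D <- B - A
  len2 <- rowSums(D^2); len2[len2 == 0] <- 1e-12
  seg_len <- sqrt(rowSums(D^2))
  arc0 <- c(0, cumsum(seg_len))[seq_len(m - 1L)]
  # t[k, m-1]
  t1 <- outer(points[, 1], A[, 1], "-") * matrix(D[, 1], k, m - 1L, byrow = TRUE)
  t2 <- outer(points[, 2], A[, 2], "-") * matrix(D[, 2], k, m - 1L, byrow = TRUE)
  t  <- pmin(pmax((t1 + t2) / matrix(len2, k, m - 1L, byrow = TRUE), 0), 1)
  pr <- matrix(A[, 1], k, m - 1L, byrow = TRUE) + t * matrix(D[, 1], k, m - 1L, byrow = TRUE)
  pc <- matrix(A[, 2], k, m - 1L, byrow = TRUE) + t * matrix(D[, 2], k, m - 1L, byrow = TRUE)
  d2 <- (points[, 1] - pr)^2 + (points[, 2] - pc)^2
  j  <- max.col(-d2, ties.method = "first")
  ij <- cbind(seq_len(k), j)
  list(dist_px = sqrt(d2[ij]),
       arc_px  = arc0[j] + t[ij] * seg_len[j])
}

segments_intersect <- function(p1, p2, q1, q2) {
  # proper intersection of open segments (shared endpoints not counted)
  d <- function(a, b, c) (b[2] - a[2]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[2] - a[2])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

## --- GeoJSON export --------------------------------------------------------

#' Export contours or regions as a GeoJSON FeatureCollection
#'
#' Coordinates are written as (x = col - 1, y = row - 1) pixel units
#' (0-based, origin top-left); micron measurements travel in the feature
#' properties.
#'
#' @param polygons List of n x 2 (row, col) vertex matrices.
#' @param properties Data frame with one row per polygon (optional).
#' @param path Optional output path; when given, JSON is written there.
#' @return The GeoJSON structure (a list), invisibly if `path` is given.
#' @export
geojson_polygons <- function(polygons, properties = NULL, path = NULL) {
  feats <- lapply(seq_along(polygons), function(i) {
    poly <- polygons[[i]]
    ring <- cbind(poly[, 2] - 1, poly[, 1] - 1)
    ring <- rbind(ring, ring[1, , drop = FALSE])
    props <- if (is.null(properties)) structure(list(), names = character(0)) else
      as.list(properties[i, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) unname(ring[j, ])))),
         properties = props)
  })
  gj <- list(type = "FeatureCollection", features = feats)
  if (!is.null(path)) {
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
    return(invisible(gj))
  }
  gj
}
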