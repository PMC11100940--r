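## Protruding-region proposal: chord test on the refined portal contour,
## partition into protruding / non-protruding segments, candidate polygons.

bilinear_sample <- function(mat, r, c) {
  # bilinear interpolation; coordinates clamped to the grid
  nr <- nrow(mat); nc <- ncol(mat)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  mat[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    mat[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    mat[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    mat[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

cyclic_indices <- function(start, end, n) {
  if (start <= end) start:end else c(start:n, 1:end)
}

arc_span_um <- function(contour, start, end) {
  s <- contour$arc_um[end] - contour$arc_um[start]
  if (s < 0) s <- s + contour$perimeter_um
  s
}

#' Chord test: flag protruding contour points
#'
#' For every contour point, the boundary arc of length `window_um` centred
#' on it (half each way along arc length) is closed with a straight chord
#' between its endpoints. The chord is sampled at sub-pixel steps (endpoints
#' and a `guard_px` margin excluded); the point is flagged protruding when
#' the chord dips into the portal deeper than `depth_min_um`.
#'
#' The depth threshold keeps the test from firing on every point of a
#' smooth convex border: across a 50 um window, a circular portal of
#' radius R incurs a chord depth of about 312/R um, below 3 um for
#' R above ~105 um, whereas an outward bump produced by infiltrating
#' lymphocytes cuts far deeper.
#'
#' @param portal A `portal_region` (typically refined).
#' @param scale A [pixel_scale()].
#' @param window_um Arc window length (um); default 50, twice the
#'   hepatocyte diameter.
#' @param depth_min_um Minimum chord incursion depth (um), default 3.
#' @param guard_px Samples within this many px of a chord endpoint are
#'   ignored, default 2.
#' @return Logical vector, one flag per contour point (TRUE = protruding).
#'   Contours shorter than the window are entirely non-protruding.
#' @export
flag_contour_points <- function(portal, scale = pixel_scale(), window_um = 50,
                                depth_min_um = 3, guard_px = 2) {
  scale <- as_pixel_scale(scale)
  ctr <- portal$contour
  n <- nrow(ctr$points)
  if (ctr$perimeter_um < window_um) return(rep(FALSE, n))
  depth_px <- EBImage::imageData(EBImage::distmap(portal$mask))
  half <- window_um / 2
  E1 <- point_at_arc(ctr, ctr$arc_um - half)
  E2 <- point_at_arc(ctr, ctr$arc_um + half)
  L <- sqrt(rowSums((E2 - E1)^2))                       # chord length, px
  m <- max(16L, ceiling(max(L))) + 1L
  t <- matrix(seq_len(m - 1L) / m, n, m - 1L, byrow = TRUE)
  valid <- (t * L >= guard_px) & ((1 - t) * L >= guard_px)
  R <- E1[, 1] + t * (E2[, 1] - E1[, 1])
  C <- E1[, 2] + t * (E2[, 2] - E1[, 2])
  # the distance map measures to background pixel centres, ~0.5 px beyond
  # the true boundary; interpolate bilinearly and subtract that offset
  d <- pmax(bilinear_sample(depth_px, as.vector(R), as.vector(C)) - 0.5, 0)
  depth_um <- matrix(d, n, m - 1L) * scale$microns_per_pixel
  depth_um[!valid] <- 0
  apply(depth_um, 1, max) > depth_min_um
}

## maximal cyclic runs of FALSE flags; list of (start, end) index pairs
nonprotruding_runs <- function(flags) {
  n <- length(flags)
  if (!any(!flags)) return(list())
  if (all(!flags)) return(list(c(1L, n)))
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  runs <- Map(c, starts[!r$values], ends[!r$values])
  # merge the wrap-around run
  if (!flags[1] && !flags[n] && length(runs) > 1L) {
    first <- runs[[1]]; last <- runs[[length(runs)]]
    runs[[1]] <- c(last[1], first[2])
    runs[[length(runs)]] <- NULL
  }
  runs
}

run_midpoint_index <- function(contour, start, end) {
  # index at (floor of) the run's middle arc-length position
  n <- nrow(contour$points)
  idx <- cyclic_indices(start, end, n)
  arc <- contour$arc_um[idx]
  if (end < start) {   # unwrap
    wrap <- idx < start
    arc[wrap] <- arc[wrap] + contour$perimeter_um
  }
  mid <- arc[1] + (arc[length(arc)] - arc[1]) / 2
  idx[max(which(arc <= mid))]
}

#' Partition a flagged contour into protruding and non-protruding segments
#'
#' Maximal cyclic runs of non-protruding points with arc span at least
#' `min_nonprotruding_um` become non-protruding segments. Each contour arc
#' between the midpoints of two adjacent qualifying runs that contains at
#' least one protruding point becomes one protruding region, so every bump
#' takes half of each flanking quiet stretch with it.
#'
#' @param flags Logical vector from [flag_contour_points()].
#' @param contour The portal contour the flags refer to.
#' @param min_nonprotruding_um Minimum run span to qualify (um), default 10.
#' @param portal_id Identifier stamped into the outputs.
#' @return `list(regions = <list>, segments = <list>)`. Each region has
#'   `start_index`/`end_index` (inclusive, wrap-around allowed) and
#'   `contour_length_um`; each segment has the run bounds and `length_um`.
#'   With no qualifying run the whole contour is a single protruding region
#'   (or, with no protruding point at all, a single non-protruding segment).
#' @export
partition_segments <- function(flags, contour, min_nonprotruding_um = 10,
                               portal_id = 1L) {
  n <- nrow(contour$points)
  stopifnot(length(flags) == n)
  whole_region <- list(list(portal_id = portal_id, start_index = 1L,
                            end_index = n,
                            contour_length_um = contour$perimeter_um,
                            whole_contour = TRUE))
  whole_segment <- list(list(portal_id = portal_id, start_index = 1L,
                             end_index = n, length_um = contour$perimeter_um))
  if (all(!flags)) return(list(regions = list(), segments = whole_segment))
  runs <- nonprotruding_runs(flags)
  spans <- vapply(runs, function(r) arc_span_um(contour, r[1], r[2]), numeric(1))
  qual <- runs[spans >= min_nonprotruding_um]
  if (!length(qual)) return(list(regions = whole_region, segments = list()))
  qual <- qual[order(vapply(qual, `[[`, integer(1), 1L))]
  k <- length(qual)
  mids <- vapply(qual, function(r) run_midpoint_index(contour, r[1], r[2]),
                 integer(1))
  segments <- lapply(seq_len(k), function(i) {
    list(portal_id = portal_id, start_index = qual[[i]][1],
         end_index = qual[[i]][2],
         length_um = arc_span_um(contour, qual[[i]][1], qual[[i]][2]))
  })
  regions <- list()
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    gap <- cyclic_indices(qual[[i]][2] %% n + 1L,
                          (qual[[j]][1] - 2L) %% n + 1L, n)
    # skip gaps that are pure sub-threshold quiet stretches
    if (i == j || any(flags[gap])) {
      regions[[length(regions) + 1L]] <- list(
        portal_id = portal_id,
        start_index = mids[i], end_index = mids[j],
        contour_length_um = if (i == j) contour$perimeter_um else
          arc_span_um(contour, mids[i], mids[j]))
    }
  }
  list(regions = regions, segments = segments)
}

#' Build the closed polygon of a protruding region
#'
#' The region polygon is its contour arc closed by the straight chord from
#' the arc's end back to its start. The area counts only polygon pixels
#' inside the portal mask (the protrusion is portal tissue), in um^2; the
#' contour length is the arc alone, chord excluded. A self-intersecting
#' polygon (chord crossing the arc) falls back to the portal pixels inside
#' the arc's convex hull and is flagged degenerate.
#'
#' @param region A region from [partition_segments()].
#' @param portal The parent `portal_region`.
#' @param scale A [pixel_scale()].
#' @return The region, augmented with `arc_points`, `polygon`, `pixels`
#'   (n x 2 row/col matrix), `area_um2` and `degenerate`.
#' @export
build_polygon <- function(region, portal, scale = pixel_scale()) {
  scale <- as_pixel_scale(scale)
  ctr <- portal$contour
  n <- nrow(ctr$points)
  idx <- cyclic_indices(region$start_index, region$end_index, n)
  pts <- ctr$points[idx, , drop = FALSE]
  region$arc_points <- pts
  region$polygon <- pts
  m <- nrow(pts)
  degenerate <- FALSE
  if (m >= 4L && !isTRUE(region$whole_contour)) {
    p1 <- pts[m, ]; p2 <- pts[1, ]   # the closing chord
    for (s in 2:(m - 2L)) {
      if (segments_intersect(p1, p2, pts[s, ], pts[s + 1L, ])) {
        degenerate <- TRUE
        break
      }
    }
  }
  poly <- if (degenerate) {
    h <- chull(pts[, 2], pts[, 1])
    pts[h, , drop = FALSE]
  } else pts
  px <- if (nrow(poly) >= 3L) rasterize_polygon(poly, dim(portal$mask)) else
    matrix(integer(), 0, 2)
  if (nrow(px)) px <- px[portal$mask[px] != 0, , drop = FALSE]
  region$pixels <- px
  region$area_um2 <- nrow(px) * scale$microns_per_pixel^2
  region$degenerate <- degenerate
  region
}

#' Propose candidate infiltrated regions on one portal
#'
#' Runs the chord test, partitions the contour, and builds region polygons.
#'
#' @param portal A refined `portal_region`.
#' @param scale A [pixel_scale()].
#' @param window_um,depth_min_um,guard_px Chord-test parameters, see
#'   [flag_contour_points()].
#' @param min_nonprotruding_um See [partition_segments()].
#' @return `list(regions, segments, flags)`; regions carry polygons and
#'   sequential `region_id`s, segments sequential `segment_id`s.
#' @export
propose_regions <- function(portal, scale = pixel_scale(), window_um = 50,
                            depth_min_um = 3, guard_px = 2,
                            min_nonprotruding_um = 10) {
  scale <- as_pixel_scale(scale)
  flags <- flag_contour_points(portal, scale, window_um, depth_min_um, guard_px)
  parts <- partition_segments(flags, portal$contour, min_nonprotruding_um,
                              portal_id = portal$id)
  parts$regions <- lapply(seq_along(parts$regions), function(i) {
    r <- build_polygon(parts$regions[[i]], portal, scale)
    r$region_id <- i
    r
  })
  parts$segments <- lapply(seq_along(parts$segments), function(i) {
    s <- parts$segments[[i]]
    s$segment_id <- i
    s$arc_points <- portal$contour$points[
      cyclic_indices(s$start_index, s$end_index, nrow(portal$contour$points)),
      , drop = FALSE]
    s
  })
  parts$flags <- flags
  parts
}
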