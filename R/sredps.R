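## Structurally-refined portal segmentation: bile-duct co-occurrence
## confirmation, periportal lymphocyte clustering, Delaunay boundary
## refinement.

new_portal_region <- function(id, mask, contour, confirmed = NA) {
  structure(list(
    id = id,
    mask = mask,
    contour = contour,
    perimeter_um = contour$perimeter_um,
    confirmed = confirmed
  ), class = "portal_region")
}

#' @export
print.portal_region <- function(x, ...) {
  cat(sprintf("<portal_region %s: %d px, perimeter %.1f um, confirmed: %s>\n",
              x$id, sum(x$mask), x$perimeter_um, x$confirmed))
  invisible(x)
}

#' Split a portal mask into candidate portal regions
#'
#' One region per 8-connected component of the portal mask with area at
#' least `min_area_um2`, each carrying its own full-scene mask and outer
#' contour. Confirmation status is left undetermined until
#' [confirm_portals()] is applied.
#'
#' @param portal_mask Binary matrix.
#' @param scale A [pixel_scale()].
#' @param min_area_um2 Minimum component area (um^2).
#' @return List of `portal_region` objects.
#' @export
portal_regions <- function(portal_mask, scale = pixel_scale(), min_area_um2 = 100) {
  scale <- as_pixel_scale(scale)
  if (!any(portal_mask != 0)) return(list())
  lab <- label_components(portal_mask)
  px_area <- tabulate(lab[lab > 0])
  keep <- which(px_area * scale$microns_per_pixel^2 >= min_area_um2)
  oc <- EBImage::ocontour(lab)
  out <- list()
  for (id in keep) {
    pts <- oc[[id]] + 1
    if (is.null(pts) || nrow(pts) < 3L) next
    ctr <- new_contour(smooth_closed(pts, 5L), scale)
    m <- matrix(0L, nrow(portal_mask), ncol(portal_mask))
    m[lab == id] <- 1L
    out[[length(out) + 1L]] <- new_portal_region(length(out) + 1L, m, ctr)
  }
  out
}

#' Confirm portal candidates by bile-duct co-occurrence
#'
#' Portal tracts contain bile ducts; central veins do not. A candidate is
#' confirmed when at least one bile-duct pixel lies inside the component or
#' within `tolerance_um` of it (the tolerance absorbs small misalignment
#' between the two segmentation branches). Unconfirmed components should be
#' treated as central veins and excluded from all downstream analysis.
#'
#' @param portals List of `portal_region` objects (see [portal_regions()]).
#' @param bile_duct_mask Binary matrix, same shape as the portal mask.
#' @param scale A [pixel_scale()].
#' @param tolerance_um Dilation tolerance (um), default 20.
#' @return The input list with `confirmed` set on each region.
#' @export
confirm_portals <- function(portals, bile_duct_mask, scale = pixel_scale(),
                            tolerance_um = 20) {
  scale <- as_pixel_scale(scale)
  if (!length(portals)) return(portals)
  tol_px <- um_to_px(tolerance_um, scale)
  duct_idx <- which(bile_duct_mask != 0)
  for (i in seq_along(portals)) {
    if (!length(duct_idx)) {
      portals[[i]]$confirmed <- FALSE
      next
    }
    d <- EBImage::imageData(EBImage::distmap(1L - portals[[i]]$mask))
    portals[[i]]$confirmed <- any(d[duct_idx] <= tol_px)
  }
  portals
}

#' Centroids of mask components
#'
#' @param mask Binary matrix.
#' @return n x 2 matrix of (row, col) component centroids (px).
#' @export
mask_centroids <- function(mask) {
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L) return(matrix(numeric(), 0, 2))
  idx <- which(lab > 0)
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  g <- lab[idx]
  cbind(tapply(rr, g, mean), tapply(cc, g, mean))
}

#' Density-based spatial clustering (DBSCAN)
#'
#' Plain DBSCAN over point coordinates: core points have at least
#' `min_pts` neighbours (the point itself included) within `eps`; clusters
#' are the density-connected sets; the rest is noise.
#'
#' @param points n x 2 coordinate matrix (any consistent unit).
#' @param eps Neighbourhood radius, same unit as `points`.
#' @param min_pts Minimum neighbourhood size for a core point.
#' @return Integer vector of cluster ids (0 = noise).
#' @export
dbscan_points <- function(points, eps, min_pts) {
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  d2 <- outer(points[, 1], points[, 1], "-")^2 + outer(points[, 2], points[, 2], "-")^2
  nb <- d2 <= eps^2
  deg <- rowSums(nb)
  core <- deg >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      reach <- which(nb[j, ] & labels == 0L)
      if (length(reach)) {
        labels[reach] <- cl
        queue <- c(queue, reach[core[reach]])
      }
    }
  }
  labels
}

#' Cluster periportal lymphocytes around one portal
#'
#' Lymphocyte centroids inside the portal or within `band_um` of its border
#' are clustered with DBSCAN (radius `eps_um`, minimum size `min_pts`).
#' A cluster is *infiltrating* when at least one member lies inside the
#' portal mask or within `touch_um` of it; only infiltrating clusters are
#' returned, since only lymphocytes continuous with the portal tract should
#' drive boundary refinement.
#'
#' @param centroids n x 2 matrix of lymphocyte centroids (row, col), px.
#' @param portal A `portal_region`.
#' @param scale A [pixel_scale()].
#' @param eps_um DBSCAN radius (um), default 25 (one hepatocyte diameter).
#' @param min_pts DBSCAN minimum neighbourhood size, default 3.
#' @param band_um Search band around the portal border (um), default 50.
#' @param touch_um Contact tolerance to the portal (um), default 7.
#' @return List of clusters, each `list(points = <m x 2 px matrix>,
#'   touches_portal = TRUE)`.
#' @export
cluster_periportal_lymphocytes <- function(centroids, portal,
                                           scale = pixel_scale(),
                                           eps_um = 25, min_pts = 3,
                                           band_um = 50, touch_um = 7) {
  scale <- as_pixel_scale(scale)
  if (is.null(centroids) || nrow(centroids) == 0L) return(list())
  d_out <- EBImage::imageData(EBImage::distmap(1L - portal$mask))
  ri <- pmin(pmax(round(centroids[, 1]), 1L), nrow(portal$mask))
  ci <- pmin(pmax(round(centroids[, 2]), 1L), ncol(portal$mask))
  dist_px <- d_out[cbind(ri, ci)]          # 0 inside the portal
  in_band <- dist_px <= um_to_px(band_um, scale)
  pts <- centroids[in_band, , drop = FALSE]
  if (nrow(pts) == 0L) return(list())
  labels <- dbscan_points(pts * scale$microns_per_pixel, eps = eps_um,
                          min_pts = min_pts)
  touch_px <- um_to_px(touch_um, scale)
  touching <- dist_px[in_band] <= touch_px
  out <- list()
  for (cl in setdiff(unique(labels), 0L)) {
    member <- labels == cl
    if (any(touching[member])) {
      out[[length(out) + 1L]] <- list(points = pts[member, , drop = FALSE],
                                      touches_portal = TRUE)
    }
  }
  out
}

delaunay_triangles <- function(points) {
  # triangles as a list of 3 x 2 (row, col) matrices
  dd <- deldir::deldir(x = points[, 2], y = points[, 1], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  lapply(tl, function(tr) cbind(tr$y, tr$x))
}

#' Refine a portal boundary through infiltrating lymphocytes
#'
#' Member points of all infiltrating clusters are pooled and Delaunay
#' triangulated; triangles with any edge longer than `max_edge_um` (the
#' minimum hepatocyte cell size, 20 um) are discarded; the remaining
#' triangles are filled and merged into the portal mask with a bitwise OR.
#' The connected component containing the original portal is kept and its
#' contour re-extracted. The output mask is always a superset of the input
#' mask.
#'
#' @param portal A confirmed `portal_region`.
#' @param clusters Clusters from [cluster_periportal_lymphocytes()].
#' @param scale A [pixel_scale()].
#' @param max_edge_um Triangle edge cutoff (um), default 20.
#' @return A refined `portal_region` (unchanged if fewer than 3 points are
#'   available or no triangle survives the edge filter).
#' @export
refine_portal_boundary <- function(portal, clusters, scale = pixel_scale(),
                                   max_edge_um = 20) {
  scale <- as_pixel_scale(scale)
  pts <- do.call(rbind, lapply(clusters, `[[`, "points"))
  if (is.null(pts) || nrow(pts) < 3L) return(portal)
  pts <- unique(pts)
  if (nrow(pts) < 3L) return(portal)
  tris <- tryCatch(delaunay_triangles(pts), error = function(e) list())
  if (!length(tris)) return(portal)
  max_edge_px <- um_to_px(max_edge_um, scale)
  keep <- vapply(tris, function(tr) {
    e <- c(sqrt(sum((tr[1, ] - tr[2, ])^2)),
           sqrt(sum((tr[2, ] - tr[3, ])^2)),
           sqrt(sum((tr[3, ] - tr[1, ])^2)))
    max(e) <= max_edge_px
  }, logical(1))
  tris <- tris[keep]
  if (!length(tris)) return(portal)
  merged <- portal$mask
  for (tr in tris) {
    px <- rasterize_polygon(tr, dim(merged))
    if (nrow(px)) merged[px] <- 1L
  }
  merged <- merged | portal$mask
  lab <- label_components(merged)
  orig_label <- lab[which(portal$mask != 0)[1]]
  m <- matrix(0L, nrow(merged), ncol(merged))
  m[lab == orig_label] <- 1L
  ctrs <- extract_contours(m, scale, min_area_um2 = 0)
  if (!length(ctrs)) return(portal)
  per <- vapply(ctrs, `[[`, numeric(1), "perimeter_um")
  out <- new_portal_region(portal$id, m, ctrs[[which.max(per)]], portal$confirmed)
  attr(out, "triangles") <- tris   # retained triangles, for auditing
  out
}
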