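## Detection of hepatocytes enclosed by lymphocytes near the portal border.

#' Find lymphocyte-enclosed hepatocytes around a portal
#'
#' Hepatocyte pixels within `band_um` of the (refined) portal border are
#' split into cell instances by a watershed on the distance transform
#' (maxima closer than `marker_sep_um` merge into one marker). Each cell is
#' dilated by `dilate_um` and the lymphocyte centroids falling inside the
#' dilated footprint become its neighbours. Neighbour bearings from the
#' cell centroid are binned into eight 45-degree sectors (sector 0 centred
#' on the +col axis, angles counter-clockwise with y up); a cell is
#' *enclosed* when more than five of the eight sectors are occupied.
#'
#' @param scene A [scene_masks()] object.
#' @param portal A `portal_region`.
#' @param scale A [pixel_scale()].
#' @param lymph_centroids Optional precomputed n x 2 (row, col) lymphocyte
#'   centroids; derived from the lymphocyte mask when `NULL`.
#' @param band_um Band around the portal border (um), default 25.
#' @param dilate_um Cell dilation radius for neighbour search (um),
#'   default 25.
#' @param marker_sep_um Minimum watershed marker separation (um), default 10.
#' @return List of cells, each `list(centroid, n_sectors, neighbor_idx,
#'   enclosed)`; `neighbor_idx` indexes into the lymphocyte centroid matrix
#'   (returned as attribute `lymph_centroids`).
#' @export
find_enclosed_hepatocytes <- function(scene, portal, scale = scene$scale,
                                      lymph_centroids = NULL,
                                      band_um = 25, dilate_um = 25,
                                      marker_sep_um = 10) {
  scale <- as_pixel_scale(scale)
  if (!any(scene$hepatocyte != 0)) {
    out <- list()
    attr(out, "lymph_centroids") <- matrix(numeric(), 0, 2)
    return(out)
  }
  if (is.null(lymph_centroids)) lymph_centroids <- mask_centroids(scene$lymphocyte)
  nr <- nrow(portal$mask); nc <- ncol(portal$mask)
  d_out <- EBImage::imageData(EBImage::distmap(1L - portal$mask))
  band <- scene$hepatocyte != 0 & d_out <= um_to_px(band_um, scale)
  out <- list()
  attr(out, "lymph_centroids") <- lymph_centroids
  if (!any(band)) return(out)
  dm <- EBImage::distmap(band)
  ws <- EBImage::imageData(EBImage::watershed(
    dm, tolerance = 1, ext = max(1L, round(um_to_px(marker_sep_um, scale)))))
  dilate_px <- um_to_px(dilate_um, scale)
  n_cells <- max(ws)
  idx_all <- which(ws > 0)
  rr <- ((idx_all - 1L) %% nr) + 1L
  cc <- ((idx_all - 1L) %/% nr) + 1L
  gg <- ws[idx_all]
  for (g in seq_len(n_cells)) {
    sel <- gg == g
    if (!any(sel)) next
    cr <- rr[sel]; ccol <- cc[sel]
    centroid <- c(mean(cr), mean(ccol))
    if (nrow(lymph_centroids)) {
      near_box <- lymph_centroids[, 1] >= min(cr) - dilate_px &
                  lymph_centroids[, 1] <= max(cr) + dilate_px &
                  lymph_centroids[, 2] >= min(ccol) - dilate_px &
                  lymph_centroids[, 2] <= max(ccol) + dilate_px
      cand <- which(near_box)
    } else cand <- integer(0)
    if (length(cand)) {
      d2 <- outer(lymph_centroids[cand, 1], cr, "-")^2 +
            outer(lymph_centroids[cand, 2], ccol, "-")^2
      mind <- sqrt(apply(d2, 1, min))
      nb <- cand[mind <= dilate_px]
    } else nb <- integer(0)
    if (length(nb)) {
      ang <- atan2(-(lymph_centroids[nb, 1] - centroid[1]),
                   lymph_centroids[nb, 2] - centroid[2]) * 180 / pi
      sector <- floor(((ang + 22.5) %% 360) / 45)
      n_sectors <- length(unique(sector))
    } else n_sectors <- 0L
    out[[length(out) + 1L]] <- list(
      centroid = centroid,
      n_sectors = n_sectors,
      neighbor_idx = nb,
      enclosed = n_sectors > 5L
    )
  }
  attr(out, "lymph_centroids") <- lymph_centroids
  out
}
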