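#' Assemble aligned scene masks
#'
#' Bundles the five per-class segmentation masks of one scene, an optional
#' grayscale intensity image, and the pixel scale. All grids must share one
#' shape; masks are binarised (any non-zero value becomes 1), so label
#' images can be passed directly.
#'
#' Matrices follow the package-wide convention: `[row, col]`, 1-based,
#' origin at the top-left, row increasing downwards.
#'
#' @param portal,bile_duct,bile_ductule,hepatocyte,lymphocyte Binary matrices
#'   (or `NULL` for the optional classes, replaced by empty grids).
#' @param intensity Optional numeric matrix (grayscale), same shape.
#' @param scale A [pixel_scale()].
#' @return An object of class `scene_masks`.
#' @export
scene_masks <- function(portal, bile_duct = NULL, bile_ductule = NULL,
                        hepatocyte = NULL, lymphocyte = NULL,
                        intensity = NULL, scale = pixel_scale()) {
  scale <- as_pixel_scale(scale)
  if (!is.matrix(portal)) stop("`portal` must be a matrix")
  shp <- dim(portal)
  empty <- matrix(0L, shp[1], shp[2])
  binarise <- function(m, name) {
    if (is.null(m)) return(empty)
    if (!is.matrix(m)) stop(sprintf("`%s` must be a matrix", name))
    if (!identical(dim(m), shp)) {
      stop(sprintf("mask shape mismatch: `%s` is %dx%d but `portal` is %dx%d",
                   name, nrow(m), ncol(m), shp[1], shp[2]))
    }
    out <- matrix(0L, shp[1], shp[2])
    out[m != 0] <- 1L
    out
  }
  if (!is.null(intensity)) {
    if (!is.matrix(intensity) || !identical(dim(intensity), shp)) {
      stop(sprintf("intensity image shape (%s) does not match portal mask shape (%s)",
                   paste(dim(intensity), collapse = "x"),
                   paste(shp, collapse = "x")))
    }
  }
  structure(list(
    portal       = binarise(portal, "portal"),
    bile_duct    = binarise(bile_duct, "bile_duct"),
    bile_ductule = binarise(bile_ductule, "bile_ductule"),
    hepatocyte   = binarise(hepatocyte, "hepatocyte"),
    lymphocyte   = binarise(lymphocyte, "lymphocyte"),
    intensity    = intensity,
    scale        = scale
  ), class = "scene_masks")
}

#' @export
print.scene_masks <- function(x, ...) {
  cat(sprintf("<scene_masks %dx%d px @ %g um/px>\n",
              nrow(x$portal), ncol(x$portal), x$scale$microns_per_pixel))
  for (nm in c("portal", "bile_duct", "bile_ductule", "hepatocyte", "lymphocyte")) {
    cat(sprintf("  %-12s %d foreground px\n", nm, sum(x[[nm]])))
  }
  cat(sprintf("  intensity    %s\n", if (is.null(x$intensity)) "absent" else "present"))
  invisible(x)
}

#' Read a single-channel mask or intensity image
#'
#' Reads PNG or TIFF. Multi-channel images are collapsed to one channel by
#' averaging. Returns a numeric matrix `[row, col]`.
#'
#' @param path File path ending in .png, .tif or .tiff.
#' @return Numeric matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, " (use PNG or TIFF)")
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a binary mask as PNG
#'
#' @param mask Binary matrix.
#' @param path Output .png path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(ifelse(mask != 0, 1, 0), target = path)
  invisible(path)
}

#' Load a scene from image files
#'
#' @param paths Named list/vector with entries `portal`, and optionally
#'   `bile_duct`, `bile_ductule`, `hepatocyte`, `lymphocyte`, `intensity`.
#' @param scale A [pixel_scale()] or um/px number.
#' @return A [scene_masks()] object.
#' @export
load_scene <- function(paths, scale = pixel_scale()) {
  paths <- as.list(paths)
  if (is.null(paths$portal)) stop("`paths` must contain a `portal` entry")
  get <- function(nm) if (is.null(paths[[nm]])) NULL else read_mask(paths[[nm]])
  scene_masks(
    portal       = get("portal"),
    bile_duct    = get("bile_duct"),
    bile_ductule = get("bile_ductule"),
    hepatocyte   = get("hepatocyte"),
    lymphocyte   = get("lymphocyte"),
    intensity    = get("intensity"),
    scale        = scale
  )
}

#' Save a scene's masks as PNG files
#'
#' Writes one PNG per mask (plus the intensity image if present) into `dir`,
#' named `portal.png`, `bile_duct.png`, ... Round-trips pixel-identically
#' with [load_scene()] for binary masks.
#'
#' @param scene A [scene_masks()] object.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
save_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "scene_masks"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- c()
  for (nm in c("portal", "bile_duct", "bile_ductule", "hepatocyte", "lymphocyte")) {
    p <- file.path(dir, paste0(nm, ".png"))
    write_mask(scene[[nm]], p)
    out[nm] <- p
  }
  if (!is.null(scene$intensity)) {
    p <- file.path(dir, "intensity.png")
    png::writePNG(pmin(pmax(scene$intensity, 0), 1), target = p)
    out["intensity"] <- p
  }
  invisible(out)
}
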