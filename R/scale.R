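#' Pixel scale of a scene
#'
#' A scene's physical resolution in micrometres per pixel. Every measurement
#' the package reports (lengths, areas, densities) is expressed in
#' micrometre units through this object. Typical 40X whole-slide scans are
#' around 0.25 um/px; the value must come from the scanner metadata and is
#' therefore always configurable.
#'
#' @param microns_per_pixel Strictly positive number, um/px.
#' @return An object of class `pixel_scale`.
#' @examples
#' s <- pixel_scale(0.25)
#' um_to_px(20, s) # 80
#' @export
pixel_scale <- function(microns_per_pixel = 0.25) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("`microns_per_pixel` must be a single strictly positive number")
  }
  structure(list(microns_per_pixel = as.numeric(microns_per_pixel)),
            class = "pixel_scale")
}

#' @export
print.pixel_scale <- function(x, ...) {
  cat(sprintf("<pixel_scale: %g um/px>\n", x$microns_per_pixel))
  invisible(x)
}

as_pixel_scale <- function(scale) {
  if (inherits(scale, "pixel_scale")) return(scale)
  pixel_scale(scale)
}

#' Convert between micrometres and pixels
#'
#' @param length_um,length_px Non-negative lengths.
#' @param scale A [pixel_scale()] (or a bare um/px number).
#' @return Numeric length in the other unit.
#' @export
um_to_px <- function(length_um, scale) {
  scale <- as_pixel_scale(scale)
  if (any(length_um < 0, na.rm = TRUE)) stop("lengths must be non-negative")
  length_um / scale$microns_per_pixel
}

#' @rdname um_to_px
#' @export
px_to_um <- function(length_px, scale) {
  scale <- as_pixel_scale(scale)
  if (any(length_px < 0, na.rm = TRUE)) stop("lengths must be non-negative")
  length_px * scale$microns_per_pixel
}
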