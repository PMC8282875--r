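#' Construct a TPEF slice
#'
#' A slice is the unit of processing: a 2D matrix of 8-bit photon counts with
#' lateral pixel-size metadata. Stored as a plain numeric matrix of class
#' `msm_slice` with attributes `pixel_size_um` and (optionally) `depth_um`.
#'
#' @param pixels numeric matrix with values in \[0, 255\], at least 3x3.
#' @param pixel_size_um lateral sampling step in micrometres (default 0.39).
#' @param depth_um optional axial depth of the slice in micrometres.
#' @return an `msm_slice` (numeric matrix with metadata attributes).
#' @export
slice <- function(pixels, pixel_size_um = 0.39, depth_um = NULL) {
  pixels <- as_pixels(pixels)
  structure(pixels,
            pixel_size_um = pixel_size_um,
            depth_um = depth_um,
            class = c("msm_slice", class(pixels)))
}

# Validate/coerce a pixel matrix: numeric, finite, in [0,255], >= 3x3.
as_pixels <- function(pixels) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop("slice must be at least 3x3 pixels")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("slice contains non-finite values")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("slice values must lie in [0, 255]")
  pixels
}

#' @export
print.msm_slice <- function(x, ...) {
  cat(sprintf("<msm_slice> %d x %d px, pixel size %.3g um, range [%g, %g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um") %||% NA_real_,
              min(x), max(x)))
  invisible(x)
}

# Strip slice class but keep the values (internal helpers work on matrices).
as_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}
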