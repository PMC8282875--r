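#' Circular (Euclidean) structuring element
#'
#' Boolean disk of odd diameter: a pixel belongs to the element iff its
#' Euclidean distance from the centre is at most `(diameter_px - 1) / 2`.
#'
#' @param diameter_px odd positive integer diameter in pixels.
#' @return list with `mask` (logical matrix) and `diameter_px`.
#' @export
make_disk_se <- function(diameter_px) {
  diameter_px <- as.integer(diameter_px)
  if (length(diameter_px) != 1L || is.na(diameter_px) || diameter_px < 1L ||
      diameter_px %% 2L == 0L)
    stop("diameter_px must be an odd positive integer")
  r <- (diameter_px - 1L) / 2
  d <- seq(-r, r)
  mask <- outer(d^2, d^2, `+`) <= r^2 + 1e-9
  structure(list(mask = mask, diameter_px = diameter_px),
            class = "msm_structuring_element")
}

# Offsets (di, dj) of the TRUE pixels of a structuring element, centre origin.
se_offsets <- function(se) {
  r <- (se$diameter_px - 1L) %/% 2L
  w <- which(se$mask, arr.ind = TRUE)
  cbind(di = w[, 1L] - r - 1L, dj = w[, 2L] - r - 1L)
}

# Grayscale erosion / dilation with reflected borders (flat SE).
erode <- function(img, se) morph_extreme(img, se, max = FALSE)
dilate <- function(img, se) morph_extreme(img, se, max = TRUE)

morph_extreme <- function(img, se, max) {
  off <- se_offsets(se)
  # dilation uses the reflected SE; all shipped SEs are symmetric, but keep
  # the convention explicit for arbitrary masks
  if (max) off <- -off
  morph_extreme_cpp(as_matrix(img), off[, 1L], off[, 2L], max)
}

morph_open <- function(img, se) dilate(erode(img, se), se)
morph_close <- function(img, se) erode(dilate(img, se), se)

#' White and black top-hat transforms
#'
#' `white_tophat` = I - opening(I); `black_tophat` = closing(I) - I, both with
#' a flat structuring element and reflected borders.
#'
#' @param img numeric matrix (intensity image).
#' @param se structuring element from [make_disk_se()].
#' @return numeric matrix of the same shape (not clipped).
#' @export
white_tophat <- function(img, se) as_matrix(img) - morph_open(img, se)

#' @rdname white_tophat
#' @export
black_tophat <- function(img, se) morph_close(img, se) - as_matrix(img)

#' Plateau transform: I + white top-hat + black top-hat
#'
#' Adds both top-hats to the image so that speckled high-frequency regions
#' (the cytoplasm fluorescence) become contiguous plateaus. The sum is
#' computed in real arithmetic and saturate-clipped to \[0, 255\] so that the
#' 8-bit intensity contract used by all later stages holds.
#'
#' @inheritParams white_tophat
#' @param se structuring element; the default follows the pipeline's 11-px
#'   circular element.
#' @return numeric matrix in \[0, 255\], same shape as `img`.
#' @export
plateau_transform <- function(img, se = make_disk_se(11L)) {
  m <- as_matrix(as_pixels(img))
  clip255(m + white_tophat(m, se) + black_tophat(m, se))
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tiled CLAHE with bilinear interpolation between tile mappings. Each tile's
#' histogram is clipped at `clip_limit` times the uniform bin height before
#' the CDF is computed; clipped mass is redistributed equally over all bins.
#' Images whose sides are not multiples of `tile_px` are reflect-padded on
#' the bottom/right, processed, and cropped.
#'
#' @param img numeric matrix in \[0, 255\].
#' @param tile_px tile side length in pixels (>= 2), default 16.
#' @param clip_limit histogram clip factor (> 0) relative to the uniform bin
#'   height; large values disable clipping.
#' @return numeric matrix in \[0, 255\], same shape.
#' @export
clahe <- function(img, tile_px = 16L, clip_limit = 2.0) {
  tile_px <- as.integer(tile_px)
  if (is.na(tile_px) || tile_px < 2L) stop("tile_px must be >= 2")
  if (!is.finite(clip_limit) || clip_limit <= 0) stop("clip_limit must be > 0")
  m <- round(as_matrix(as_pixels(img)))
  nr <- nrow(m); nc <- ncol(m)
  t <- tile_px
  nrp <- ceiling(nr / t) * t
  ncp <- ceiling(nc / t) * t
  mp <- m[reflect_index(seq_len(nrp), nr), reflect_index(seq_len(ncp), nc),
          drop = FALSE]
  nty <- nrp %/% t; ntx <- ncp %/% t
  npx <- t * t
  clip_count <- max(1, clip_limit * npx / 256)

  # per-tile clipped-CDF mapping, stored as LUT[value + 1, tile_y, tile_x]
  lut <- array(0, dim = c(256L, nty, ntx))
  for (tx in seq_len(ntx)) {
    for (ty in seq_len(nty)) {
      tile <- mp[((ty - 1L) * t + 1L):(ty * t), ((tx - 1L) * t + 1L):(tx * t)]
      h <- tabulate(tile + 1L, nbins = 256L)
      hc <- pmin(h, clip_count)
      hc <- hc + (npx - sum(hc)) / 256
      lut[, ty, tx] <- cumsum(hc) / npx * 255
    }
  }

  # bilinear interpolation between the four surrounding tile mappings
  gy <- (seq_len(nrp) - 0.5) / t + 0.5
  gx <- (seq_len(ncp) - 0.5) / t + 0.5
  y0 <- floor(gy); wy <- gy - y0
  x0 <- floor(gx); wx <- gx - x0
  y0c <- pmin(pmax(y0, 1L), nty); y1c <- pmin(pmax(y0 + 1L, 1L), nty)
  x0c <- pmin(pmax(x0, 1L), ntx); x1c <- pmin(pmax(x0 + 1L, 1L), ntx)

  v <- mp + 1L
  Y0 <- matrix(y0c, nrp, ncp); Y1 <- matrix(y1c, nrp, ncp)
  X0 <- matrix(x0c, nrp, ncp, byrow = TRUE); X1 <- matrix(x1c, nrp, ncp, byrow = TRUE)
  WY <- matrix(wy, nrp, ncp); WX <- matrix(wx, nrp, ncp, byrow = TRUE)
  at <- function(Y, X) lut[cbind(as.vector(v), as.vector(Y), as.vector(X))]
  out <- (1 - WY) * (1 - WX) * at(Y0, X0) + (1 - WY) * WX * at(Y0, X1) +
         WY * (1 - WX) * at(Y1, X0) + WY * WX * at(Y1, X1)
  out <- matrix(out, nrp, ncp)[seq_len(nr), seq_len(nc), drop = FALSE]
  clip255(out)
}

#' Perona-Malik anisotropic diffusion
#'
#' Edge-preserving iterative smoothing over the 8-neighbourhood. Each
#' directional diffusion coefficient is `1 / (1 + (|dI| / K)^2)` where `dI` is
#' the directional difference of the current iterate, and the update is
#' `I <- I + lambda / 8 * sum(d * dI)` over the eight cardinal and diagonal
#' directions (equal weights, no diagonal distance correction). Borders are
#' reflected; intermediate arithmetic is real-valued and the result is clipped
#' to \[0, 255\] only at the end.
#'
#' @param img numeric matrix in \[0, 255\].
#' @param K edge-sensitivity constant (> 0), default 15.
#' @param lambda smoothing weight in (0, 1\], default 1.
#' @param iterations number of iterations (>= 0), default 5.
#' @return numeric matrix in \[0, 255\], same shape.
#' @export
anisotropic_diffuse <- function(img, K = 15, lambda = 1.0, iterations = 5L) {
  if (!is.finite(K) || K <= 0) stop("K must be > 0")
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L) stop("iterations must be >= 0")
  m <- as_matrix(as_pixels(img))
  if (iterations == 0L || lambda == 0) return(m)
  dirs <- cbind(di = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
                dj = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  for (it in seq_len(iterations)) {
    acc <- matrix(0, nrow(m), ncol(m))
    for (k in seq_len(8L)) {
      D <- shift_reflect(m, dirs[k, 1L], dirs[k, 2L]) - m
      acc <- acc + D / (1 + (D / K)^2)
    }
    m <- m + lambda / 8 * acc
  }
  clip255(m)
}

#' Full pre-processing chain
#'
#' Plateau transform, CLAHE, anisotropic diffusion, in that order, yielding
#' the edge-preserved image consumed by segmentation.
#'
#' @param img numeric matrix in \[0, 255\] (or [slice()]).
#' @param config pipeline configuration, see [msm_config()].
#' @return numeric matrix in \[0, 255\] (the diffused image).
#' @export
preprocess_slice <- function(img, config = msm_config()) {
  p <- config$preprocess
  se <- make_disk_se(p$tophat_diameter)
  ith <- plateau_transform(img, se)
  ice <- clahe(ith, p$clahe_tile, p$clahe_clip)
  anisotropic_diffuse(ice, K = p$diffusion$K, lambda = p$diffusion$lambda,
                      iterations = p$diffusion$iterations)
}
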