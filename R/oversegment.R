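#' Sobel gradient magnitude
#'
#' Convolves the image (kernel-flipped convolution, reflected borders) with
#' the two 3x3 Sobel kernels and returns the Euclidean norm of the responses.
#'
#' @param img numeric matrix.
#' @return non-negative numeric matrix of the same shape.
#' @export
sobel_gradient_magnitude <- function(img) {
  m <- as_matrix(img)
  hsx <- matrix(c(-1, 0, 1,
                  -2, 0, 2,
                  -1, 0, 1), 3L, 3L, byrow = TRUE)
  hsy <- t(hsx)
  dx <- conv2_reflect(m, hsx)
  dy <- conv2_reflect(m, hsy)
  sqrt(dx^2 + dy^2)
}

#' Gaussian smoothing of a gradient image
#'
#' Sampled, unit-sum-normalized 2D Gaussian kernel truncated at
#' `truncate * sigma`; `sigma = 0` returns the input unchanged.
#'
#' @param grad numeric matrix.
#' @param sigma standard deviation in pixels (>= 0).
#' @param truncate kernel half-width in units of sigma (default 4).
#' @return numeric matrix of the same shape.
#' @export
gaussian_smooth <- function(grad, sigma = 1.0, truncate = 4.0) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  m <- as_matrix(grad)
  if (sigma == 0) return(m)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  d <- seq(-r, r)
  g1 <- exp(-d^2 / (2 * sigma^2))
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)
  conv2_reflect(m, kern)
}

#' Watershed over-segmentation
#'
#' Flooding watershed from all regional minima of the gradient magnitude
#' image (8-connected basins). No watershed-line pixels are left: each pixel
#' is absorbed into the basin that reaches it first in ascending-gray
#' flooding order (ties in scanline order), so the labels form a complete
#' partition. Deterministic given the input.
#'
#' @param grad non-negative numeric matrix (gradient magnitude).
#' @return integer label matrix with labels `1..k`.
#' @export
watershed_partition <- function(grad) {
  m <- as_matrix(grad)
  if (anyNA(m) || any(!is.finite(m)) || min(m) < 0)
    stop("gradient magnitudes must be finite and non-negative")
  watershed_cpp(m)
}

#' Summarize a label partition as a superpixel graph
#'
#' Computes the per-label mean of the supplied intensity image, per-label
#' pixel areas, and the 4-neighbour label adjacency.
#'
#' @param labels integer label matrix (complete partition, labels `1..k`).
#' @param intensity numeric matrix of the same shape (typically the diffused
#'   image that the watershed gradient was derived from).
#' @return an `msm_superpixel_graph`: list with `labels`, `k`,
#'   `mean_intensity` (length `k`), `area_px` (length `k`), and `adjacency`
#'   (2-column integer matrix of unordered label pairs, `a < b`).
#' @export
summarize_superpixels <- function(labels, intensity) {
  if (!all(dim(labels) == dim(intensity)))
    stop("labels and intensity must have the same shape")
  labels <- as_label_matrix(labels)
  k <- max(labels)
  if (min(labels) < 1L) stop("labels must form a complete partition (1..k)")
  area <- tabulate(labels, nbins = k)
  if (any(area == 0L)) stop("labels must be consecutive 1..k")
  sums <- rowsum(as.vector(intensity), group = as.vector(labels))
  means <- as.vector(sums) / area
  structure(list(labels = labels, k = k, mean_intensity = means,
                 area_px = area, adjacency = label_adjacency(labels)),
            class = "msm_superpixel_graph")
}

as_label_matrix <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) stop("labels contain NA")
  labels
}

# Unordered 4-neighbour adjacency pairs (a < b) of a label map.
label_adjacency <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  a <- c(labels[-nr, ], labels[, -nc])
  b <- c(labels[-1L, ], labels[, -1L])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  pairs <- unique(cbind(lo, hi))
  dimnames(pairs) <- NULL
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}
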