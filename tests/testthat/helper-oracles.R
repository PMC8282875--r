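# Independent brute-force oracles, deliberately written as naive pixel loops
# so they share no code path with the package implementation.

# reflected (edge-inclusive) index, scalar
refl1 <- function(i, n) {
  if (n == 1) return(1L)
  j <- (i - 1) %% (2 * n)
  if (j < 0) j <- j + 2 * n
  as.integer(if (j < n) j + 1 else 2 * n - j)
}

# naive min/max filter over the TRUE offsets of a structuring element
brute_extreme <- function(img, se_mask, fun) {
  r <- (nrow(se_mask) - 1) / 2
  out <- img
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      vals <- c()
      for (a in seq_len(nrow(se_mask))) {
        for (b in seq_len(ncol(se_mask))) {
          if (!se_mask[a, b]) next
          vals <- c(vals, img[refl1(i + a - r - 1, nrow(img)),
                              refl1(j + b - r - 1, ncol(img))])
        }
      }
      out[i, j] <- fun(vals)
    }
  }
  out
}

brute_erode <- function(img, se_mask) brute_extreme(img, se_mask, min)
brute_dilate <- function(img, se_mask) brute_extreme(img, se_mask, max)

brute_white_tophat <- function(img, se_mask) {
  img - brute_dilate(brute_erode(img, se_mask), se_mask)
}
brute_black_tophat <- function(img, se_mask) {
  brute_erode(brute_dilate(img, se_mask), se_mask) - img
}

as_matrix_attrless <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

# a tiny fast phantom configuration used across tests
tiny_phantom_spec <- function(seed = 3L, ...) {
  phantom_spec(shape_px = c(128L, 128L), n_cells = 3L,
               cell_radius_px = c(16, 20), seed = seed, ...)
}

# rasterized centred disk mask
disk_mask <- function(radius, pad = 5L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  d2 <= radius^2
}

# build a merged-partition object directly (for combine_stages toys)
toy_partition <- function(labels, means, background_label) {
  structure(list(labels = labels, mean_intensity = means,
                 area_px = tabulate(labels, nbins = length(means)),
                 background_label = background_label,
                 membership = seq_along(means)),
            class = "msm_merged_partition")
}
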