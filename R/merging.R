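#' Flooding-based superpixel merge at a single threshold
#'
#' Starting from the region with the lowest current mean intensity and moving
#' in ascending order, adjacent regions whose absolute difference of current
#' means is at most `T_m` are merged; a merged region's mean is the
#' pixel-area-weighted mean of its members and is recomputed after every
#' merge. Passes repeat until no adjacent pair satisfies the criterion.
#' Deterministic: candidate ties are broken by the lowest label and a merged
#' region keeps the lowest member label. The result is invariant to label
#' renumbering up to relabelling.
#'
#' @param graph superpixel graph from [summarize_superpixels()], or any list
#'   with `mean_intensity`, `area_px`, `adjacency` and optionally `labels`.
#' @param T_m merge threshold (>= 0) on the mean-intensity difference.
#' @return an `msm_merged_partition`: list with `labels` (relabelled `1..m`;
#'   `NULL` when the graph carries no label map), `mean_intensity`, `area_px`,
#'   `background_label` (largest segment, ties to the lowest mean), and
#'   `membership` (new label for each input superpixel).
#' @export
flood_merge <- function(graph, T_m) {
  if (!is.finite(T_m) || T_m < 0) stop("T_m must be >= 0")
  k <- length(graph$mean_intensity)
  adj <- graph$adjacency
  if (is.null(adj)) adj <- matrix(integer(0), 0L, 2L)
  storage.mode(adj) <- "integer"
  roots <- flood_merge_cpp(k, as.numeric(graph$mean_intensity),
                           as.numeric(graph$area_px), adj, T_m)
  uroots <- sort(unique(roots))
  remap <- integer(k)
  remap[uroots] <- seq_along(uroots)
  membership <- remap[roots]
  m <- length(uroots)
  area <- as.vector(rowsum(as.numeric(graph$area_px), membership))
  sums <- as.vector(rowsum(graph$mean_intensity * graph$area_px, membership))
  means <- sums / area
  # background: maximal area, ties broken by the lowest mean
  ord <- order(-area, means)
  bg <- ord[1L]
  labels <- if (!is.null(graph$labels)) {
    matrix(membership[graph$labels], nrow(graph$labels), ncol(graph$labels))
  }
  structure(list(labels = labels, mean_intensity = means, area_px = area,
                 background_label = bg, membership = membership),
            class = "msm_merged_partition")
}

#' Object mask of a merged partition
#'
#' TRUE exactly where the label differs from the background label (the
#' largest contiguous segment after merging).
#'
#' @param part an `msm_merged_partition` with a label map.
#' @return logical matrix.
#' @export
object_mask <- function(part) {
  if (is.null(part$labels)) stop("partition carries no label map")
  part$labels != part$background_label
}

#' Combine the per-threshold merge stages
#'
#' Stage 1's object segments are adopted verbatim. At every later stage, a
#' non-background segment is adopted only if it lies entirely in the
#' accumulated background (segments overlapping any previously adopted object
#' by even one pixel are discarded whole), so previously extracted objects
#' are never decomposed or removed. Adopted segments keep their identity and
#' extent; the residual pixels form a single background segment with final
#' label 0.
#'
#' @param parts list of `msm_merged_partition` in processing order
#'   (descending threshold by default in [multistage_merge()]).
#' @param intensity numeric matrix used to attach per-segment mean
#'   intensities (including the background segment).
#' @param mode `"segment-clip"` (default): every non-background segment of
#'   stage `i` contributes its pixels that still lie in the accumulated
#'   background, realizing the pixelwise exclusive-disjunction/disjunction
#'   combination exactly — earlier objects keep every pixel and new object
#'   area is only admitted on background. `"segment-reject"`: a stage
#'   segment overlapping any previously adopted object by even one pixel is
#'   discarded whole.
#' @export
combine_stages <- function(parts, intensity,
                           mode = c("segment-clip", "segment-reject")) {
  mode <- match.arg(mode)
  stopifnot(length(parts) >= 1L)
  shp <- dim(parts[[1L]]$labels)
  for (p in parts) {
    if (is.null(p$labels) || !all(dim(p$labels) == shp))
      stop("all partitions must carry label maps of the same shape")
  }
  if (!all(dim(intensity) == shp)) stop("intensity shape mismatch")
  acc <- matrix(0L, shp[1L], shp[2L])
  stage_of <- integer(0)
  intermediates <- vector("list", length(parts))
  nseg <- 0L
  for (i in seq_along(parts)) {
    part <- parts[[i]]
    labs <- part$labels
    nlab <- length(part$mean_intensity)
    if (mode == "segment-reject") {
      # labels (other than background) overlapping accumulated objects
      overl <- unique(labs[acc > 0L])
      candidate <- setdiff(seq_len(nlab), c(part$background_label, overl))
    } else {
      # labels with at least one pixel on the accumulated background
      fresh <- unique(labs[acc == 0L])
      candidate <- setdiff(fresh, part$background_label)
    }
    if (length(candidate)) {
      candidate <- sort(candidate)
      remap <- integer(nlab)
      remap[candidate] <- nseg + seq_along(candidate)
      sel <- acc == 0L & remap[labs] > 0L
      acc[sel] <- remap[labs][sel]
      stage_of <- c(stage_of, rep.int(i, length(candidate)))
      nseg <- nseg + length(candidate)
    }
    intermediates[[i]] <- acc > 0L
  }
  av <- as.vector(acc)
  sums <- rowsum(as.vector(intensity), av)
  areas <- rowsum(rep(1, length(av)), av)
  present <- as.integer(rownames(sums))
  seg_mean <- numeric(nseg + 1L)
  seg_area <- numeric(nseg + 1L)
  seg_mean[present + 1L] <- sums / areas
  seg_area[present + 1L] <- areas
  structure(list(final_labels = acc, seg_mean = seg_mean, seg_area = seg_area,
                 stage_of = stage_of, intermediates = intermediates),
            class = "msm_multistage")
}

#' Stability index of the multi-stage merge
#'
#' Per pixel, the number of stages `i` in `1..(n-1)` at which the pixel is an
#' object both in the accumulated intermediate result of stage `i` and in the
#' single-threshold merge of stage `i + 1`. Per final segment the per-pixel
#' values are aggregated by their mean (default) or median; the background
#' segment is aggregated too (first entry).
#'
#' @param result `msm_multistage` from [combine_stages()].
#' @param parts the same list of partitions, in processing order (`n >= 2`).
#' @param aggregate `"mean"` or `"median"`.
#' @return list with `stability_px` (integer matrix, values `0..n-1`) and
#'   `stability_seg` (length `m + 1`, first entry = background segment).
#' @export
stability_map <- function(result, parts, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  n <- length(parts)
  if (n < 2L) stop("stability requires at least two stages")
  spx <- matrix(0L, nrow(result$final_labels), ncol(result$final_labels))
  for (i in seq_len(n - 1L)) {
    conj <- result$intermediates[[i]] & object_mask(parts[[i + 1L]])
    spx <- spx + conj
  }
  grp <- as.vector(result$final_labels)
  agg_fun <- if (aggregate == "mean") {
    function(v) mean(v)
  } else {
    function(v) stats::median(v)
  }
  vals <- tapply(as.vector(spx), grp, agg_fun)
  sseg <- numeric(length(result$seg_mean))
  sseg[as.integer(names(vals)) + 1L] <- as.numeric(vals)
  list(stability_px = spx, stability_seg = sseg)
}

#' Multi-stage merging driver
#'
#' Runs the flooding merge independently at every threshold of the ladder,
#' combines the stages in the configured order (descending thresholds by
#' default, so the highest-contrast objects are locked in first), and
#' computes the stability index.
#'
#' @param graph superpixel graph from [summarize_superpixels()].
#' @param intensity intensity image used for per-segment means (typically the
#'   diffused image).
#' @param thresholds strictly increasing positive merge thresholds; default
#'   `10 * (1:7)`.
#' @param order `"desc"` (default) or `"asc"` processing order.
#' @param stability_aggregate `"mean"` or `"median"`.
#' @param combine stage-combination mode, see [combine_stages()].
#' @return an `msm_multistage` result augmented with `stability_px`,
#'   `stability_seg`, `parts`, `thresholds` (in processing order) and
#'   `msm_max` (= number of thresholds).
#' @export
multistage_merge <- function(graph, intensity, thresholds = 10 * (1:7),
                             order = c("desc", "asc"),
                             stability_aggregate = c("mean", "median"),
                             combine = c("segment-clip", "segment-reject")) {
  order <- match.arg(order)
  stability_aggregate <- match.arg(stability_aggregate)
  combine <- match.arg(combine)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || any(!is.finite(thresholds)) ||
      any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing positive values")
  proc <- if (order == "desc") rev(thresholds) else thresholds
  parts <- lapply(proc, function(tm) flood_merge(graph, tm))
  res <- combine_stages(parts, intensity, mode = combine)
  if (length(parts) >= 2L) {
    st <- stability_map(res, parts, stability_aggregate)
  } else {
    st <- list(stability_px = 0L * res$final_labels,
               stability_seg = numeric(length(res$seg_mean)))
  }
  res$stability_px <- st$stability_px
  res$stability_seg <- st$stability_seg
  res$parts <- parts
  res$thresholds <- proc
  res$msm_max <- length(thresholds)
  res
}
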