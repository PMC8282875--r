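#' Run the full pipeline on one slice
#'
#' Pre-processing (plateau, CLAHE, diffusion), Sobel gradient + Gaussian
#' smoothing, watershed over-segmentation, multi-stage merging, and semantic
#' assignment. Deterministic: identical input and configuration give
#' identical output.
#'
#' @param img numeric matrix in \[0, 255\] or [slice()].
#' @param config [msm_config()].
#' @param quiet suppress per-stage log messages.
#' @return list with `preprocessed`, `gradient`, `watershed_labels`,
#'   `graph`, `msr` (multi-stage result), `sem` (semantic result),
#'   `class_map`, `features`, `counts` (per-stage segment counts), and
#'   `timings` (seconds per stage).
#' @export
run_slice <- function(img, config = msm_config(), quiet = FALSE) {
  m <- as_matrix(as_pixels(if (inherits(img, "msm_slice")) img else
    as_pixels(img)))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c(); t0 <- tic()

  pre <- preprocess_slice(m, config)
  timings["preprocess"] <- tic() - t0; t0 <- tic()

  grad <- sobel_gradient_magnitude(pre)
  gs <- gaussian_smooth(grad, config$oversegmentation$gaussian_sigma)
  ws <- watershed_partition(gs)
  src <- if (config$oversegmentation$mean_source == "raw") m else pre
  graph <- summarize_superpixels(ws, src)
  timings["oversegmentation"] <- tic() - t0; t0 <- tic()

  msr <- multistage_merge(graph, src,
                          thresholds = config$merging$thresholds,
                          order = config$merging$order,
                          stability_aggregate = config$merging$stability_aggregate,
                          combine = config$merging$combine)
  timings["merging"] <- tic() - t0; t0 <- tic()

  sem <- semantic_assign(msr, pre,
                         T_qual = config$semantics$tqual,
                         boundary_mode = config$semantics$boundary_mode,
                         perimeter = config$semantics$perimeter,
                         quiet = quiet)
  timings["semantic"] <- tic() - t0

  counts <- c(superpixels = graph$k,
              msm_segments = length(msr$seg_mean) - 1L,
              nucleus_candidates = nrow(sem$features),
              nuclei = length(sem$selected))
  if (!quiet) {
    message(sprintf(
      "pipeline: %d superpixels -> %d segments -> %d candidates -> %d nuclei (%.1fs)",
      counts[1L], counts[2L], counts[3L], counts[4L], sum(timings)))
  }
  list(preprocessed = pre, gradient = gs, watershed_labels = ws,
       graph = graph, msr = msr, sem = sem,
       class_map = sem$class_map, features = sem$features,
       counts = counts, timings = timings)
}

#' Quality-threshold sweep over a stack
#'
#' Runs the pipeline once per slice, then sweeps the relative quality
#' threshold over the configured grid (the candidate scores are reused, so
#' only the selection changes per threshold). Reports per-slice curves, the
#' per-slice argmax-Dice thresholds, their median, and the global argmax
#' computed from the object counts summed over slices.
#'
#' @param slices list of lists with `image` and `gt` (as produced by
#'   [generate_phantom()] / [depth_series()]).
#' @param config [msm_config()].
#' @param quiet passed to [run_slice()].
#' @return list with `curves` (one data.frame, column `slice` added),
#'   `per_slice_best`, `median_best`, `global_curve`, `global_best`.
#' @export
run_sweep <- function(slices, config = msm_config(), quiet = TRUE) {
  grid <- config$evaluation$sweep_grid
  curves <- list(); best <- numeric(length(slices))
  for (s in seq_along(slices)) {
    sl <- slices[[s]]
    if (!all(dim(sl$image) == dim(sl$gt$nucleus_labels)))
      stop("slice/GT shape mismatch")
    res <- run_slice(sl$image, config, quiet = quiet)
    sw <- threshold_sweep(res$features, res$msr$final_labels, sl$gt, grid)
    cv <- sw$curve
    cv$slice <- s
    curves[[s]] <- cv
    best[s] <- sw$best_threshold
  }
  curves <- do.call(rbind, curves)
  agg <- stats::aggregate(
    curves[c("TP", "TP_uncertain", "FP", "FN", "FN_uncertain")],
    by = list(threshold = curves$threshold), FUN = sum)
  tp <- agg$TP + agg$TP_uncertain
  agg$dice_objects <- 2 * tp / (2 * tp + agg$FP + agg$FN + agg$FN_uncertain)
  gbest <- agg$threshold[max(which(agg$dice_objects == max(agg$dice_objects)))]
  list(curves = curves, per_slice_best = best,
       median_best = stats::median(best),
       global_curve = agg, global_best = gbest)
}

#' Noise robustness experiment
#'
#' Adds Gaussian noise of each sigma (per seed) to the image, runs the full
#' pipeline at the configured fixed quality threshold, and reports object
#' counts, Dice, and PSNR per run.
#'
#' @param img clean input image.
#' @param gt ground truth (nucleus labels + certainty).
#' @param sigmas noise standard deviations (>= 0).
#' @param seeds RNG seeds (one run per sigma x seed).
#' @param config [msm_config()].
#' @param quiet passed to [run_slice()].
#' @return data.frame with one row per run: `sigma`, `seed`, `psnr_db`,
#'   `TP`, `TP_uncertain`, `FP`, `FN`, `FN_uncertain`, `dice`.
#' @export
run_noise_experiment <- function(img, gt, sigmas = c(0, 5, 10, 15, 20),
                                 seeds = 1:3, config = msm_config(),
                                 quiet = TRUE) {
  rows <- list()
  for (sg in sigmas) {
    for (sd in seeds) {
      nz <- add_noise_and_psnr(img, sigma = sg, seed = sd)
      res <- run_slice(nz$noisy, config, quiet = quiet)
      sel <- res$sem$selected
      pred <- matrix(0L, nrow(nz$noisy), ncol(nz$noisy))
      if (length(sel)) {
        keep <- res$msr$final_labels %in% sel
        pred[keep] <- res$msr$final_labels[keep]
      }
      cnt <- match_nuclei(pred, gt$nucleus_labels, gt$certainty)
      rows[[length(rows) + 1L]] <- data.frame(
        sigma = sg, seed = sd, psnr_db = nz$psnr_db,
        TP = cnt$TP, TP_uncertain = cnt$TP_uncertain, FP = cnt$FP,
        FN = cnt$FN, FN_uncertain = cnt$FN_uncertain,
        dice = dice(pred > 0L, gt$nucleus_labels > 0L))
      if (sg == 0) break  # sigma 0 is deterministic; one run suffices
    }
  }
  do.call(rbind, rows)
}
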