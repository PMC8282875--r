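#' Dice coefficient of two binary masks
#'
#' `DC = 2 TP / (2 TP + FP + FN)` computed pixelwise. Two empty masks are
#' defined to agree perfectly (`DC = 1`).
#'
#' @param pred_mask,gt_mask logical matrices of the same shape.
#' @return value in \[0, 1\].
#' @export
dice <- function(pred_mask, gt_mask) {
  if (!all(dim(pred_mask) == dim(gt_mask))) stop("shape mismatch")
  tp <- sum(pred_mask & gt_mask)
  fp <- sum(pred_mask & !gt_mask)
  fn <- sum(!pred_mask & gt_mask)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Object-level nucleus matching
#'
#' One-to-one greedy matching of predicted objects to ground-truth objects by
#' descending overlap area (ties by ascending ground-truth then predicted
#' label). Matched ground-truth objects count as true positives, split by
#' their certainty flag; unmatched predictions are false positives and
#' unmatched ground-truth objects false negatives (also split by certainty).
#'
#' @param pred_labels integer label matrix of predicted nuclei (0 = none).
#' @param gt_labels integer label matrix of ground-truth nuclei (0 = none).
#' @param certainty named character vector (`"certain"` / `"uncertain"`) per
#'   ground-truth label; missing labels default to `"certain"`.
#' @param min_overlap minimum shared pixel count for a valid match
#'   (default 1, i.e. any positive overlap).
#' @return list with counts `TP`, `TP_uncertain`, `FP`, `FN`, `FN_uncertain`
#'   and the `matches` data.frame (`gt`, `pred`, `overlap`).
#' @export
match_nuclei <- function(pred_labels, gt_labels, certainty = NULL,
                         min_overlap = 1L) {
  if (!all(dim(pred_labels) == dim(gt_labels))) stop("shape mismatch")
  gt_ids <- setdiff(sort(unique(as.vector(gt_labels))), 0L)
  pred_ids <- setdiff(sort(unique(as.vector(pred_labels))), 0L)
  cert <- stats::setNames(rep("certain", length(gt_ids)), gt_ids)
  if (!is.null(certainty)) {
    hit <- intersect(names(certainty), names(cert))
    cert[hit] <- certainty[hit]
  }
  both <- pred_labels > 0L & gt_labels > 0L
  matches <- data.frame(gt = integer(0), pred = integer(0),
                        overlap = integer(0))
  if (any(both)) {
    ov <- table(gt = gt_labels[both], pred = pred_labels[both])
    df <- as.data.frame(ov, stringsAsFactors = FALSE)
    df <- df[df$Freq >= min_overlap, ]
    df$gt <- as.integer(df$gt); df$pred <- as.integer(df$pred)
    df <- df[order(-df$Freq, df$gt, df$pred), ]
    used_gt <- logical(0); used_pred <- logical(0)
    for (r in seq_len(nrow(df))) {
      g <- as.character(df$gt[r]); p <- as.character(df$pred[r])
      if (isTRUE(used_gt[g]) || isTRUE(used_pred[p])) next
      used_gt[g] <- TRUE; used_pred[p] <- TRUE
      matches <- rbind(matches, data.frame(gt = df$gt[r], pred = df$pred[r],
                                           overlap = df$Freq[r]))
    }
  }
  tp_cert <- cert[as.character(matches$gt)]
  fn_ids <- setdiff(gt_ids, matches$gt)
  fn_cert <- cert[as.character(fn_ids)]
  list(TP = sum(tp_cert == "certain"),
       TP_uncertain = sum(tp_cert == "uncertain"),
       FP = length(setdiff(pred_ids, matches$pred)),
       FN = sum(fn_cert == "certain"),
       FN_uncertain = sum(fn_cert == "uncertain"),
       matches = matches)
}

#' Quality-threshold sweep
#'
#' Evaluates the nucleus selection over a grid of relative quality
#' thresholds: per threshold, object-level TP/FP/FN counts (certainty-split),
#' the pixelwise Dice coefficient including and excluding uncertain
#' ground-truth objects, and pixel accuracy. Returns the argmax-Dice
#' threshold (ties resolved toward the larger threshold).
#'
#' @param scores candidate score data.frame (`label`, `d`), e.g.
#'   `semantic_assign()$features`.
#' @param final_labels multi-stage segment label map (0 = background).
#' @param gt ground truth list with `nucleus_labels` and `certainty` (see
#'   [generate_phantom()]).
#' @param grid threshold grid; default 21 equidistant values 0.900..1.000.
#' @param use_uncertain which Dice variant decides the argmax (default TRUE:
#'   include uncertain objects).
#' @return list with `curve` (one row per threshold) and `best_threshold`.
#' @export
threshold_sweep <- function(scores, final_labels, gt,
                            grid = seq(0.900, 1.000, by = 0.005),
                            use_uncertain = TRUE) {
  if (!length(grid)) stop("grid must be non-empty")
  grid <- sort(grid)
  gt_mask_all <- gt$nucleus_labels > 0L
  unc_ids <- as.integer(names(gt$certainty)[gt$certainty == "uncertain"])
  unc_mask <- gt$nucleus_labels %in% unc_ids &
    gt$nucleus_labels > 0L
  dim(unc_mask) <- dim(gt$nucleus_labels)
  gt_cert <- gt$nucleus_labels
  gt_cert[unc_mask] <- 0L
  rows <- lapply(grid, function(tq) {
    sel <- select_nuclei(scores, tq)
    pred <- matrix(0L, nrow(final_labels), ncol(final_labels))
    if (length(sel)) {
      keep <- final_labels %in% sel
      pred[keep] <- final_labels[keep]
    }
    cnt <- match_nuclei(pred, gt$nucleus_labels, gt$certainty)
    pm <- pred > 0L
    dc_with <- dice(pm, gt_mask_all)
    dc_without <- dice(pm & !unc_mask, gt_cert > 0L)
    acc <- mean(pm == gt_mask_all)
    data.frame(threshold = tq, TP = cnt$TP, TP_uncertain = cnt$TP_uncertain,
               FP = cnt$FP, FN = cnt$FN, FN_uncertain = cnt$FN_uncertain,
               dice = dc_with, dice_certain = dc_without,
               pixel_accuracy = acc)
  })
  curve <- do.call(rbind, rows)
  dcol <- if (use_uncertain) curve$dice else curve$dice_certain
  best <- max(which(dcol == max(dcol)))  # ties -> larger threshold
  list(curve = curve, best_threshold = curve$threshold[best])
}

#' Segment registration between prediction and ground truth
#'
#' For every ground-truth object, the predicted segment maximizing the
#' shared pixel area (ties to the lowest predicted label); pairs whose
#' pairwise Dice coefficient falls below `min_dc` are dropped.
#'
#' @param pred_labels,gt_labels integer label matrices of the same shape.
#' @param min_dc minimum segment-specific Dice coefficient (default 0.75).
#' @return data.frame with `gt`, `pred`, `overlap`, `dc` (only retained
#'   pairs).
#' @export
register_segments <- function(pred_labels, gt_labels, min_dc = 0.75) {
  if (!all(dim(pred_labels) == dim(gt_labels))) stop("shape mismatch")
  gt_area <- table(gt_labels[gt_labels > 0L])
  pred_area <- table(pred_labels[pred_labels > 0L])
  both <- pred_labels > 0L & gt_labels > 0L
  out <- data.frame(gt = integer(0), pred = integer(0),
                    overlap = integer(0), dc = numeric(0))
  if (!any(both)) return(out)
  ov <- as.data.frame(table(gt = gt_labels[both], pred = pred_labels[both]),
                      stringsAsFactors = FALSE)
  ov <- ov[ov$Freq > 0L, ]
  ov$gt <- as.integer(ov$gt); ov$pred <- as.integer(ov$pred)
  for (g in sort(unique(ov$gt))) {
    sub <- ov[ov$gt == g, ]
    sub <- sub[order(-sub$Freq, sub$pred), ]
    p <- sub$pred[1L]; o <- sub$Freq[1L]
    dc <- 2 * o / (gt_area[[as.character(g)]] + pred_area[[as.character(p)]])
    if (dc >= min_dc)
      out <- rbind(out, data.frame(gt = g, pred = p, overlap = o, dc = dc))
  }
  out
}

#' Add Gaussian noise and report PSNR
#'
#' Pixelwise additive Gaussian noise, rounded and clipped to \[0, 255\],
#' with `PSNR = 10 log10(255^2 / MSE)` against the input (infinite for an
#' unchanged image). Reproducible via the seed.
#'
#' @param img numeric matrix in \[0, 255\].
#' @param sigma noise standard deviation (>= 0).
#' @param mu noise mean (default 0).
#' @param seed RNG seed.
#' @return list with `noisy` (matrix) and `psnr_db`.
#' @export
add_noise_and_psnr <- function(img, sigma, mu = 0, seed = 1L) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  m <- as_matrix(as_pixels(img))
  noisy <- if (sigma == 0 && mu == 0) m else with_seed(seed, {
    clip255(round(m + stats::rnorm(length(m), mean = mu, sd = sigma)))
  })
  mse <- mean((noisy - m)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(255^2 / mse)
  list(noisy = noisy, psnr_db = psnr)
}
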