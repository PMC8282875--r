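chain_graph <- function(means, areas = rep(1, length(means))) {
  k <- length(means)
  adj <- if (k > 1L) cbind(seq_len(k - 1L), 2:k) else matrix(integer(0), 0, 2)
  list(mean_intensity = means, area_px = areas, adjacency = adj,
       labels = NULL)
}

test_that("flood_merge follows the ascending flooding rule", {
  # T_m = 0 with distinct means: identity partition
  g <- chain_graph(c(10, 20, 30))
  expect_equal(length(flood_merge(g, 0)$mean_intensity), 3L)
  # T_m >= 255: everything merges
  expect_equal(length(flood_merge(g, 255)$mean_intensity), 1L)
  # hand simulation: means 10, 15, 30 at T_m = 10 -> {10,15} merge to 12.5,
  # |12.5 - 30| > 10, so two segments remain
  p <- flood_merge(chain_graph(c(10, 15, 30)), 10)
  expect_equal(sort(p$mean_intensity), c(12.5, 30))
  # area-weighted means: areas 3 and 1 -> (3*10 + 15)/4
  p2 <- flood_merge(chain_graph(c(10, 15, 30), areas = c(3, 1, 1)), 10)
  expect_equal(sort(p2$mean_intensity), c(11.25, 30))
})

test_that("flood_merge is invariant to label renumbering", {
  set.seed(8)
  grad <- gaussian_smooth(matrix(runif(30 * 30, 0, 255), 30L), 1)
  ws <- watershed_partition(grad)
  g <- summarize_superpixels(ws, grad)
  p <- flood_merge(g, 20)
  # permute labels and re-run
  k <- g$k
  perm <- sample(k)
  ws2 <- matrix(perm[ws], nrow(ws))
  g2 <- summarize_superpixels(ws2, grad)
  p2 <- flood_merge(g2, 20)
  expect_equal(length(p$mean_intensity), length(p2$mean_intensity))
  # identical partitions up to renaming: co-membership matrices agree
  expect_true(all((outer(as.vector(p$labels), as.vector(p$labels), "==")) ==
                  (outer(as.vector(p2$labels), as.vector(p2$labels), "=="))))
  # merging never increases the segment count
  expect_lte(length(flood_merge(g, 40)$mean_intensity),
             length(p$mean_intensity))
})

test_that("object_mask uses the largest segment, ties to the lowest mean", {
  lab <- matrix(1L, 4L, 4L)
  p <- toy_partition(lab, means = 50, background_label = 1L)
  expect_false(any(object_mask(p)))
  # two equal-area segments: the lower-mean one is background
  lab2 <- matrix(rep(c(1L, 2L), each = 8L), 4L)
  g <- summarize_superpixels(lab2, matrix(rep(c(80, 20), each = 8L), 4L))
  p2 <- flood_merge(g, 5)
  expect_equal(p2$background_label,
               which.min(p2$mean_intensity))
  expect_equal(sum(object_mask(p2)), 8L)
})

test_that("combine_stages accumulates objects per the XOR/OR scheme", {
  # n = 1: stage-1 objects adopted verbatim
  lab1 <- matrix(1L, 8L, 8L); lab1[2:4, 2:4] <- 2L
  p1 <- toy_partition(lab1, means = c(20, 90), background_label = 1L)
  int <- matrix(20, 8L, 8L); int[2:4, 2:4] <- 90
  r1 <- combine_stages(list(p1), int)
  expect_equal(sum(r1$final_labels > 0L), 9L)
  expect_equal(r1$seg_mean, c(20, 90))

  # disjoint object added at stage 2: union with two components
  lab2 <- matrix(1L, 8L, 8L); lab2[6:7, 6:7] <- 2L
  p2 <- toy_partition(lab2, means = c(25, 95), background_label = 1L)
  r2 <- combine_stages(list(p1, p2), int)
  expect_equal(length(r2$seg_mean) - 1L, 2L)
  expect_equal(sum(r2$final_labels > 0L), 13L)

  # stage-2 segment overlapping a stage-1 object by >= 1 px
  lab3 <- matrix(1L, 8L, 8L); lab3[3:6, 3:6] <- 2L
  p3 <- toy_partition(lab3, means = c(25, 95), background_label = 1L)
  rej <- combine_stages(list(p1, p3), int, mode = "segment-reject")
  # discarded whole; stage-1 object unchanged
  expect_equal(sum(rej$final_labels > 0L), 9L)
  expect_equal(unique(as.vector(rej$final_labels[2:4, 2:4])), 1L)
  clip <- combine_stages(list(p1, p3), int, mode = "segment-clip")
  # clipped: the non-overlapping part is adopted, stage-1 object unchanged
  expect_equal(unique(as.vector(clip$final_labels[2:4, 2:4])), 1L)
  expect_equal(sum(clip$final_labels > 0L), 9L + (16L - 4L))

  # monotone accumulation in both modes
  for (mode in c("segment-clip", "segment-reject")) {
    r <- combine_stages(list(p1, p3, p2), int, mode = mode)
    for (i in 2:3)
      expect_true(all(r$intermediates[[i]][r$intermediates[[i - 1L]]]))
  }
  expect_error(combine_stages(list(p1), matrix(0, 4L, 4L)))
})

test_that("stability counts stage conjunctions as printed", {
  int <- matrix(0, 8L, 8L)
  obj_at <- function(rows, cols, mean_obj = 90) {
    lab <- matrix(1L, 8L, 8L); lab[rows, cols] <- 2L
    toy_partition(lab, means = c(20, mean_obj), background_label = 1L)
  }
  # object present in every one of 7 stages -> per-pixel S = 6
  parts <- replicate(7, obj_at(2:4, 2:4), simplify = FALSE)
  res <- combine_stages(parts, int)
  st <- stability_map(res, parts)
  expect_equal(unique(as.vector(st$stability_px[2:4, 2:4])), 6L)
  expect_equal(unique(as.vector(st$stability_px[6:8, 6:8])), 0L)
  expect_equal(st$stability_seg[2L], 6)
  # object appearing only from stage 3 onward scores 4 (n = 7)
  parts2 <- c(replicate(2, obj_at(1, 1) , simplify = FALSE),
              replicate(5, obj_at(2:4, 2:4), simplify = FALSE))
  parts2[[1L]]$labels[] <- 1L  # stages 1-2: no object at all
  parts2[[1L]] <- toy_partition(matrix(1L, 8L, 8L), 20, 1L)
  parts2[[2L]] <- toy_partition(matrix(1L, 8L, 8L), 20, 1L)
  res2 <- combine_stages(parts2, int)
  st2 <- stability_map(res2, parts2)
  expect_equal(unique(as.vector(st2$stability_px[2:4, 2:4])), 4L)
  expect_error(stability_map(res2, parts2[1L]))
})

test_that("multistage_merge validates the ladder and orders stages", {
  set.seed(10)
  grad <- gaussian_smooth(matrix(runif(24 * 24, 0, 255), 24L), 1)
  ws <- watershed_partition(grad)
  g <- summarize_superpixels(ws, grad)
  msr <- multistage_merge(g, grad)
  expect_equal(msr$thresholds, seq(70, 10, by = -10))
  expect_equal(msr$msm_max, 7)
  expect_true(all(msr$stability_px <= 6L))
  asc <- multistage_merge(g, grad, order = "asc")
  expect_equal(asc$thresholds, seq(10, 70, by = 10))
  expect_error(multistage_merge(g, grad, thresholds = c(10, 10)))
  expect_error(multistage_merge(g, grad, thresholds = c(-5, 10)))
})
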