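# concentric fixture: dark disk (1) inside bright ring (2) inside matrix (0)
concentric_labels <- function(n = 21L, r_in = 3.2, r_out = 7.2) {
  ctr <- (n + 1L) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`))
  lab <- matrix(0L, n, n)
  lab[d <= r_out] <- 2L
  lab[d <= r_in] <- 1L
  lab
}

test_that("enclosure hierarchy records nested containment", {
  lab <- concentric_labels()
  h <- build_enclosure_hierarchy(lab)
  expect_equal(h$parent_of[["1"]], 2L)
  expect_equal(h$parent_of[["2"]], 0L)
  expect_true(!"0" %in% names(h$parent_of))  # border segment, never a child
  # 3-level nested toy: disk in ring in outer ring in background
  lab3 <- concentric_labels(31L, 4, 8)
  ctr <- 16; d <- sqrt(outer((1:31 - ctr)^2, (1:31 - ctr)^2, `+`))
  lab3[d > 8 & d <= 12] <- 3L
  h3 <- build_enclosure_hierarchy(lab3)
  expect_equal(h3$parent_of[["1"]], 2L)
  expect_equal(h3$parent_of[["2"]], 3L)
  expect_equal(h3$parent_of[["3"]], 0L)
  # two segments sharing the border strip: both residual
  strip <- matrix(1L, 10L, 10L); strip[, 6:10] <- 2L
  hs <- build_enclosure_hierarchy(strip)
  expect_equal(sort(hs$residual), c(1L, 2L))
  expect_equal(length(hs$parent_of), 0L)
  # containment works across an intervening sliver: nucleus + sliver both
  # children of the enclosing ring
  lab4 <- concentric_labels()
  lab4[11L, 16L] <- 3L  # 1-px sliver inside the ring annulus
  h4 <- build_enclosure_hierarchy(lab4)
  expect_equal(h4$parent_of[["1"]], 2L)
  expect_equal(h4$parent_of[["3"]], 2L)
})

test_that("OCIN labelling follows the sign rule and iteration hierarchy", {
  lab <- concentric_labels()
  h <- build_enclosure_hierarchy(lab)
  means <- c("0" = 70, "1" = 40, "2" = 120)
  oc <- ocin_assign(h, means, quiet = TRUE)
  expect_equal(oc$ocin_class[oc$label == 1L], "nucleus")
  expect_equal(oc$H[oc$label == 1L], 1L)
  # the enclosing ring is the outer cell of the relation, also at H = 1
  expect_equal(oc$ocin_class[oc$label == 2L], "cell")
  expect_equal(oc$H[oc$label == 2L], 1L)
  # bright blob inside darker surround -> cell candidate at H = 1
  oc2 <- ocin_assign(h, c("0" = 70, "1" = 180, "2" = 120), quiet = TRUE)
  expect_equal(oc2$ocin_class[oc2$label == 1L], "cell")
  expect_equal(oc2$H[oc2$label == 1L], 1L)
  # a dark border strip resolves in iteration 2 against the background
  lab2 <- concentric_labels()
  lab2[1:2, 8:14] <- 3L
  h2 <- build_enclosure_hierarchy(lab2)
  oc3 <- ocin_assign(h2, c("0" = 70, "1" = 40, "2" = 120, "3" = 30),
                     quiet = TRUE)
  expect_equal(oc3$ocin_class[oc3$label == 3L], "nucleus")
  expect_equal(oc3$H[oc3$label == 3L], 2L)
})

test_that("OCIN terminates with every segment labelled on random maps", {
  set.seed(14)
  for (rep in 1:3) {
    grad <- gaussian_smooth(matrix(runif(32 * 32, 0, 255), 32L), 1)
    ws <- watershed_partition(grad)
    g <- summarize_superpixels(ws, grad)
    msr <- multistage_merge(g, grad)
    h <- build_enclosure_hierarchy(msr$final_labels)
    means <- stats::setNames(msr$seg_mean[h$nodes + 1L], h$nodes)
    areas <- stats::setNames(msr$seg_area[h$nodes + 1L], h$nodes)
    oc <- ocin_assign(h, means, areas, quiet = TRUE)
    expect_false(anyNA(oc$ocin_class))
    expect_true(all(oc$H >= 1L))
  }
})

test_that("compactness matches closed forms within rasterization tolerance", {
  # rasterized disk of radius 20 within 5% of the circle value 1
  expect_lt(abs(compactness(disk_mask(20L)) - 1), 0.05)
  # square: continuous C = (4L)^2 / (4 pi L^2) = 4 / pi ~ 1.273; the
  # Crofton estimator underestimates corner perimeter, wide tolerance
  sq <- matrix(FALSE, 40L, 40L); sq[6:35, 6:35] <- TRUE
  expect_lt(abs(compactness(sq) - 4 / pi), 0.2)
  # elongated 3 x 30 bar: evaluate the Crofton estimator by hand
  bar <- matrix(TRUE, 3L, 30L)
  P_manual <- pi / 4 * (30 + 3 + (32 + 32) / sqrt(2))
  expect_equal(compactness(bar), P_manual^2 / (4 * pi * 90))
  expect_gt(compactness(bar), compactness(disk_mask(20L)))
  expect_error(compactness(matrix(FALSE, 3L, 3L)))
  # closed form helper
  expect_equal(compactness_from_PA(2 * pi * 7, pi * 49), 1)
})

test_that("contour gradient: zero on flat images, shift equivariant", {
  msk <- disk_mask(5L)
  expect_equal(contour_gradient(msk, matrix(7, nrow(msk), ncol(msk))), 0)
  # dark disk on bright background: matches a naive central-difference oracle
  img <- matrix(200, 25L, 25L)
  big <- matrix(FALSE, 25L, 25L)
  big[6:20, 6:20] <- disk_mask(5L, pad = 2L)
  img[big] <- 0
  got <- contour_gradient(big, img)
  contour <- which(big & !(rbind(big[-1, ], TRUE) & rbind(TRUE, big[-25, ]) &
                           cbind(big[, -1], TRUE) & cbind(TRUE, big[, -25])),
                   arr.ind = TRUE)
  oracle <- mean(apply(contour, 1L, function(p) {
    i <- p[1]; j <- p[2]
    gx <- (img[i, min(j + 1, 25)] - img[i, max(j - 1, 1)]) / 2
    gy <- (img[min(i + 1, 25), j] - img[max(i - 1, 1), j]) / 2
    sqrt(gx^2 + gy^2)
  }))
  expect_equal(got, oracle)
  # translation invariance
  img2 <- matrix(200, 25L, 25L); big2 <- matrix(FALSE, 25L, 25L)
  big2[8:22, 9:23] <- disk_mask(5L, pad = 2L)
  img2[big2] <- 0
  expect_equal(contour_gradient(big2, img2), got)
})

test_that("quality scores implement the normalized 2-norm distance", {
  # ideal candidate in a single-candidate scene
  f <- data.frame(label = 1L, S = 7, grad = 255, C = 1, H = 1)
  expect_equal(quality_scores(f)$d, 0)
  # half-way vector: every normalized component 0.5 -> d = 1
  f2 <- data.frame(label = 1:2, S = c(3.5, 3.5), grad = c(127.5, 127.5),
                   C = c(2, 2), H = c(2L, 2L))
  expect_equal(quality_scores(f2)$d, c(1, 1))
  # reference constants of the pipeline: MSM_max 7, I_max 255
  expect_equal(formals(quality_scores)$MSM_max, 7)
  expect_equal(formals(quality_scores)$I_max, 255)
  # d strictly decreases when one feature moves toward its ideal
  f3 <- data.frame(label = 1:2, S = c(3, 5), grad = c(100, 100),
                   C = c(1.2, 1.2), H = c(1L, 1L))
  d3 <- quality_scores(f3)$d
  expect_lt(d3[2L], d3[1L])
  expect_error(quality_scores(f, MSM_max = 0))
})

test_that("select_nuclei applies the strict relative threshold", {
  sc <- data.frame(label = 1:3, d = c(0.2, 0.5, 1.0))
  # T_qual = 1: threshold = min(d), strict < selects nothing
  expect_length(select_nuclei(sc, 1), 0L)
  # T_qual = 0: threshold = max(d), all but the worst ties
  expect_equal(select_nuclei(sc, 0), c(1L, 2L))
  # printed arithmetic: threshold 0.8 * 0.03 + 0.2 = 0.224
  expect_equal(select_nuclei(sc, 0.97), 1L)
  expect_error(select_nuclei(sc, 1.2))
  # monotonicity: lower T_qual selects a superset
  set.seed(2)
  sc2 <- data.frame(label = 1:20, d = runif(20))
  for (t in seq(0, 0.9, by = 0.3)) {
    expect_true(all(select_nuclei(sc2, t + 0.1) %in% select_nuclei(sc2, t)))
  }
})

test_that("assign_classes paints nuclei, adjacent cells, and matrix", {
  lab <- concentric_labels()
  h <- build_enclosure_hierarchy(lab)
  oc <- data.frame(label = c(0L, 1L, 2L),
                   ocin_class = c("cell", "nucleus", "cell"),
                   H = c(2L, 1L, 1L))
  # no nuclei selected: everything is matrix
  cl0 <- assign_classes(lab, integer(0), h$adjacency, oc)
  expect_true(all(cl0$class_map == 0L))
  # nucleus enclosed by one cell candidate: that candidate becomes cytoplasm
  cl1 <- assign_classes(lab, 1L, h$adjacency, oc)
  expect_equal(unique(cl1$class_map[lab == 1L]), 2L)
  expect_equal(unique(cl1$class_map[lab == 2L]), 1L)
  expect_equal(unique(cl1$class_map[lab == 0L]), 0L)  # background stays matrix
  expect_equal(cl1$cytoplasm_of[["1"]], 2L)
  # nucleus touching two cell candidates: both become cytoplasm
  lab2 <- matrix(0L, 12L, 12L)
  lab2[4:9, 4:6] <- 2L; lab2[4:9, 7:9] <- 3L; lab2[6:7, 6:7] <- 1L
  h2 <- build_enclosure_hierarchy(lab2)
  oc2 <- data.frame(label = 0:3,
                    ocin_class = c("cell", "nucleus", "cell", "cell"),
                    H = c(2L, 1L, 1L, 1L))
  cl2 <- assign_classes(lab2, 1L, h2$adjacency, oc2)
  expect_equal(unique(cl2$class_map[lab2 == 2L]), 1L)
  expect_equal(unique(cl2$class_map[lab2 == 3L]), 1L)
})

test_that("semantic_assign produces an exhaustive, consistent classification", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 6L, speckle_strength = 0,
                                           open_boundary_fraction = 0))
  res <- run_slice(as.matrix(ph$image), msm_config(), quiet = TRUE)
  sem <- res$sem
  expect_true(all(sem$class_map %in% 0:2))
  # every selected nucleus is a scored candidate
  expect_true(all(sem$selected %in% sem$features$label))
  # cytoplasm pixels belong to segments adjacent to a selected nucleus
  for (nuc in names(sem$cytoplasm_of)) {
    cyt <- sem$cytoplasm_of[[nuc]]
    nb <- sem$hierarchy$adjacency
    expect_true(all(cyt %in% nb$b[nb$a == as.integer(nuc)]))
  }
  # raw-pixel boundary mode runs and classifies everything too
  sem2 <- semantic_assign(res$msr, res$preprocessed, T_qual = 0.97,
                          boundary_mode = "raw-pixel", quiet = TRUE)
  expect_false(anyNA(sem2$ocin$ocin_class))
})
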