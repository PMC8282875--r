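test_that("make_disk_se produces Euclidean disks and rejects bad diameters", {
  expect_equal(sum(make_disk_se(1L)$mask), 1L)
  # diameter 3: radius-1 Euclidean disk = 4-connected cross of 5 pixels
  se3 <- make_disk_se(3L)
  expect_equal(sum(se3$mask), 5L)
  expect_true(se3$mask[2L, 2L])
  expect_false(se3$mask[1L, 1L])
  # diameter 11: brute-force count of lattice points within distance 5
  cnt <- sum(outer((-5:5)^2, (-5:5)^2, `+`) <= 25)
  expect_equal(sum(make_disk_se(11L)$mask), cnt)
  # symmetric under 90 degree rotation
  m <- make_disk_se(7L)$mask
  expect_identical(m, t(m)[, rev(seq_len(ncol(m)))])
  expect_error(make_disk_se(4L))
  expect_error(make_disk_se(-3L))
})

test_that("top-hats match the definitional min/max-filter oracle", {
  se <- make_disk_se(5L)
  for (seed in c(1L, 2L)) {
    set.seed(seed)
    img <- matrix(sample(0:255, 256, replace = TRUE) * 1.0, 16L, 16L)
    expect_equal(white_tophat(img, se), brute_white_tophat(img, se$mask))
    expect_equal(black_tophat(img, se), brute_black_tophat(img, se$mask))
  }
})

test_that("plateau transform: flat input fixed, impulse kept, range clipped", {
  flat <- matrix(117, 8L, 8L)
  expect_equal(plateau_transform(flat, make_disk_se(3L)), flat)
  imp <- matrix(0, 9L, 9L); imp[5L, 5L] <- 255
  out <- plateau_transform(imp, make_disk_se(3L))
  expect_equal(out[5L, 5L], 255)  # white top-hat restores it after clipping
  set.seed(7)
  img <- matrix(sample(0:255, 400, replace = TRUE) * 1.0, 20L)
  se <- make_disk_se(5L)
  out <- plateau_transform(img, se)
  expect_true(all(out >= 0 & out <= 255))
  expect_identical(dim(out), dim(img))
  # where the black top-hat vanishes the (pre-clip) result is >= the input
  bt <- brute_black_tophat(img, se$mask)
  expect_true(all(out[bt == 0] >= pmin(img[bt == 0], 255) - 1e-9))
})

test_that("CLAHE: constant input, global-equalization oracle, contrast", {
  flat <- matrix(90, 32L, 32L)
  out <- clahe(flat, 16L, 2)
  expect_equal(max(out) - min(out), 0)
  # one tile spanning the image with unbounded clip = global equalization
  set.seed(5)
  img <- matrix(sample(0:255, 1024, replace = TRUE) * 1.0, 32L)
  ce <- clahe(img, 32L, 1e9)
  oracle <- matrix(vapply(as.vector(img), function(v) mean(img <= v) * 255, 0),
                   32L)
  expect_equal(ce, oracle, tolerance = 1e-12)
  # two-level image: dynamic range must not shrink
  two <- matrix(100, 32L, 32L); two[, 17:32] <- 140
  out2 <- clahe(two, 16L, 4)
  expect_gte(max(out2) - min(out2), 40)
  expect_error(clahe(img, 1L, 2))
  expect_error(clahe(img, 16L, 0))
})

test_that("anisotropic diffusion follows the printed 8-neighbour update", {
  flat <- matrix(33, 6L, 6L)
  expect_equal(anisotropic_diffuse(flat, K = 10, iterations = 7L), flat)
  # hand evaluation on a 3x3 impulse: all 8 neighbour differences are -80,
  # each coefficient 1 / (1 + (80/10)^2) = 1/65
  m <- matrix(0, 3L, 3L); m[2L, 2L] <- 80
  out <- anisotropic_diffuse(m, K = 10, lambda = 1, iterations = 1L)
  expect_equal(out[2L, 2L], 80 - 80 / 65, tolerance = 1e-12)
  # K -> Inf limit: one step equals linear 8-neighbour diffusion
  set.seed(9)
  img <- matrix(runif(64, 0, 255), 8L)
  out <- anisotropic_diffuse(img, K = 1e9, lambda = 0.8, iterations = 1L)
  acc <- matrix(0, 8L, 8L)
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    sh <- img[vapply(seq_len(8) + d[1], refl1, 1L, n = 8L),
              vapply(seq_len(8) + d[2], refl1, 1L, n = 8L)]
    acc <- acc + (sh - img)
  }
  expect_equal(out, img + 0.8 / 8 * acc, tolerance = 1e-9)
  # identity cases and range contract
  expect_equal(anisotropic_diffuse(img, K = 10, iterations = 0L), img)
  expect_equal(anisotropic_diffuse(img, K = 10, lambda = 0, iterations = 5L),
               img)
  out5 <- anisotropic_diffuse(img, K = 20, iterations = 5L)
  expect_true(all(out5 >= 0 & out5 <= 255))
  expect_error(anisotropic_diffuse(img, K = -1))
})

test_that("preprocess_slice composes the chain and keeps the 8-bit contract", {
  set.seed(21)
  img <- matrix(sample(0:255, 48 * 48, replace = TRUE) * 1.0, 48L)
  out <- preprocess_slice(img, msm_config())
  expect_identical(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 255))
})
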