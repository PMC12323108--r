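test_that("laplacian filter vanishes on constant and affine images", {
  expect_equal(laplacian_filter(matrix(7, 6, 6)), matrix(0, 6, 6))
  ramp_s <- outer(1:7, rep(1, 5))      # g(s,t) = s
  ramp_t <- outer(rep(1, 7), 1:5)      # g(s,t) = t
  aff <- 3 * ramp_s - 2 * ramp_t + 11
  for (img in list(ramp_s, ramp_t, aff)) {
    out <- laplacian_filter(img)
    expect_equal(out[2:6, 2:4], matrix(0, 5, 3))
  }
})

test_that("laplacian of a unit impulse reproduces the kernel stencil", {
  img <- matrix(0, 5, 5); img[3, 3] <- 1
  out <- laplacian_filter(img)
  expect_equal(out[2:4, 2:4], matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3))
})

test_that("sharpen matches the 9*center - neighbours stencil and preserves ramps", {
  expect_equal(sharpen(matrix(4, 5, 5)), matrix(4, 5, 5))
  ramp <- outer(1:6, rep(1, 6))
  expect_equal(sharpen(ramp)[2:5, 2:5], ramp[2:5, 2:5])
  set.seed(11)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
    expect_equal(sharpen(img), or_sharpen(img))
  }
})

test_that("sharpen minus image equals the negated laplacian everywhere", {
  set.seed(2)
  img <- matrix(rnorm(48), 6, 8)
  expect_equal(sharpen(img) - img, -laplacian_filter(img))
})

test_that("kernel constructors obey their sum invariants", {
  expect_equal(sum(laplacian_kernel()), 0)
  expect_equal(sum(sharpening_kernel()), 1)
  expect_error(filter_kernel(1:8), "9")
  expect_error(laplacian_filter(matrix(1, 2, 5)), "3x3")
})

test_that("clip_and_standardize yields zero mean and unit sd", {
  set.seed(3)
  v <- array(runif(1000, -100, 100), c(10, 10, 10))
  out <- clip_and_standardize(v)
  expect_lt(abs(mean(out)), 1e-6)
  expect_lt(abs(sd(out) - 1), 1e-6)
  # idempotent up to clipping: second application also standard
  out2 <- clip_and_standardize(out)
  expect_lt(abs(mean(out2)), 1e-6)
  expect_lt(abs(sd(out2) - 1), 1e-6)
})

test_that("constant volumes standardize to zeros with a warning", {
  expect_warning(out <- clip_and_standardize(array(5, c(2, 4, 4))), "constant")
  expect_equal(out, array(0, c(2, 4, 4)))
})

test_that("clip bounds match a sort-based percentile oracle", {
  x <- array(1:10000, c(10, 10, 100))
  spec <- clip_spec(0.55, 99.4)
  # linear interpolation between order statistics (sorted vector reference)
  s <- sort(as.vector(x))
  n <- length(s)
  oracle_q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  out <- clip_and_standardize(x, spec)
  lo <- oracle_q(0.0055); hi <- oracle_q(0.994)
  clipped <- pmin(pmax(as.vector(x), lo), hi)
  expect_equal(as.vector(out), (clipped - mean(clipped)) / sd(clipped))
})

test_that("resampling is exact on constants, identity requests and ramps", {
  cv <- volume_image(array(40, c(3, 6, 6)), c(2, 1, 1))
  expect_equal(resample_volume(cv, c(1, 2, 3))$voxels,
               array(40, dim(resample_volume(cv, c(1, 2, 3))$voxels)))
  expect_equal(resample_volume(cv, c(2, 1, 1))$voxels, cv$voxels)
  v <- array(0, c(1, 8, 16))
  for (j in 1:16) v[1, , j] <- j
  rs <- resample_volume(volume_image(v, c(1, 1, 1)), c(1, 1, 2))
  expect_equal(rs$voxels[1, 1, ], seq(1, 15, by = 2))
  expect_equal(rs$spacing, c(1, 1, 2))
  expect_error(resample_volume(cv, c(0, 1, 1)), "positive")
})

test_that("mask resampling keeps labels binary", {
  set.seed(4)
  m <- array(rbinom(4 * 12 * 12, 1, 0.4), c(4, 12, 12))
  out <- resample_volume(volume_image(m, c(3, 1, 1)), c(3, 0.7, 0.7),
                         is_mask = TRUE)
  expect_true(all(out$voxels %in% c(0, 1)))
})

test_that("single-slice volumes survive depth resampling by replication", {
  v <- volume_image(array(rnorm(64), c(1, 8, 8)), c(5, 1, 1))
  out <- resample_volume(v, c(2.5, 1, 1))
  expect_equal(dim(out$voxels)[1], 2L)
  expect_equal(out$voxels[1, , ], out$voxels[2, , ])
})

test_that("augmentation is an involution under certain flips and a pure function", {
  set.seed(5)
  img <- matrix(rnorm(100), 10, 10)
  msk <- matrix(rbinom(100, 1, 0.3), 10, 10)
  fl <- augment_spec(c(1, 1), c(1, 1), flip_prob = 1, shear = c(0, 0), seed = 2)
  twice <- augment(augment(img, msk, fl)$image, augment(img, msk, fl)$mask, fl)
  expect_equal(twice$image, img)
  expect_equal(twice$mask, msk)
  idsp <- augment_spec(c(1, 1), c(1, 1), 0, c(0, 0), seed = 1)
  expect_equal(augment(img, msk, idsp)$image, img)
  sp <- augment_spec(seed = 77)
  expect_identical(augment(img, msk, sp), augment(img, msk, sp))
  expect_error(augment(img, msk[1:5, ], sp), "identical")
})

test_that("gaussian patch weights are unimodal with the closed-form profile", {
  expect_equal(gaussian_patch_weights(c(1, 1, 1)), array(1, c(1, 1, 1)))
  w <- gaussian_patch_weights(c(9, 9, 9), sigma_scale = 1 / 3)
  expect_equal(max(w), w[5, 5, 5])
  expect_equal(w[5, 5, 5], 1)
  expect_true(all(w > 0))
  sig <- 3 # 9 * 1/3
  expect_equal(w[5 + sig, 5, 5] / w[5, 5, 5], exp(-1 / 2))
  w2 <- gaussian_patch_weights(c(17, 1, 1), sigma_scale = 2 / 17) # sigma 2
  for (k in 1:3)
    expect_equal(w2[9 + 2 * k, 1, 1] / w2[9, 1, 1], exp(-k^2 / 2))
})

test_that("sliding-window fusion is a partition of unity", {
  set.seed(6)
  x <- array(rnorm(6 * 20 * 20), c(6, 20, 20))
  echo <- sliding_window_predict(x, function(p) p, patch_size = c(2, 8, 8))
  expect_lt(max(abs(echo - x)), 1e-5)
  const <- sliding_window_predict(x, function(p) array(0.7, dim(p)),
                                  patch_size = c(3, 7, 7))
  expect_equal(const, array(0.7, dim(x)))
  # exact tiling with stride == patch: each voxel from exactly one patch
  counts <- sliding_window_predict(
    array(0, c(4, 8, 8)),
    function(p) array(1, dim(p)), # weight-normalized count stays 1
    patch_size = c(2, 4, 4), stride = c(2, 4, 4))
  expect_equal(counts, array(1, c(4, 8, 8)))
  expect_error(
    sliding_window_predict(x, function(p) p[1, , , drop = FALSE],
                           patch_size = c(2, 8, 8)),
    "shape")
})

test_that("volumes smaller than the patch are padded and cropped back", {
  x <- array(rnorm(2 * 5 * 5), c(2, 5, 5))
  out <- sliding_window_predict(x, function(p) p, patch_size = c(4, 8, 8))
  expect_equal(dim(out), dim(x))
  expect_lt(max(abs(out - x)), 1e-5)
})

test_that("the preprocessing pipeline output is standardized", {
  set.seed(7)
  vol <- volume_image(array(rnorm(4 * 16 * 16, 40, 30), c(4, 16, 16)), c(3, 1, 1))
  out <- preprocess_volume(vol, target_spacing = c(3, 1, 1))
  expect_lt(abs(mean(out$voxels)), 1e-6)
  expect_lt(abs(sd(out$voxels) - 1), 1e-6)
})
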