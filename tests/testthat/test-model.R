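test_that("cnn encoder produces the stride-1/2/4/8 pyramid deterministically", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 1)
  img <- matrix(rnorm(32 * 32), 32, 32)
  maps <- cnn_encode(m, img)
  expect_equal(vapply(maps, function(x) dim(x)[1], numeric(1)),
               c(32, 16, 8, 4))
  expect_equal(dim(maps[[4]])[3], 8 * cfg$base_channels)
  expect_identical(maps, cnn_encode(m, img))
  # zero input with zero biases gives zero features (linear before ReLU)
  zmaps <- cnn_encode(m, matrix(0, 32, 32))
  expect_equal(max(abs(zmaps[[4]])), 0)
})

test_that("a DuSAL with zeroed projections is the identity (pure residual)", {
  cfg <- tiny_config()
  C <- 8 * cfg$base_channels
  p <- pancseg:::.dusal_init(C, cfg)
  zero <- function(m) m * 0
  p$sp <- lapply(p$sp, zero)
  p$spec$Wq <- zero(p$spec$Wq); p$spec$Wk <- zero(p$spec$Wk)
  p$spec$Wv <- zero(p$spec$Wv)
  p$mlp <- lapply(p$mlp, zero)
  f <- array(rnorm(4 * 4 * C), c(4, 4, C))
  expect_equal(dusal_forward(f, p, cfg), f, tolerance = 1e-12)
})

test_that("dusal forward preserves shape and composes as a stack", {
  set.seed(21)
  cfg <- tiny_config()
  C <- 8 * cfg$base_channels
  p1 <- pancseg:::.dusal_init(C, cfg)
  p2 <- pancseg:::.dusal_init(C, cfg)
  f <- array(rnorm(4 * 6 * C), c(4, 6, C))
  out <- dusal_forward(f, p1, cfg)
  expect_equal(dim(out), dim(f))
  expect_true(all(is.finite(out)))
  # composing two applications equals running the fused two-layer stack:
  # block output = conv(dusal2(dusal1(f))) + f
  manual <- dusal_forward(dusal_forward(f, p1, cfg), p2, cfg)
  conv <- list(w = matrix(rnorm(9 * C * C, sd = 0.05), 9 * C, C),
               b = matrix(0, 1, C))
  stacked <- dsat_encode(f, list(dusals = list(p1, p2), conv = conv), cfg)
  tape <- pancseg:::ad_tape(FALSE)
  cv <- pancseg:::nn_conv(tape,
                          pancseg:::ad_const(tape, matrix(manual, 24, C)),
                          4, 6,
                          list(w = pancseg:::ad_const(tape, conv$w),
                               b = pancseg:::ad_const(tape, conv$b)),
                          stride = 1L, relu = FALSE)
  expect_equal(matrix(stacked, 24, C), cv$x$val + matrix(f, 24, C),
               tolerance = 1e-10)
  # zeroed convolution leaves only the long residual
  zeroconv <- list(w = conv$w * 0, b = conv$b)
  resid_only <- dsat_encode(f, list(dusals = list(p1, p2), conv = zeroconv), cfg)
  expect_equal(resid_only, f, tolerance = 1e-12)
})

test_that("the transformer block keeps its long residual and N = 0 limit", {
  set.seed(22)
  cfg <- tiny_config()
  C <- 8 * cfg$base_channels
  f <- array(rnorm(4 * 4 * C), c(4, 4, C))
  conv <- list(w = matrix(rnorm(9 * C * C, sd = 0.05), 9 * C, C),
               b = matrix(rnorm(C, sd = 0.01), 1, C))
  # N = 0 degenerates to conv + residual
  got <- dsat_encode(f, list(dusals = list(), conv = conv), cfg)
  tape <- pancseg:::ad_tape(FALSE)
  x <- pancseg:::ad_const(tape, matrix(f, 16, C))
  cv <- pancseg:::nn_conv(tape, x, 4, 4,
                          list(w = pancseg:::ad_const(tape, conv$w),
                               b = pancseg:::ad_const(tape, conv$b)),
                          stride = 1L, relu = FALSE)
  expect_equal(matrix(got, 16, C), cv$x$val + matrix(f, 16, C))
})

test_that("refinement unrolls to manual steps and accepts forced masks", {
  set.seed(23)
  X <- 3; P <- 16; D <- 6
  A0 <- matrix(rnorm(X * D), X, D)
  f <- matrix(rnorm(P * D), P, D)
  prm <- list(Wq = matrix(rnorm(D * D), D, D), Wk = matrix(rnorm(D * D), D, D),
              Wv = matrix(rnorm(D * D), D, D))
  Y0 <- coarse_predict(A0, f)$mask
  # T = 1 equals one manual MCA + predict step
  r1 <- refine(A0, Y0, f, prm, t_refine = 1)
  A1 <- masked_cross_attention(A0, Y0, f, prm)
  cp <- coarse_predict(A1, f)
  expect_equal(r1$A, A1)
  expect_equal(r1$Y, cp$mask)
  # all-ones initial masks reproduce an unmasked iterative decoder
  ones <- matrix(1, X, P)
  r2 <- refine(A0, ones, f, prm, t_refine = 2)
  A <- A0; Y <- ones
  for (i in 1:2) {
    m0 <- matrix(0, X, P)
    A <- A + or_attention(A %*% prm$Wq, f %*% prm$Wk, f %*% prm$Wv,
                          scale = 1 / sqrt(D),
                          mask = if (i == 1) m0 else pancseg:::mca_additive_mask(Y))
    Y <- coarse_predict(A, f)$mask
  }
  expect_equal(r2$A, A, tolerance = 1e-6)
  expect_equal(r2$Y, Y)
  # deterministic
  expect_identical(refine(A0, Y0, f, prm, 3), refine(A0, Y0, f, prm, 3))
})

test_that("the full forward pass yields calibrated per-pixel outputs", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 2)
  img <- matrix(rnorm(24 * 40), 24, 40)
  r <- segment_slice(m, img)
  expect_equal(dim(r$prob), dim(img))
  expect_equal(dim(r$label), dim(img))
  expect_true(all(r$prob >= 0 & r$prob <= 1))
  expect_true(all(r$label %in% 0:(cfg$n_classes - 1)))
  expect_equal(nrow(r$class_logits), cfg$n_queries)
  expect_equal(ncol(r$class_logits), cfg$n_classes + 1L)
  # deterministic under fixed weights
  expect_identical(r$prob, segment_slice(m, img)$prob)
  # non-multiple-of-8 sides are padded and cropped transparently
  img2 <- matrix(rnorm(19 * 21), 19, 21)
  r2 <- segment_slice(m, img2)
  expect_equal(dim(r2$prob), c(19L, 21L))
})

test_that("model configuration validates its invariants", {
  expect_error(model_config(tau = 1.2), "tau")
  expect_error(model_config(n_queries = 1, n_classes = 2))
  expect_error(model_config(t_refine = 0))
  expect_error(model_config(base_channels = 3, heads = 7), "heads")
  cfg <- model_config(spectral = "dwt")
  expect_equal(cfg$spectral, "dwt")
})

test_that("checkpoints round-trip weights and configuration", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 3)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$config, m$config)
  expect_equal(m2$params, m$params)
  img <- matrix(rnorm(16 * 16), 16, 16)
  expect_identical(segment_slice(m, img)$prob, segment_slice(m2, img)$prob)
})

test_that("analytic network gradients match finite differences", {
  set.seed(77)
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 7)
  img <- matrix(rnorm(16 * 16), 16, 16)
  mask <- matrix(0, 16, 16); mask[5:10, 6:12] <- 1
  inst <- pancseg:::slice_instances(mask)
  lossfun <- function(params) {
    tape <- pancseg:::ad_tape(FALSE)
    pw <- pancseg:::wrap_params(tape, params)
    fw <- pancseg:::nn_forward(tape, pw, img, cfg)
    pancseg:::nn_slice_loss(tape, fw, inst, cfg, loss_config())$val[1]
  }
  tape <- pancseg:::ad_tape(TRUE)
  pw <- pancseg:::wrap_params(tape, m$params)
  fw <- pancseg:::nn_forward(tape, pw, img, cfg)
  L <- pancseg:::nn_slice_loss(tape, fw, inst, cfg, loss_config())
  pancseg:::ad_backward(tape, L)
  grads <- pancseg:::flatten_params(pancseg:::collect_grads(pw))
  flat <- pancseg:::flatten_params(m$params)
  eps <- 1e-5
  # spot-check entries across every layer family
  keys <- c("enc.1.w", "dsat.dusals.1.sp.Nq", "dsat.dusals.1.spec.Wq",
            "dsat.dusals.1.spec.sigma", "dsat.dusals.1.sp.bias",
            "dsat.dusals.1.mlp.w1", "dsat.conv.w", "dec.3.w", "proj_mid.w",
            "proj_full.w", "mca.Wq", "queries", "cls.w",
            "dsat.dusals.1.ln1.g")
  for (key in keys) {
    i <- sample(length(flat[[key]]), 1)
    fl <- flat; fl[[key]][i] <- fl[[key]][i] + eps
    lp <- lossfun(pancseg:::rebuild_params(m$params, fl))
    fl[[key]][i] <- fl[[key]][i] - 2 * eps
    lm <- lossfun(pancseg:::rebuild_params(m$params, fl))
    num <- (lp - lm) / (2 * eps)
    g <- grads[[key]][i]
    # guarded relative error: finite differences carry ~1e-6 absolute noise
    relerr <- abs(num - g) / max(1e-3, abs(num) + abs(g))
    expect_lt(relerr, 1e-3, label = paste("gradient error for", key))
  }
})
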