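test_that("window partition and merge are mutually inverse", {
  set.seed(1)
  f <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  wins <- window_partition(f, 2)
  expect_length(wins, 4L)
  expect_equal(window_merge(wins), f)
  one <- window_partition(f, 4)
  expect_length(one, 1L)
  expect_equal(one[[1]], f)
  for (n in c(1, 2, 3, 6)) {
    g <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
    expect_equal(window_merge(window_partition(g, n)), g)
  }
  expect_error(window_partition(f, 0), "positive")
  expect_error(window_partition(f, 3), "divide")
})

test_that("single-token and symmetric windows behave trivially", {
  set.seed(2)
  C <- 5; d <- 4
  prm <- random_params_spatial(C, d)
  S1 <- matrix(rnorm(C), 1, C) # n = 1: softmax over one logit
  expect_equal(spatial_window_attention(S1, prm), S1 %*% prm$Nv)
  Sid <- matrix(rep(rnorm(C), each = 4), 4, C) # identical tokens
  out <- spatial_window_attention(Sid, prm)
  expect_equal(out, Sid %*% prm$Nv, tolerance = 1e-10)
})

test_that("spatial window attention matches an explicit-loop oracle", {
  set.seed(3)
  for (trial in 1:50) {
    n <- sample(2:3, 1); C <- sample(2:5, 1); d <- sample(2:4, 1)
    prm <- random_params_spatial(C, d)
    S <- matrix(rnorm(n^2 * C), n^2, C)
    got <- spatial_window_attention(S, prm)
    want <- or_attention(S %*% prm$Nq, S %*% prm$Nk, S %*% prm$Nv,
                         scale = 1 / sqrt(d))
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("relative positional bias enters the logits per head", {
  set.seed(4)
  n <- 2; C <- 4; d <- 4
  prm <- random_params_spatial(C, d, heads = 1, n = n, bias = TRUE)
  S <- matrix(rnorm(n^2 * C), n^2, C)
  got <- spatial_window_attention(S, prm)
  rp <- pancseg:::relpos_index(n)
  bias <- matrix(prm$bias[rp, 1], n^2, n^2)
  want <- or_attention(S %*% prm$Nq, S %*% prm$Nk, S %*% prm$Nv,
                       scale = 1 / sqrt(d), bias = bias)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("legacy multiplier scale reproduces the printed convention", {
  set.seed(5)
  C <- 3; d <- 4
  prm <- random_params_spatial(C, d)
  prm$legacy_scale <- TRUE
  S <- matrix(rnorm(4 * C), 4, C)
  want <- or_attention(S %*% prm$Nq, S %*% prm$Nk, S %*% prm$Nv,
                       scale = sqrt(d))
  expect_equal(spatial_window_attention(S, prm), want, tolerance = 1e-5)
})

test_that("spectral channel attention follows its closed forms and oracle", {
  set.seed(6)
  # single channel: softmax over one logit is 1 -> output equals V
  tk <- matrix(rnorm(7), 7, 1)
  wq <- matrix(1.3); wk <- matrix(-0.7); wv <- matrix(2)
  expect_equal(spectral_channel_attention(tk, wq, wk, wv, sigma = 3), tk %*% wv)
  # sigma = 0: uniform channel mixing -> each column is the channel mean of V
  tk <- matrix(rnorm(12), 3, 4)
  out0 <- spectral_channel_attention(tk, diag(4), diag(4), diag(4), sigma = 0)
  expect_equal(out0, matrix(rowMeans(tk), 3, 4))
  # explicit matrix-product + column-softmax oracle
  for (trial in 1:50) {
    P <- sample(2:5, 1); C <- sample(2:4, 1)
    tk <- matrix(rnorm(P * C), P, C)
    Wq <- matrix(rnorm(C * C), C); Wk <- matrix(rnorm(C * C), C)
    Wv <- matrix(rnorm(C * C), C)
    sg <- runif(1, 0.2, 2)
    M <- sg * (t(tk %*% Wk) %*% (tk %*% Wq))
    A <- apply(M, 2, function(col) { e <- exp(col - max(col)); e / sum(e) })
    want <- (tk %*% Wv) %*% A
    got <- spectral_channel_attention(tk, Wq, Wk, Wv, sg)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("spectral attention preserves shape and inverts its transform", {
  set.seed(7)
  for (dims in list(c(4, 6, 3), c(3, 5, 2), c(4, 4, 1))) {
    f <- array(rnorm(prod(dims)), dims)
    C2 <- 2 * dims[3]
    prm <- list(Wq = matrix(rnorm(C2^2), C2), Wk = matrix(rnorm(C2^2), C2),
                Wv = matrix(rnorm(C2^2), C2), sigma = 0.5)
    out <- spectral_attention(f, prm)
    expect_equal(dim(out), dims)
    expect_true(all(is.finite(out)))
  }
  # with identity value projection and sigma -> attention output in the
  # frequency domain equals a known matrix product; check full-path oracle
  f <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  dm <- pancseg:::dft_mats(4, 4)
  x <- matrix(f, 16, 2)
  tk <- cbind(dm$Re %*% x, dm$Im %*% x)
  C2 <- 4
  prm <- list(Wq = matrix(rnorm(16), 4), Wk = matrix(rnorm(16), 4),
              Wv = matrix(rnorm(16), 4), sigma = 0.8)
  M <- prm$sigma * (t(tk %*% prm$Wk) %*% (tk %*% prm$Wq))
  A <- apply(M, 2, function(col) { e <- exp(col - max(col)); e / sum(e) })
  o <- (tk %*% prm$Wv) %*% A
  want <- dm$iRe %*% o[, 1:2] - dm$iIm %*% o[, 3:4]
  got <- spectral_attention(f, prm)
  expect_equal(matrix(got, 16, 2), want, tolerance = 1e-8)
})

test_that("Haar transform option round-trips shape on even grids", {
  set.seed(8)
  f <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  prm <- list(Wq = diag(4), Wk = diag(4), Wv = diag(4), sigma = 1,
              transform = "dwt")
  expect_equal(dim(spectral_attention(f, prm)), dim(f))
  expect_error(spectral_attention(array(0, c(3, 5, 1)),
                                  c(prm, list())), "even")
})

test_that("masked cross-attention renormalizes over foreground only", {
  set.seed(9)
  X <- 3; P <- 10; D <- 6; C <- 4
  A <- matrix(rnorm(X * D), X, D)
  f <- matrix(rnorm(P * C), P, C)
  prm <- list(Wq = matrix(rnorm(D * 4), D, 4), Wk = matrix(rnorm(C * 4), C, 4),
              Wv = matrix(rnorm(C * D), C, D))
  # all-ones mask equals plain cross-attention
  Y1 <- matrix(1, X, P)
  got <- masked_cross_attention(A, Y1, f, prm)
  want <- A + or_attention(A %*% prm$Wq, f %*% prm$Wk, f %*% prm$Wv,
                           scale = 1 / sqrt(4))
  expect_equal(got, want, tolerance = 1e-6)
  # single foreground pixel: the update is exactly that pixel's value row
  Ys <- matrix(0, X, P); Ys[, 3] <- 1
  gs <- masked_cross_attention(A, Ys, f, prm)
  expect_equal(gs, A + matrix((f %*% prm$Wv)[3, ], X, D, byrow = TRUE),
               tolerance = 1e-10)
  # empty mask for one query: falls back to unmasked, never NaN
  Ye <- Y1; Ye[2, ] <- 0
  ge <- masked_cross_attention(A, Ye, f, prm)
  expect_true(all(is.finite(ge)))
  expect_equal(ge[2, ], want[2, ], tolerance = 1e-6)
})

test_that("masked attention is exactly invariant to masked-out features", {
  set.seed(10)
  for (trial in 1:20) {
    X <- 4; P <- 12; D <- 6; C <- 5
    A <- matrix(rnorm(X * D), X, D)
    f <- matrix(rnorm(P * C), P, C)
    prm <- list(Wq = matrix(rnorm(D * 6), D, 6), Wk = matrix(rnorm(C * 6), C, 6),
                Wv = matrix(rnorm(C * D), C, D), heads = 2)
    Y <- matrix(rbinom(X * P, 1, 0.4), X, P)
    Y[rowSums(Y) == 0, 1] <- 1 # keep masks nonempty for strict invariance
    base <- masked_cross_attention(A, Y, f, prm)
    # perturb features only where EVERY query is masked out
    dead <- which(colSums(Y) == 0)
    if (length(dead) == 0) next
    f2 <- f
    f2[dead, ] <- f2[dead, ] + matrix(rnorm(length(dead) * C) * 100,
                                      length(dead), C)
    expect_identical(base, masked_cross_attention(A, Y, f2, prm))
  }
})

test_that("masked cross-attention matches the explicit oracle", {
  set.seed(11)
  for (trial in 1:50) {
    X <- sample(2:4, 1); P <- sample(4:9, 1); D <- 4; C <- 3
    A <- matrix(rnorm(X * D), X, D)
    f <- matrix(rnorm(P * C), P, C)
    prm <- list(Wq = matrix(rnorm(D * D), D, D), Wk = matrix(rnorm(C * D), C, D),
                Wv = matrix(rnorm(C * D), C, D))
    Y <- matrix(rbinom(X * P, 1, 0.5), X, P)
    m <- matrix(-Inf, X, P); m[Y > 0] <- 0; m[rowSums(Y) == 0, ] <- 0
    want <- A + or_attention(A %*% prm$Wq, f %*% prm$Wk, f %*% prm$Wv,
                             scale = 1 / sqrt(D), mask = m)
    expect_equal(masked_cross_attention(A, Y, f, prm), want, tolerance = 1e-5)
  }
})

test_that("coarse prediction applies the sharp cutoff with >= convention", {
  # orthogonal query and feature: logit 0, sigmoid 0.5 < 0.6 -> background
  A <- matrix(c(1, 0), 1, 2)
  f <- matrix(c(0, 1), 1, 2)
  cp <- coarse_predict(A, f, tau = 0.6)
  expect_equal(cp$logits[1, 1], 0)
  expect_equal(cp$mask[1, 1], 0)
  # aligned strong query: sigmoid ~ 1 -> foreground
  A2 <- matrix(c(10, 0), 1, 2)
  f2 <- matrix(c(10, 0), 1, 2)
  expect_equal(coarse_predict(A2, f2)$mask[1, 1], 1)
  # probability exactly tau counts as foreground
  tau <- 0.6
  logit <- log(tau / (1 - tau))
  A3 <- matrix(c(logit, 0), 1, 2)
  f3 <- matrix(c(1, 0), 1, 2)
  expect_equal(coarse_predict(A3, f3, tau)$mask[1, 1], 1)
  expect_error(coarse_predict(matrix(0, 1, 3), matrix(0, 1, 2)), "dimension")
})

test_that("query classification is the plain linear map", {
  set.seed(12)
  A <- matrix(rnorm(12), 3, 4)
  expect_equal(classify_queries(A, matrix(0, 4, 3)), matrix(0, 3, 3))
  W <- matrix(rnorm(12), 4, 3)
  expect_equal(classify_queries(A, W), A %*% W)
  onehot <- matrix(0, 1, 4); onehot[1, 2] <- 1
  expect_equal(classify_queries(onehot, diag(4)), onehot)
})

test_that("attention rows sum to one in every mechanism", {
  set.seed(13)
  # verified through the uniform-value trick: with V = all-ones, the output
  # of softmax(QK^T)V equals the row sums of the attention matrix
  C <- 4; d <- 4; n <- 2
  prm <- list(Nq = matrix(rnorm(C * d), C, d), Nk = matrix(rnorm(C * d), C, d),
              Nv = matrix(1, C, d) * 0) # start from zero...
  S <- matrix(rnorm(n^2 * C), n^2, C)
  prm$Nv <- diag(C)[, 1:d] * 0
  ones_out <- or_attention(S %*% prm$Nq, S %*% prm$Nk,
                           matrix(1, n^2, 1), scale = 1 / sqrt(d))
  expect_equal(as.vector(ones_out), rep(1, n^2), tolerance = 1e-10)
  # same property through the exported op by giving a value projection that
  # maps every token to 1
  prm2 <- random_params_spatial(C, d)
  prm2$Nv <- matrix(0, C, d)
  S1 <- cbind(S, 1)
  prm3 <- list(Nq = rbind(prm2$Nq, 0), Nk = rbind(prm2$Nk, 0),
               Nv = rbind(matrix(0, C, d), 1))
  out <- spatial_window_attention(S1, prm3)
  expect_equal(out, matrix(1, n^2, d), tolerance = 1e-10)
})
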