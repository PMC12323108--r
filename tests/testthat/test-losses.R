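test_that("hungarian solver equals the brute-force permutation minimum", {
  set.seed(31)
  for (trial in 1:200) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n, -5, 5), n, n)
    sol <- hungarian_solve(cost)
    expect_equal(sol$cost, or_min_assignment(cost), tolerance = 1e-10)
    expect_equal(sort(sol$assignment), seq_len(n)) # a permutation
  }
})

test_that("hungarian solver handles rectangles, dominance and edge cases", {
  # 1 row, 1 column: matched regardless of cost
  expect_equal(hungarian_solve(matrix(42))$assignment, 1L)
  # strictly dominant diagonal -> identity assignment
  cost <- matrix(10, 4, 4); diag(cost) <- 0:3
  expect_equal(hungarian_solve(cost)$assignment, 1:4)
  # rectangular: rows fewer than columns, distinct columns chosen
  set.seed(32)
  for (trial in 1:50) {
    n <- sample(1:4, 1); m <- n + sample(1:3, 1)
    cost <- matrix(runif(n * m), n, m)
    sol <- hungarian_solve(cost)
    expect_equal(length(unique(sol$assignment)), n)
    # oracle: pad to square with a constant column cost
    pad <- rbind(cost, matrix(max(cost) + 1, m - n, m))
    best <- or_min_assignment(pad) - (m - n) * (max(cost) + 1)
    expect_equal(sol$cost, best, tolerance = 1e-10)
  }
  expect_error(hungarian_solve(matrix(0, 3, 2)), "nrow")
})

test_that("mask losses match their closed forms", {
  g <- c(1, 1, 0, 0)
  # uniform 0.5 prediction: L_ce = ln 2 regardless of the mask
  expect_equal(mask_losses(rep(0.5, 4), g)$l_ce, log(2))
  # perfect hard prediction: dice loss reduces to the smoothing residual
  p <- c(1, 1, 0, 0)
  ml <- mask_losses(p, g)
  # probabilities are clamped to (0,1) by epsilon, hence the loose tolerance
  expect_equal(ml$l_dice, 1 - (2 * 2 + 1) / (2 + 2 + 1), tolerance = 1e-6)
  expect_lt(ml$l_ce, 1e-5)
  # 4-pixel arithmetic oracle
  p2 <- c(0.9, 0.6, 0.2, 0.1)
  ml2 <- mask_losses(p2, g)
  expect_equal(ml2$l_ce,
               -mean(c(log(0.9), log(0.6), log(0.8), log(0.9))))
  expect_equal(ml2$l_dice, 1 - (2 * 1.5 + 1) / (sum(p2) + 2 + 1))
  expect_error(mask_losses(c(0.1, 0.2), c(1, 0, 1)), "congruent")
})

test_that("loss combination follows L = alpha(Lce + Ldice) + beta*Lclas", {
  cfg <- loss_config(alpha = 0.7, beta = 0.3)
  expect_equal(combine_loss(1, 0.5, 2, cfg), 0.7 * 1.5 + 0.3 * 2)
  expect_equal(combine_loss(1, 0.5, 2, cfg), 1.65)
  # linear in alpha and beta
  expect_equal(combine_loss(1, 1, 1, loss_config(alpha = 1.4, beta = 0.3)),
               2 * combine_loss(1, 1, 1, loss_config(alpha = 0.7, beta = 0.15)))
})

test_that("total loss matches queries to targets and is non-negative", {
  set.seed(33)
  X <- 4; P <- 25
  mask_prob <- matrix(runif(X * P), X, P)
  class_logits <- matrix(rnorm(X * 3), X, 3)
  gt <- matrix(0, 5, 5); gt[2:4, 2:3] <- 1
  inst <- list(list(mask = as.numeric(gt), class = 2))
  tl <- total_loss(mask_prob, class_logits, inst)
  expect_gte(tl$total, 0)
  expect_equal(tl$total, combine_loss(tl$l_ce, tl$l_dice, tl$l_clas))
  expect_equal(nrow(tl$match$pairs), 1L)
  expect_length(tl$match$unmatched_queries, X - 1L)
  # beta = 0 removes all dependence on the class logits
  cfg0 <- loss_config(beta = 0)
  t1 <- total_loss(mask_prob, class_logits, inst, cfg0)
  t2 <- total_loss(mask_prob, class_logits + 3, inst, cfg0)
  expect_equal(t1$total, t2$total)
  # empty ground truth: every query is no-object
  t3 <- total_loss(mask_prob, class_logits, list())
  expect_length(t3$match$unmatched_queries, X)
  expect_equal(t3$l_ce, 0)
})

test_that("one gradient step on a linear predictor decreases the loss", {
  set.seed(34)
  # linearly parameterized mask logits: logits = W %*% feat
  P <- 16; D <- 5
  feat <- matrix(rnorm(P * D), P, D)
  W <- matrix(rnorm(D), 1, D)
  gt <- as.numeric(runif(P) > 0.5)
  lossW <- function(W) {
    pr <- 1 / (1 + exp(-(feat %*% t(W))))
    ml <- mask_losses(pr, gt)
    ml$l_ce + ml$l_dice
  }
  # finite-difference gradient and a small descent step
  g <- numeric(D)
  eps <- 1e-6
  for (i in 1:D) {
    Wp <- W; Wp[i] <- Wp[i] + eps
    Wm <- W; Wm[i] <- Wm[i] - eps
    g[i] <- (lossW(Wp) - lossW(Wm)) / (2 * eps)
  }
  expect_lt(lossW(W - 0.1 * matrix(g, 1)), lossW(W))
})

test_that("matching cost prefers the query overlapping the target", {
  set.seed(35)
  P <- 30
  gtm <- c(rep(1, 10), rep(0, 20))
  good <- pmin(pmax(gtm + rnorm(P, 0, 0.05), 0.01), 0.99)
  bad <- pmin(pmax(1 - gtm + rnorm(P, 0, 0.05), 0.01), 0.99)
  mask_prob <- rbind(bad, good)
  class_logits <- matrix(0, 2, 3)
  mt <- hungarian_match(mask_prob, class_logits,
                        list(list(mask = gtm, class = 2)))
  expect_equal(unname(mt$pairs[1, "query"]), 2L)
})
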