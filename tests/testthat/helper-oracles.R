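# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation: explicit loops and closed forms.

# explicit-loop scaled dot-product attention with optional additive bias/mask
or_attention <- function(Q, K, V, scale, bias = NULL, mask = NULL) {
  n <- nrow(Q); m <- nrow(K)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    logits <- numeric(m)
    for (j in seq_len(m)) {
      logits[j] <- sum(Q[i, ] * K[j, ]) * scale
      if (!is.null(bias)) logits[j] <- logits[j] + bias[i, j]
      if (!is.null(mask)) logits[j] <- logits[j] + mask[i, j]
    }
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    for (j in seq_len(m)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# double-loop evaluation of the sharpening stencil 9*center - sum(neighbours)
# with replicate padding
or_sharpen <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    acc <- 9 * img[r, c]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- min(max(r + dr, 1), h)
      cc <- min(max(c + dc, 1), w)
      acc <- acc - img[rr, cc]
    }
    out[r, c] <- acc
  }
  out
}

# triple-loop surface extraction (face adjacency, border = background)
or_surface_voxels <- function(mask) {
  d <- dim(mask)
  coords <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] <= 0) next
    nb <- c(
      if (i > 1) mask[i - 1, j, k] else 0, if (i < d[1]) mask[i + 1, j, k] else 0,
      if (j > 1) mask[i, j - 1, k] else 0, if (j < d[2]) mask[i, j + 1, k] else 0,
      if (k > 1) mask[i, j, k - 1] else 0, if (k < d[3]) mask[i, j, k + 1] else 0
    )
    if (any(nb <= 0)) coords <- rbind(coords, c(i, j, k))
  }
  coords
}

# all-pairs symmetric surface distances
or_surface_distances <- function(a, b, spacing) {
  ca <- sweep(or_surface_voxels(a), 2, spacing, "*")
  cb <- sweep(or_surface_voxels(b), 2, spacing, "*")
  d_ab <- apply(ca, 1, function(p) min(sqrt(colSums((t(cb) - p)^2))))
  d_ba <- apply(cb, 1, function(p) min(sqrt(colSums((t(ca) - p)^2))))
  pooled <- c(d_ab, d_ba)
  list(hd95 = unname(quantile(pooled, 0.95, type = 7)), assd = mean(pooled),
       hd_max = max(pooled))
}

# all permutations of 1..n (n small)
or_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- or_permutations(n - 1L)
  out <- list()
  for (p in sub) for (pos in 0:(n - 1L)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  }
  out
}

# brute-force minimum assignment cost over all permutations (square matrix)
or_min_assignment <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  for (p in or_permutations(n)) {
    v <- sum(cost[cbind(seq_len(n), p)])
    if (v < best) best <- v
  }
  best
}

# small model configuration for fast structural tests
tiny_config <- function(...) {
  model_config(base_channels = 2, n_dusal = 1, window = 2, heads = 2,
               d_dec = 8, n_queries = 3, t_refine = 2, ...)
}

random_params_spatial <- function(C, d, heads = 1, n = NULL, bias = FALSE) {
  p <- list(Nq = matrix(rnorm(C * d), C, d), Nk = matrix(rnorm(C * d), C, d),
            Nv = matrix(rnorm(C * d), C, d), heads = heads)
  if (bias) p$bias <- matrix(rnorm((2 * n - 1)^2 * heads), (2 * n - 1)^2, heads)
  p
}
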