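# Attention building blocks. Each exported operation is a thin wrapper that
# runs the same tape primitives the network uses, without gradients, so the
# tested op IS the op inside the model.

#' Partition a feature map into non-overlapping windows (and merge back)
#'
#' `window_partition()` cuts an `h x w x C` feature map into `h*w/n^2`
#' windows of `n x n` feature vectors; `window_merge()` is its exact inverse.
#'
#' @param f numeric array `h x w x C` (a matrix is treated as `C = 1`).
#' @param n window side; must divide both spatial sides.
#' @return `window_partition()`: list of `n x n x C` arrays, ordered
#'   column-major over the window grid, with attributes `h`, `w`, `n`.
#' @export
window_partition <- function(f, n) {
  if (is.matrix(f)) f <- array(f, c(dim(f), 1L))
  d <- dim(f)
  n <- as.integer(n)
  if (n <= 0L) stop("window size must be positive", call. = FALSE)
  if (d[1] %% n != 0L || d[2] %% n != 0L)
    stop("window size must divide the feature-map sides", call. = FALSE)
  wins <- list()
  for (wj in seq_len(d[2] %/% n)) for (wi in seq_len(d[1] %/% n)) {
    wins[[length(wins) + 1L]] <-
      f[((wi - 1L) * n + 1L):(wi * n), ((wj - 1L) * n + 1L):(wj * n), , drop = FALSE]
  }
  attr(wins, "h") <- d[1]; attr(wins, "w") <- d[2]; attr(wins, "n") <- n
  wins
}

#' @rdname window_partition
#' @param windows a list produced by `window_partition()`.
#' @export
window_merge <- function(windows) {
  h <- attr(windows, "h"); w <- attr(windows, "w"); n <- attr(windows, "n")
  if (is.null(h)) stop("`windows` must come from window_partition()", call. = FALSE)
  C <- dim(windows[[1]])[3]
  f <- array(0, c(h, w, C))
  k <- 0L
  for (wj in seq_len(w %/% n)) for (wi in seq_len(h %/% n)) {
    k <- k + 1L
    f[((wi - 1L) * n + 1L):(wi * n), ((wj - 1L) * n + 1L):(wj * n), ] <- windows[[k]]
  }
  f
}

# permutation stacking (H*W) x C tokens into contiguous n x n window blocks
win_perm <- function(H, W, n) {
  perm <- integer(H * W)
  k <- 0L
  for (wj in seq_len(W %/% n)) for (wi in seq_len(H %/% n))
    for (c in seq_len(n)) for (r in seq_len(n)) {
      k <- k + 1L
      gr <- (wi - 1L) * n + r
      gc <- (wj - 1L) * n + c
      perm[k] <- (gc - 1L) * H + gr
    }
  perm
}

# relative-position code (1 .. (2n-1)^2) for every (query, key) pair in an
# n x n window, column-major over the n^2 x n^2 logit matrix
relpos_index <- function(n) {
  pos <- expand.grid(r = seq_len(n), c = seq_len(n)) # token order: column-major
  idx <- integer(n^2 * n^2)
  k <- 0L
  for (j in seq_len(n^2)) for (i in seq_len(n^2)) {
    k <- k + 1L
    dr <- pos$r[i] - pos$r[j]
    dc <- pos$c[i] - pos$c[j]
    idx[k] <- (dc + n - 1L) * (2L * n - 1L) + (dr + n)
  }
  idx
}

# largest window size <= n dividing both sides (>= 1)
effective_window <- function(H, W, n) {
  for (d in seq(min(n, H, W), 1L)) if (H %% d == 0L && W %% d == 0L) return(d)
  1L
}

.head_cols <- function(d, heads) {
  dh <- d %/% heads
  lapply(seq_len(heads), function(h) ((h - 1L) * dh + 1L):(h * dh))
}

# tape version used by the model; x: P x C tokens of an H x W grid
nn_spatial_window_attention <- function(tape, x, H, W, prm, n, heads = 1L,
                                        legacy_scale = FALSE) {
  ne <- effective_window(H, W, n)
  perm <- win_perm(H, W, ne)
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  blocks <- (H * W) %/% (ne * ne)
  xp <- ad_gather_rows(tape, x, perm)
  Q <- ad_matmul(tape, xp, prm$Nq)
  K <- ad_matmul(tape, xp, prm$Nk)
  V <- ad_matmul(tape, xp, prm$Nv)
  d <- ncol(prm$Nq$val)
  dh <- d %/% heads
  scale <- if (legacy_scale) sqrt(dh) else 1 / sqrt(dh)
  cols <- .head_cols(d, heads)
  rp <- if (!is.null(prm$bias)) relpos_index(ne) else NULL
  outs <- lapply(seq_len(heads), function(h) {
    bias_h <- NULL
    if (!is.null(prm$bias)) {
      tab <- ad_gather_rows(tape, prm$bias, rp) # (ne^4) x heads
      bias_h <- ad_reshape(tape, ad_cols(tape, tab, h), ne^2, ne^2)
    }
    ad_attention(tape,
                 ad_cols(tape, Q, cols[[h]]),
                 ad_cols(tape, K, cols[[h]]),
                 ad_cols(tape, V, cols[[h]]),
                 scale = scale, bias = bias_h, blocks = blocks)
  })
  o <- if (heads == 1L) outs[[1]] else ad_cbind(tape, outs)
  if (!is.null(prm$Wo)) o <- ad_matmul(tape, o, prm$Wo)
  ad_gather_rows(tape, o, inv)
}

#' Windowed spatial self-attention
#'
#' Scaled dot-product self-attention among the `n^2` tokens of one local
#' window (optionally multi-head, with a learnable relative positional bias
#' added to the logits). The queries, keys and values are linear projections
#' of the window tokens; each attention row is a softmax, so rows sum to 1.
#'
#' @param S window tokens: an `n^2 x C` matrix or `n x n x C` array.
#' @param params list with projection matrices `Nq`, `Nk`, `Nv` (`C x d`),
#'   optional output projection `Wo` (`d x C`), optional relative positional
#'   bias table `bias` (`(2n-1)^2 x heads`), and optionally `heads` (default
#'   1) and `legacy_scale` (use the logit multiplier `sqrt(d)` instead of the
#'   standard divisor).
#' @return Matrix of attended tokens, `n^2` rows.
#' @export
spatial_window_attention <- function(S, params) {
  if (is.array(S) && length(dim(S)) == 3L) {
    n <- dim(S)[1]
    S <- matrix(S, n * n, dim(S)[3])
  } else {
    n <- as.integer(sqrt(nrow(S)))
  }
  if (n * n != nrow(S)) stop("window must hold n^2 tokens", call. = FALSE)
  if (any(!is.finite(S))) stop("NaN/Inf in attention input", call. = FALSE)
  heads <- params$heads %||% 1L
  tape <- ad_tape(grad = FALSE)
  prm <- list(
    Nq = ad_const(tape, params$Nq), Nk = ad_const(tape, params$Nk),
    Nv = ad_const(tape, params$Nv),
    Wo = if (!is.null(params$Wo)) ad_const(tape, params$Wo),
    bias = if (!is.null(params$bias)) ad_const(tape, as_ad_mat(params$bias))
  )
  x <- ad_const(tape, S)
  nn_spatial_window_attention(tape, x, n, n, prm, n = n, heads = heads,
                              legacy_scale = isTRUE(params$legacy_scale))$val
}

# --- spectral attention -------------------------------------------------------

.dft_cache <- new.env(parent = emptyenv())

# real/imaginary parts of the 2-D DFT over a column-major-flattened H x W
# grid, plus the inverse pair, as dense P x P matrices
dft_mats <- function(H, W) {
  key <- paste(H, W, sep = "_")
  hit <- .dft_cache[[key]]
  if (!is.null(hit)) return(hit)
  dft1 <- function(n) {
    j <- 0:(n - 1)
    exp(-2i * pi * outer(j, j) / n)
  }
  Wf <- kronecker(dft1(W), dft1(H)) # vec(F_H X F_W^T) = (F_W %x% F_H) vec(X)
  Wi <- Conj(Wf) / (H * W)
  out <- list(Re = Re(Wf), Im = Im(Wf), iRe = Re(Wi), iIm = Im(Wi))
  .dft_cache[[key]] <- out
  out
}

# single-level Haar transform matrix (orthonormal), even n
haar1 <- function(n) {
  stopifnot(n %% 2L == 0L)
  Hm <- matrix(0, n, n)
  for (i in seq_len(n / 2)) {
    Hm[i, 2 * i - 1] <- 1 / sqrt(2); Hm[i, 2 * i] <- 1 / sqrt(2)
    Hm[n / 2 + i, 2 * i - 1] <- 1 / sqrt(2); Hm[n / 2 + i, 2 * i] <- -1 / sqrt(2)
  }
  Hm
}

dwt_mats <- function(H, W) {
  if (H %% 2L || W %% 2L)
    stop("Haar spectral transform requires even feature-map sides", call. = FALSE)
  Wf <- kronecker(haar1(W), haar1(H))
  list(Re = Wf, Im = matrix(0, H * W, H * W), iRe = t(Wf),
       iIm = matrix(0, H * W, H * W))
}

# channel attention on an arbitrary token matrix (already in the transform
# domain): softmax over the key-channel axis of sigma * K^T Q, applied to V
nn_spectral_channel_attention <- function(tape, tk, Wq, Wk, Wv, sigma) {
  Q <- ad_matmul(tape, tk, Wq)
  K <- ad_matmul(tape, tk, Wk)
  V <- ad_matmul(tape, tk, Wv)
  M <- ad_matmul(tape, ad_transpose(tape, K), Q) # [key, query] channel logits
  M <- ad_mul(tape, M, sigma)
  A <- ad_transpose(tape, ad_softmax_rows(tape, ad_transpose(tape, M)))
  ad_matmul(tape, V, A)
}

#' Spectral (frequency-domain) channel self-attention
#'
#' `spectral_channel_attention()` performs channel-channel attention on a
#' token matrix: with projections `Qb = T Wq`, `Kb = T Wk`, `Vb = T Wv`, the
#' logits `sigma * t(Kb) %*% Qb` are softmax-normalized along the key-channel
#' axis and applied to the value channels. `spectral_attention()` wraps it
#' between a forward and inverse 2-D transform (FFT by default, single-level
#' Haar DWT as alternative) of each feature channel, stacking real and
#' imaginary parts as separate channels; output shape equals input shape.
#'
#' @param tokens numeric matrix (positions x channels) in the transform
#'   domain.
#' @param Wq,Wk,Wv channel projection matrices.
#' @param sigma scalar temperature reweighting the logits.
#' @return Matrix of the same shape as `tokens`.
#' @export
spectral_channel_attention <- function(tokens, Wq, Wk, Wv, sigma = 1) {
  tape <- ad_tape(grad = FALSE)
  nn_spectral_channel_attention(
    tape, ad_const(tape, tokens), ad_const(tape, Wq), ad_const(tape, Wk),
    ad_const(tape, Wv), ad_const(tape, matrix(sigma, 1, 1))
  )$val
}

nn_spectral_attention <- function(tape, x, H, W, prm, transform = "fft") {
  C <- ncol(x$val)
  dm <- if (identical(transform, "dwt")) dwt_mats(H, W) else dft_mats(H, W)
  Rp <- ad_cmatmul(tape, dm$Re, x)
  Ip <- ad_cmatmul(tape, dm$Im, x)
  tk <- ad_cbind(tape, list(Rp, Ip)) # P x 2C frequency channels
  o <- nn_spectral_channel_attention(tape, tk, prm$Wq, prm$Wk, prm$Wv, prm$sigma)
  Ro <- ad_cols(tape, o, seq_len(C))
  Io <- ad_cols(tape, o, C + seq_len(C))
  ad_sub(tape, ad_cmatmul(tape, dm$iRe, Ro), ad_cmatmul(tape, dm$iIm, Io))
}

#' @rdname spectral_channel_attention
#' @param f feature map: `h x w x C` array or `(h*w) x C` matrix (then `h`,
#'   `w` must be given); pixels flattened column-major.
#' @param params list with `Wq`, `Wk`, `Wv` (`2C x 2C`), scalar `sigma`, and
#'   optionally `transform` (`"fft"` or `"dwt"`).
#' @param h,w spatial sides when `f` is a matrix.
#' @export
spectral_attention <- function(f, params, h = NULL, w = NULL) {
  arr <- is.array(f) && length(dim(f)) == 3L
  if (arr) {
    h <- dim(f)[1]; w <- dim(f)[2]
    x <- matrix(f, h * w, dim(f)[3])
  } else {
    if (is.null(h) || is.null(w)) stop("supply `h` and `w` for matrix input", call. = FALSE)
    x <- as.matrix(f)
  }
  tape <- ad_tape(grad = FALSE)
  prm <- list(Wq = ad_const(tape, params$Wq), Wk = ad_const(tape, params$Wk),
              Wv = ad_const(tape, params$Wv),
              sigma = ad_const(tape, matrix(params$sigma %||% 1, 1, 1)))
  out <- nn_spectral_attention(tape, ad_const(tape, x), h, w, prm,
                               transform = params$transform %||% "fft")$val
  if (arr) array(out, c(h, w, ncol(out))) else out
}

# --- masked cross-attention ---------------------------------------------------

# additive attention mask from binary per-query masks: 0 on foreground,
# -Inf elsewhere; queries with an empty mask fall back to unmasked attention
mca_additive_mask <- function(Ybin) {
  m <- matrix(-Inf, nrow(Ybin), ncol(Ybin))
  m[Ybin > 0] <- 0
  empty <- rowSums(Ybin > 0) == 0
  m[empty, ] <- 0
  m
}

nn_masked_cross_attention <- function(tape, A, mask_add, fkv, prm, heads = 1L) {
  Q <- ad_matmul(tape, A, prm$Wq)
  K <- ad_matmul(tape, fkv, prm$Wk)
  V <- ad_matmul(tape, fkv, prm$Wv)
  d <- ncol(prm$Wq$val)
  dh <- d %/% heads
  cols <- .head_cols(d, heads)
  vcols <- .head_cols(ncol(prm$Wv$val), heads)
  outs <- lapply(seq_len(heads), function(h) {
    ad_attention(tape,
                 ad_cols(tape, Q, cols[[h]]),
                 ad_cols(tape, K, cols[[h]]),
                 ad_cols(tape, V, vcols[[h]]),
                 scale = 1 / sqrt(dh), mask = mask_add)
  })
  o <- if (heads == 1L) outs[[1]] else ad_cbind(tape, outs)
  ad_add(tape, A, o) # residual query update
}

#' Masked cross-attention query update
#'
#' One refinement step of the organ queries: every query attends to the
#' feature-map pixels inside its current binary mask (attention logits at
#' masked-out pixels are set to `-Inf` before the softmax, so the output is
#' exactly invariant to features there), and the attended value is added to
#' the query as a residual update. A query whose mask is empty falls back to
#' unmasked attention over all pixels.
#'
#' @param A query matrix `X x D`.
#' @param Y binary masks `X x P` (one row per query).
#' @param f feature tokens `P x C`.
#' @param params list with `Wq` (`D x d`), `Wk` (`C x d`), `Wv` (`C x D`),
#'   optionally `heads`.
#' @return Updated query matrix `X x D`.
#' @export
masked_cross_attention <- function(A, Y, f, params) {
  stopifnot(nrow(A) == nrow(Y), ncol(Y) == nrow(f))
  tape <- ad_tape(grad = FALSE)
  prm <- list(Wq = ad_const(tape, params$Wq), Wk = ad_const(tape, params$Wk),
              Wv = ad_const(tape, params$Wv))
  nn_masked_cross_attention(tape, ad_const(tape, A), mca_additive_mask(Y),
                            ad_const(tape, f), prm,
                            heads = params$heads %||% 1L)$val
}

#' Coarse mask prediction from organ queries
#'
#' Per-query, per-pixel logits are the dot products of the query vectors with
#' the feature tokens; probabilities are their sigmoid, and the binary mask
#' applies the sharp cutoff `probability >= tau`.
#'
#' @param A query matrix `X x D`.
#' @param f feature tokens `P x D`.
#' @param tau binarization threshold (default 0.6; the boundary value counts
#'   as foreground).
#' @return List with `logits`, `prob` and binary `mask`, each `X x P`.
#' @export
coarse_predict <- function(A, f, tau = 0.6) {
  if (ncol(A) != ncol(f))
    stop("query dimension must match the feature dimension", call. = FALSE)
  logits <- A %*% t(f)
  prob <- 1 / (1 + exp(-logits))
  list(logits = logits, prob = prob, mask = (prob >= tau) * 1)
}

#' Classify organ queries
#'
#' Linear classification head mapping each refined query to `C + 1` logits
#' (the semantic classes plus a no-object slot).
#'
#' @param A query matrix `X x D`.
#' @param W_fc weight matrix `D x (C+1)`.
#' @param b optional bias (length `C+1`).
#' @return Logit matrix `X x (C+1)`.
#' @export
classify_queries <- function(A, W_fc, b = NULL) {
  out <- A %*% W_fc
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
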