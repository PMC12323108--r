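# Reverse-mode automatic differentiation on a tape of matrix operations.
# Internal machinery for the network: nodes are environments holding a value
# matrix, an accumulated gradient and a backward closure; ad_backward() walks
# the tape in reverse creation order. Only the primitives the architecture
# needs are implemented (matmul, elementwise ops, softmax/attention,
# layer norm, gather/scatter for im2col convolutions).

ad_tape <- function(grad = TRUE) {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t$grad <- isTRUE(grad)
  t
}

ad_node <- function(tape, val, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backfn <- if (tape$grad) backfn else NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

is_ad_node <- function(x) is.environment(x) && !is.null(x$val)

ad_const <- function(tape, val) ad_node(tape, as_ad_mat(val))
ad_param <- ad_const # params are leaves; their $grad is read after backward

as_ad_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = if (length(x) == 1L) 1L else length(x))
}

ad_acc <- function(node, g) {
  if (is.null(node$backfn) && is.null(node$grad) && !isTRUE(node$leaf)) {
    # still accumulate; leaves read it, dead consts just waste a matrix
  }
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

ad_backward <- function(tape, loss) {
  stopifnot(tape$grad)
  loss$grad <- matrix(1, 1, 1)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backfn) && !is.null(nd$grad)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

# --- scalar-broadcast helpers -------------------------------------------------

.ad_is_scalar <- function(v) length(v) == 1L

# reduce gradient g to the shape of value v (handles 1x1 broadcast)
.ad_fit <- function(g, v) {
  if (.ad_is_scalar(v) && length(g) != 1L) matrix(sum(g), 1, 1) else g
}

.ad_wrap <- function(tape, x) if (is_ad_node(x)) x else ad_const(tape, x)

# --- arithmetic ---------------------------------------------------------------

ad_add <- function(tape, a, b) {
  a <- .ad_wrap(tape, a); b <- .ad_wrap(tape, b)
  av <- a$val; bv <- b$val
  val <- if (.ad_is_scalar(av)) av[1] + bv else if (.ad_is_scalar(bv)) av + bv[1] else av + bv
  ad_node(tape, val, function(g) {
    ad_acc(a, .ad_fit(g, av)); ad_acc(b, .ad_fit(g, bv))
  })
}

ad_sub <- function(tape, a, b) {
  a <- .ad_wrap(tape, a); b <- .ad_wrap(tape, b)
  av <- a$val; bv <- b$val
  val <- if (.ad_is_scalar(av)) av[1] - bv else if (.ad_is_scalar(bv)) av - bv[1] else av - bv
  ad_node(tape, val, function(g) {
    ad_acc(a, .ad_fit(g, av)); ad_acc(b, .ad_fit(-g, bv))
  })
}

ad_mul <- function(tape, a, b) {
  a <- .ad_wrap(tape, a); b <- .ad_wrap(tape, b)
  av <- a$val; bv <- b$val
  val <- if (.ad_is_scalar(av)) av[1] * bv else if (.ad_is_scalar(bv)) av * bv[1] else av * bv
  ad_node(tape, val, function(g) {
    ga <- if (.ad_is_scalar(bv)) g * bv[1] else g * bv
    gb <- if (.ad_is_scalar(av)) g * av[1] else g * av
    ad_acc(a, .ad_fit(ga, av)); ad_acc(b, .ad_fit(gb, bv))
  })
}

ad_div <- function(tape, a, b) {
  a <- .ad_wrap(tape, a); b <- .ad_wrap(tape, b)
  av <- a$val; bv <- b$val
  val <- if (.ad_is_scalar(bv)) av / bv[1] else av / bv
  ad_node(tape, val, function(g) {
    ga <- if (.ad_is_scalar(bv)) g / bv[1] else g / bv
    gb <- -g * val / (if (.ad_is_scalar(bv)) bv[1] else bv)
    ad_acc(a, .ad_fit(ga, av)); ad_acc(b, .ad_fit(gb, bv))
  })
}

ad_matmul <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  ad_node(tape, av %*% bv, function(g) {
    ad_acc(a, g %*% t(bv)); ad_acc(b, t(av) %*% g)
  })
}

# constant matrix times node (e.g. DFT matrices)
ad_cmatmul <- function(tape, W, x) {
  ad_node(tape, W %*% x$val, function(g) ad_acc(x, t(W) %*% g))
}

ad_add_bias <- function(tape, x, b) { # b: 1 x C
  bv <- b$val
  ad_node(tape, sweep(x$val, 2L, as.vector(bv), "+"), function(g) {
    ad_acc(x, g); ad_acc(b, matrix(colSums(g), 1L))
  })
}

ad_transpose <- function(tape, x) {
  ad_node(tape, t(x$val), function(g) ad_acc(x, t(g)))
}

# --- nonlinearities -----------------------------------------------------------

ad_relu <- function(tape, x) {
  keep <- x$val > 0
  ad_node(tape, x$val * keep, function(g) ad_acc(x, g * keep))
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$val))
  ad_node(tape, s, function(g) ad_acc(x, g * s * (1 - s)))
}

ad_exp <- function(tape, x) {
  v <- exp(x$val)
  ad_node(tape, v, function(g) ad_acc(x, g * v))
}

ad_log <- function(tape, x) {
  v <- x$val
  ad_node(tape, log(v), function(g) ad_acc(x, g / v))
}

ad_clamp <- function(tape, x, lo, hi) {
  inside <- x$val >= lo & x$val <= hi
  ad_node(tape, pmin(pmax(x$val, lo), hi), function(g) ad_acc(x, g * inside))
}

ad_sum <- function(tape, x) {
  v <- x$val
  ad_node(tape, matrix(sum(v), 1, 1), function(g)
    ad_acc(x, matrix(g[1], nrow(v), ncol(v))))
}

ad_mean <- function(tape, x) {
  v <- x$val
  ad_node(tape, matrix(mean(v), 1, 1), function(g)
    ad_acc(x, matrix(g[1] / length(v), nrow(v), ncol(v))))
}

ad_softmax_rows <- function(tape, x, mask = NULL) {
  s <- x$val
  if (!is.null(mask)) s <- s + mask
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  a <- e / rowSums(e)
  ad_node(tape, a, function(g) {
    ad_acc(x, (g - rowSums(g * a)) * a)
  })
}

# layer norm across columns of each row, learnable per-column gamma/beta (1 x C)
ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  v <- x$val
  C <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$val)
  out <- sweep(xhat, 2L, gv, "*")
  out <- sweep(out, 2L, as.vector(beta$val), "+")
  ad_node(tape, out, function(g) {
    ad_acc(gamma, matrix(colSums(g * xhat), 1L))
    ad_acc(beta, matrix(colSums(g), 1L))
    gx <- sweep(g, 2L, gv, "*")
    # standard layer-norm backward per row
    gi <- inv * (gx - rowMeans(gx) - xhat * rowMeans(gx * xhat))
    ad_acc(x, gi)
  })
}

# gather rows (with repetition); backward is scatter-add
ad_gather_rows <- function(tape, x, idx) {
  v <- x$val
  ad_node(tape, v[idx, , drop = FALSE], function(g) {
    dg <- matrix(0, nrow(v), ncol(v))
    rs <- rowsum(g, group = idx)
    dg[as.integer(rownames(rs)), ] <- rs
    ad_acc(x, dg)
  })
}

ad_cols <- function(tape, x, idx) {
  v <- x$val
  ad_node(tape, v[, idx, drop = FALSE], function(g) {
    dg <- matrix(0, nrow(v), ncol(v))
    # idx assumed without repetition (head/channel splits)
    dg[, idx] <- g
    ad_acc(x, dg)
  })
}

ad_cbind <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$val)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, vals), function(g) {
    for (i in seq_along(nodes))
      ad_acc(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
  })
}

# --- im2col convolution -------------------------------------------------------

# pixel layout: feature maps are (H*W) x C matrices, pixels flattened
# column-major from an H x W grid (p = (col-1)*H + row).
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(H, W, stride = 1L) {
  key <- paste(H, W, stride, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  rows <- seq(1L, H, by = stride)
  cols <- seq(1L, W, by = stride)
  ctr <- expand.grid(r = rows, c = cols) # column-major over output grid
  offs <- expand.grid(dr = -1:1, dc = -1:1) # 9 offsets, column-major
  idx <- vector("list", 9L)
  ok <- vector("list", 9L)
  for (k in 1:9) {
    r <- ctr$r + offs$dr[k]; c <- ctr$c + offs$dc[k]
    valid <- r >= 1L & r <= H & c >= 1L & c <= W
    i <- (pmin(pmax(c, 1L), W) - 1L) * H + pmin(pmax(r, 1L), H)
    idx[[k]] <- i; ok[[k]] <- valid
  }
  out <- list(idx = idx, ok = ok, Ho = length(rows), Wo = length(cols))
  .im2col_cache[[key]] <- out
  out
}

# x: (H*W) x C node -> (Ho*Wo) x (9C) node (zero padding outside the grid)
ad_im2col <- function(tape, x, H, W, stride = 1L) {
  v <- x$val
  C <- ncol(v)
  ix <- im2col_index(H, W, stride)
  P <- ix$Ho * ix$Wo
  out <- matrix(0, P, 9L * C)
  for (k in 1:9) {
    blk <- v[ix$idx[[k]], , drop = FALSE]
    blk[!ix$ok[[k]], ] <- 0
    out[, ((k - 1L) * C + 1L):(k * C)] <- blk
  }
  ad_node(tape, out, function(g) {
    dg <- matrix(0, nrow(v), C)
    for (k in 1:9) {
      gk <- g[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
      sel <- ix$ok[[k]]
      ii <- ix$idx[[k]][sel]
      dg[ii, ] <- dg[ii, ] + gk[sel, , drop = FALSE]
    }
    ad_acc(x, dg)
  })
}

# --- fused attention ----------------------------------------------------------

# Scaled dot-product attention over `blocks` equal row-blocks of q (and of
# k/v). bias: optional node (m x mk), shared across blocks (gradient
# accumulates). mask: optional constant additive matrix (m x mk).
ad_attention <- function(tape, q, k, v, scale, bias = NULL, mask = NULL,
                         blocks = 1L) {
  qv <- q$val; kv <- k$val; vv <- v$val
  m <- nrow(qv) / blocks; mk <- nrow(kv) / blocks
  stopifnot(m == as.integer(m), mk == as.integer(mk))
  m <- as.integer(m); mk <- as.integer(mk)
  A <- vector("list", blocks)
  out <- matrix(0, nrow(qv), ncol(vv))
  bval <- if (!is.null(bias)) bias$val else NULL
  for (b in seq_len(blocks)) {
    qi <- ((b - 1L) * m + 1L):(b * m)
    ki <- ((b - 1L) * mk + 1L):(b * mk)
    S <- (qv[qi, , drop = FALSE] %*% t(kv[ki, , drop = FALSE])) * scale
    if (!is.null(bval)) S <- S + bval
    if (!is.null(mask)) S <- S + mask
    S <- S - apply(S, 1L, max)
    E <- exp(S)
    Ab <- E / rowSums(E)
    A[[b]] <- Ab
    out[qi, ] <- Ab %*% vv[ki, , drop = FALSE]
  }
  ad_node(tape, out, function(g) {
    dq <- matrix(0, nrow(qv), ncol(qv))
    dk <- matrix(0, nrow(kv), ncol(kv))
    dv <- matrix(0, nrow(vv), ncol(vv))
    db <- if (!is.null(bias)) matrix(0, m, mk) else NULL
    for (b in seq_len(blocks)) {
      qi <- ((b - 1L) * m + 1L):(b * m)
      ki <- ((b - 1L) * mk + 1L):(b * mk)
      Ab <- A[[b]]
      gO <- g[qi, , drop = FALSE]
      dv[ki, ] <- dv[ki, ] + t(Ab) %*% gO
      dA <- gO %*% t(vv[ki, , drop = FALSE])
      dS <- (dA - rowSums(dA * Ab)) * Ab
      dq[qi, ] <- dq[qi, ] + (dS %*% kv[ki, , drop = FALSE]) * scale
      dk[ki, ] <- dk[ki, ] + (t(dS) %*% qv[qi, , drop = FALSE]) * scale
      if (!is.null(db)) db <- db + dS
    }
    ad_acc(q, dq); ad_acc(k, dk); ad_acc(v, dv)
    if (!is.null(bias)) ad_acc(bias, db)
  })
}

# --- fused losses -------------------------------------------------------------

# numerically stable mean binary cross-entropy with logits
ad_bce_logits <- function(tape, logits, target) {
  x <- logits$val
  v <- mean(pmax(x, 0) - x * target + log1p(exp(-abs(x))))
  ad_node(tape, matrix(v, 1, 1), function(g) {
    p <- 1 / (1 + exp(-x))
    ad_acc(logits, g[1] * (p - target) / length(x))
  })
}

# soft dice loss with logits; smoothing s
ad_dice_logits <- function(tape, logits, target, s = 1) {
  x <- logits$val
  p <- 1 / (1 + exp(-x))
  num <- 2 * sum(p * target) + s
  den <- sum(p) + sum(target) + s
  ad_node(tape, matrix(1 - num / den, 1, 1), function(g) {
    dp <- -(2 * target * den - num) / den^2
    ad_acc(logits, g[1] * dp * p * (1 - p))
  })
}

# weighted mean softmax cross-entropy: logits (n x K), target class index
# vector (1..K), per-row weights; mean over sum of weights
ad_softmax_xent <- function(tape, logits, target, weights = NULL) {
  x <- logits$val
  n <- nrow(x); K <- ncol(x)
  if (is.null(weights)) weights <- rep(1, n)
  sm <- x - apply(x, 1L, max)
  e <- exp(sm)
  p <- e / rowSums(e)
  ce <- -log(pmax(p[cbind(seq_len(n), target)], 1e-12))
  wsum <- sum(weights)
  ad_node(tape, matrix(sum(weights * ce) / wsum, 1, 1), function(g) {
    tg <- matrix(0, n, K)
    tg[cbind(seq_len(n), target)] <- 1
    ad_acc(logits, g[1] * (p - tg) * (weights / wsum))
  })
}

ad_reshape <- function(tape, x, nr, nc) {
  v <- x$val
  ad_node(tape, matrix(as.vector(v), nr, nc), function(g)
    ad_acc(x, matrix(as.vector(g), nrow(v), ncol(v))))
}
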