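#' Model configuration
#'
#' Hyperparameters of the dual self-attentive transformer U-Net. The network
#' is 2-D and applied per axial slice; volumes are handled slice-wise and
#' re-assembled. Feature channels double per encoder stage starting at
#' `base_channels`; the deepest map (stride 8) feeds the transformer encoder.
#'
#' @param base_channels channels of the first CNN stage (doubled per stage).
#' @param n_dusal number of dual self-attention layers (DuSALs) per
#'   transformer block.
#' @param window spatial attention window side `n`; if it does not divide the
#'   deepest feature-map side, the largest divisor `<= n` is used.
#' @param heads attention heads (must divide `8 * base_channels` and `d_dec`).
#' @param d_dec organ-query dimension.
#' @param n_queries number of organ queries `X`.
#' @param n_classes semantic classes `C` (default 2: background, pancreas).
#' @param t_refine masked cross-attention refinement iterations `T`.
#' @param tau mask binarization cutoff (probability `>= tau` is foreground).
#' @param spectral frequency transform for spectral attention: `"fft"` or
#'   `"dwt"` (single-level Haar).
#' @param mlp_ratio expansion ratio of the DuSAL MLP.
#' @param legacy_scale use the attention logit multiplier `sqrt(d)` instead
#'   of the standard divisor `1/sqrt(d)`.
#' @return A `model_config` object.
#' @export
model_config <- function(base_channels = 16L, n_dusal = 2L, window = 7L,
                         heads = 4L, d_dec = 64L, n_queries = 8L,
                         n_classes = 2L, t_refine = 3L, tau = 0.6,
                         spectral = c("fft", "dwt"), mlp_ratio = 2,
                         legacy_scale = FALSE) {
  spectral <- match.arg(spectral)
  stopifnot(base_channels >= 1, n_dusal >= 0, window >= 1, heads >= 1,
            d_dec >= heads, n_queries >= n_classes, t_refine >= 1,
            tau > 0, tau < 1, mlp_ratio > 0)
  c4 <- 8L * as.integer(base_channels)
  if (c4 %% heads != 0L || d_dec %% heads != 0L)
    stop("`heads` must divide both 8*base_channels and d_dec", call. = FALSE)
  structure(list(
    base_channels = as.integer(base_channels), n_dusal = as.integer(n_dusal),
    window = as.integer(window), heads = as.integer(heads),
    d_dec = as.integer(d_dec), n_queries = as.integer(n_queries),
    n_classes = as.integer(n_classes), t_refine = as.integer(t_refine),
    tau = tau, spectral = spectral, mlp_ratio = mlp_ratio,
    legacy_scale = isTRUE(legacy_scale)
  ), class = "model_config")
}

.xavier <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

.ln_init <- function(C) list(g = matrix(1, 1, C), b = matrix(0, 1, C))

.dusal_init <- function(C, cfg) {
  n <- cfg$window
  list(
    ln1 = .ln_init(C),
    sp = list(Nq = .xavier(C, C), Nk = .xavier(C, C), Nv = .xavier(C, C),
              Wo = .xavier(C, C),
              bias = matrix(0, (2L * n - 1L)^2, cfg$heads)),
    ln2 = .ln_init(C),
    spec = list(Wq = .xavier(2L * C, 2L * C), Wk = .xavier(2L * C, 2L * C),
                Wv = .xavier(2L * C, 2L * C),
                sigma = matrix(1 / sqrt(2 * C), 1, 1)),
    ln3 = .ln_init(C),
    mlp = list(w1 = .xavier(C, round(cfg$mlp_ratio * C)),
               b1 = matrix(0, 1, round(cfg$mlp_ratio * C)),
               w2 = .xavier(round(cfg$mlp_ratio * C), C),
               b2 = matrix(0, 1, C))
  )
}

#' Initialize a model
#'
#' Builds the full parameter set (CNN encoder/decoder, transformer encoder
#' DuSALs, masked cross-attention decoder, organ queries, classification
#' head) with seeded Xavier-uniform initialization.
#'
#' @param config a [model_config].
#' @param seed integer RNG seed for the initialization.
#' @return A `pancseg_model` object (fields `config`, `params`).
#' @export
init_model <- function(config = model_config(), seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  bc <- config$base_channels
  ch <- c(bc, 2L * bc, 4L * bc, 8L * bc)
  D <- config$d_dec
  params <- list(
    enc = list(
      list(w = .xavier(9L, ch[1]), b = matrix(0, 1, ch[1])),
      list(w = .xavier(9L * ch[1], ch[2]), b = matrix(0, 1, ch[2])),
      list(w = .xavier(9L * ch[2], ch[3]), b = matrix(0, 1, ch[3])),
      list(w = .xavier(9L * ch[3], ch[4]), b = matrix(0, 1, ch[4]))
    ),
    dsat = list(
      dusals = lapply(seq_len(config$n_dusal), function(i) .dusal_init(ch[4], config)),
      conv = list(w = .xavier(9L * ch[4], ch[4]), b = matrix(0, 1, ch[4]))
    ),
    dec = list(
      list(w = .xavier(9L * (ch[4] + ch[3]), ch[3]), b = matrix(0, 1, ch[3])),
      list(w = .xavier(9L * (ch[3] + ch[2]), ch[2]), b = matrix(0, 1, ch[2])),
      list(w = .xavier(9L * (ch[2] + ch[1]), ch[1]), b = matrix(0, 1, ch[1]))
    ),
    proj_mid = list(w = .xavier(ch[3], D), b = matrix(0, 1, D)),
    proj_full = list(w = .xavier(ch[1], D), b = matrix(0, 1, D)),
    mca = list(Wq = .xavier(D, D), Wk = .xavier(D, D), Wv = .xavier(D, D)),
    queries = matrix(stats::rnorm(config$n_queries * D, sd = 0.02),
                     config$n_queries, D),
    cls = list(w = .xavier(D, config$n_classes + 1L),
               b = matrix(0, 1, config$n_classes + 1L))
  )
  structure(list(config = config, params = params), class = "pancseg_model")
}

#' @export
print.pancseg_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params), length, numeric(1)))
  cat(sprintf(
    "<pancseg_model> base_channels=%d, N=%d DuSALs, window=%d, heads=%d, X=%d queries, T=%d, %s spectral transform, %s parameters\n",
    x$config$base_channels, x$config$n_dusal, x$config$window, x$config$heads,
    x$config$n_queries, x$config$t_refine, x$config$spectral,
    format(np, big.mark = ",")))
  invisible(x)
}

# --- parameter plumbing -------------------------------------------------------

flatten_params <- function(p, prefix = "") {
  out <- list()
  nms <- names(p)
  if (is.null(nms)) nms <- as.character(seq_along(p))
  for (i in seq_along(p)) {
    nm <- if (is.null(names(p)) || !nzchar(names(p)[i])) as.character(i) else names(p)[i]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- p[[i]]
    if (is.list(v)) out <- c(out, flatten_params(v, key))
    else out[[key]] <- v
  }
  out
}

unflatten_set <- function(p, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  expr <- p
  # recursive assignment
  assign_rec <- function(node, path, value) {
    if (length(path) == 1L) { node[[path]] <- value; return(node) }
    node[[path[1]]] <- assign_rec(node[[path[1]]], path[-1], value)
    node
  }
  assign_rec(p, path, value)
}

# wrap every parameter matrix as a tape node, preserving structure
wrap_params <- function(tape, p) {
  lapply(p, function(v) {
    if (is.list(v)) wrap_params(tape, v) else ad_param(tape, v)
  })
}

# collect gradients from a wrapped parameter tree (zeros where untouched)
collect_grads <- function(pw) {
  lapply(pw, function(v) {
    if (is.list(v)) collect_grads(v)
    else if (is.null(v$grad)) matrix(0, nrow(v$val), ncol(v$val))
    else v$grad
  })
}

# numbered list names for lapply results get lost; restore by template
name_like <- function(x, template) {
  if (is.list(template)) {
    names(x) <- names(template)
    for (i in seq_along(x)) if (is.list(template[[i]])) x[[i]] <- name_like(x[[i]], template[[i]])
  }
  x
}

# --- forward pass -------------------------------------------------------------

nn_conv <- function(tape, x, H, W, prm, stride = 1L, relu = TRUE) {
  col <- ad_im2col(tape, x, H, W, stride)
  z <- ad_add_bias(tape, ad_matmul(tape, col, prm$w), prm$b)
  if (relu) z <- ad_relu(tape, z)
  ix <- im2col_index(H, W, stride)
  list(x = z, H = ix$Ho, W = ix$Wo)
}

.up_cache <- new.env(parent = emptyenv())
up_index <- function(H, W) {
  key <- paste(H, W, sep = "_")
  hit <- .up_cache[[key]]
  if (!is.null(hit)) return(hit)
  rs <- rep(ceiling(seq_len(2L * H) / 2), times = 2L * W)
  cs <- rep(ceiling(seq_len(2L * W) / 2), each = 2L * H)
  idx <- (cs - 1L) * H + rs
  .up_cache[[key]] <- idx
  idx
}

nn_dusal <- function(tape, x, H, W, p, cfg) {
  a <- ad_layernorm(tape, x, p$ln1$g, p$ln1$b)
  a <- nn_spatial_window_attention(tape, a, H, W, p$sp, n = cfg$window,
                                   heads = cfg$heads,
                                   legacy_scale = cfg$legacy_scale)
  x <- ad_add(tape, x, a)
  b <- ad_layernorm(tape, x, p$ln2$g, p$ln2$b)
  b <- nn_spectral_attention(tape, b, H, W, p$spec, transform = cfg$spectral)
  x <- ad_add(tape, x, b)
  cmlp <- ad_layernorm(tape, x, p$ln3$g, p$ln3$b)
  cmlp <- ad_relu(tape, ad_add_bias(tape, ad_matmul(tape, cmlp, p$mlp$w1), p$mlp$b1))
  cmlp <- ad_add_bias(tape, ad_matmul(tape, cmlp, p$mlp$w2), p$mlp$b2)
  ad_add(tape, x, cmlp)
}

nn_dsat <- function(tape, x, H, W, p, cfg) {
  x0 <- x
  for (q in seq_along(p$dusals)) x <- nn_dusal(tape, x, H, W, p$dusals[[q]], cfg)
  cv <- nn_conv(tape, x, H, W, p$conv, stride = 1L, relu = FALSE)
  ad_add(tape, cv$x, x0)
}

# full forward on one 2-D slice (matrix H x W, sides divisible by 8);
# returns tape nodes plus plain-array side products
nn_forward <- function(tape, pw, img, cfg) {
  H <- nrow(img); W <- ncol(img)
  if (H %% 8L || W %% 8L) stop("slice sides must be divisible by 8", call. = FALSE)
  x <- ad_const(tape, matrix(as.vector(img), H * W, 1L))
  e1 <- nn_conv(tape, x, H, W, pw$enc[[1]], 1L)
  e2 <- nn_conv(tape, e1$x, e1$H, e1$W, pw$enc[[2]], 2L)
  e3 <- nn_conv(tape, e2$x, e2$H, e2$W, pw$enc[[3]], 2L)
  e4 <- nn_conv(tape, e3$x, e3$H, e3$W, pw$enc[[4]], 2L)
  fs <- nn_dsat(tape, e4$x, e4$H, e4$W, pw$dsat, cfg)
  # CNN decoder with skip connections
  u3 <- ad_gather_rows(tape, fs, up_index(e4$H, e4$W))
  d3 <- nn_conv(tape, ad_cbind(tape, list(u3, e3$x)), e3$H, e3$W, pw$dec[[1]], 1L)
  u2 <- ad_gather_rows(tape, d3$x, up_index(e3$H, e3$W))
  d2 <- nn_conv(tape, ad_cbind(tape, list(u2, e2$x)), e2$H, e2$W, pw$dec[[2]], 1L)
  u1 <- ad_gather_rows(tape, d2$x, up_index(e2$H, e2$W))
  d1 <- nn_conv(tape, ad_cbind(tape, list(u1, e1$x)), e1$H, e1$W, pw$dec[[3]], 1L)
  fmid <- ad_add_bias(tape, ad_matmul(tape, d3$x, pw$proj_mid$w), pw$proj_mid$b)
  ffull <- ad_add_bias(tape, ad_matmul(tape, d1$x, pw$proj_full$w), pw$proj_full$b)
  A <- pw$queries
  # coarse prediction against the stride-4 decoder map
  Ylog <- ad_matmul(tape, A, ad_transpose(tape, fmid))
  Ybin <- (1 / (1 + exp(-Ylog$val)) >= cfg$tau) * 1
  # granular attention refinement
  for (i in seq_len(cfg$t_refine)) {
    A <- nn_masked_cross_attention(tape, A, mca_additive_mask(Ybin), fmid,
                                   pw$mca, heads = cfg$heads)
    Ylog <- ad_matmul(tape, A, ad_transpose(tape, fmid))
    Ybin <- (1 / (1 + exp(-Ylog$val)) >= cfg$tau) * 1
  }
  mask_logits <- ad_matmul(tape, A, ad_transpose(tape, ffull))
  class_logits <- ad_add_bias(tape, ad_matmul(tape, A, pw$cls$w), pw$cls$b)
  list(mask_logits = mask_logits, class_logits = class_logits,
       queries = A, coarse_logits = Ylog, coarse_bin = Ybin,
       H = H, W = W, Hmid = e3$H, Wmid = e3$W)
}

# --- exported block-level operations -----------------------------------------

#' CNN encoder feature pyramid
#'
#' Runs the convolutional encoder of a model on one slice and returns the
#' feature maps at strides 1, 2, 4 and 8 as `h x w x C` arrays.
#'
#' @param model a [init_model()] object.
#' @param image numeric matrix (slice), sides divisible by 8.
#' @return List of 4 feature arrays, shallow to deep.
#' @export
cnn_encode <- function(model, image) {
  tape <- ad_tape(grad = FALSE)
  pw <- wrap_params(tape, model$params)
  H <- nrow(image); W <- ncol(image)
  x <- ad_const(tape, matrix(as.vector(image), H * W, 1L))
  maps <- list()
  st <- list(c(1L, H, W))
  e <- list(x = x, H = H, W = W)
  strides <- c(1L, 2L, 2L, 2L)
  for (s in 1:4) {
    e <- nn_conv(tape, e$x, e$H, e$W, pw$enc[[s]], strides[s])
    maps[[s]] <- array(e$x$val, c(e$H, e$W, ncol(e$x$val)))
  }
  maps
}

#' One dual self-attention layer (DuSAL)
#'
#' Pre-norm residual stack: layer norm, windowed spatial self-attention,
#' layer norm, spectral channel attention, then a two-layer MLP with ReLU —
#' each sub-block added back to its input. Shape-preserving.
#'
#' @param f feature map `h x w x C` array (or `(h*w) x C` matrix with `h`,
#'   `w` supplied).
#' @param params one DuSAL parameter list (see [init_model()] structure:
#'   `ln1`, `sp`, `ln2`, `spec`, `ln3`, `mlp`).
#' @param config a [model_config] (window size, heads, transform).
#' @param h,w spatial sides when `f` is a matrix.
#' @return Same shape as the input.
#' @export
dusal_forward <- function(f, params, config = model_config(), h = NULL, w = NULL) {
  arr <- is.array(f) && length(dim(f)) == 3L
  if (arr) { h <- dim(f)[1]; w <- dim(f)[2]; x <- matrix(f, h * w, dim(f)[3]) }
  else x <- as.matrix(f)
  tape <- ad_tape(grad = FALSE)
  pw <- wrap_params(tape, params)
  out <- nn_dusal(tape, ad_const(tape, x), h, w, pw, config)$val
  if (arr) array(out, c(h, w, ncol(out))) else out
}

#' Transformer encoder block (DuSAL stack + convolution + long residual)
#'
#' Applies `N` DuSALs, a 3x3 convolution, and adds the block input back
#' (so zeroed convolution weights reduce the block to the identity).
#'
#' @inheritParams dusal_forward
#' @param params list with `dusals` (list of DuSAL parameter lists, may be
#'   empty) and `conv` (`w`, `b`).
#' @return Same shape as the input.
#' @export
dsat_encode <- function(f, params, config = model_config(), h = NULL, w = NULL) {
  arr <- is.array(f) && length(dim(f)) == 3L
  if (arr) { h <- dim(f)[1]; w <- dim(f)[2]; x <- matrix(f, h * w, dim(f)[3]) }
  else x <- as.matrix(f)
  tape <- ad_tape(grad = FALSE)
  pw <- wrap_params(tape, params)
  out <- nn_dsat(tape, ad_const(tape, x), h, w, pw, config)$val
  if (arr) array(out, c(h, w, ncol(out))) else out
}

#' Iterative granular attention refinement
#'
#' Alternates masked cross-attention query updates with mask re-prediction:
#' for `i = 0 .. T-1`, `A_{i+1}` attends to the features inside the current
#' binary mask `Y_i` and `Y_{i+1}` is re-predicted from the updated queries.
#'
#' @param A0 initial query matrix `X x D`.
#' @param Y0 initial binary masks `X x P`.
#' @param f feature tokens `P x D` (keys/values and mask-prediction map).
#' @param params masked cross-attention parameters (`Wq`, `Wk`, `Wv`,
#'   optionally `heads`).
#' @param t_refine number of iterations `T >= 1`.
#' @param tau binarization cutoff.
#' @return List with final `A`, `Y` (binary), and `prob`.
#' @export
refine <- function(A0, Y0, f, params, t_refine = 1L, tau = 0.6) {
  stopifnot(t_refine >= 1L)
  A <- A0; Y <- Y0
  prob <- NULL
  for (i in seq_len(t_refine)) {
    A <- masked_cross_attention(A, Y, f, params)
    cp <- coarse_predict(A, f, tau)
    Y <- cp$mask; prob <- cp$prob
  }
  list(A = A, Y = Y, prob = prob)
}

# fuse per-query masks and class posteriors into semantic maps
fuse_queries <- function(mask_prob, class_logits, n_classes) {
  p <- exp(class_logits - apply(class_logits, 1L, max))
  p <- p / rowSums(p) # X x (C+1), last slot = no-object
  S <- t(mask_prob) %*% p[, seq_len(n_classes), drop = FALSE] # P x C
  tot <- rowSums(S)
  prob <- S[, n_classes] / pmax(tot, 1e-12) # pancreas = last semantic class
  label <- max.col(S, ties.method = "first") - 1L # 0 = background
  label[tot < 1e-12] <- 0L
  list(prob = prob, label = label, class_post = p)
}

#' Segment one CT slice
#'
#' Full forward pass of the network on a preprocessed slice: CNN encoder,
#' transformer encoder, CNN decoder, coarse query prediction, iterative
#' masked-attention refinement and query classification; the per-query masks
#' and class posteriors are fused into a per-pixel pancreas probability (in
#' `[0, 1]`) and an argmax label map. Slices whose sides are not divisible by
#' 8 are replicate-padded and cropped back.
#'
#' @param model a `pancseg_model`.
#' @param image numeric matrix (one standardized slice).
#' @return A `segmentation_result`: list with `prob` and `label` matrices
#'   shaped like `image`, per-query `query_masks` (`X x pixels`, sigmoid
#'   probabilities at full resolution), `class_logits` (`X x (C+1)`) and the
#'   refined `queries`.
#' @export
segment_slice <- function(model, image) {
  H0 <- nrow(image); W0 <- ncol(image)
  H <- 8L * ((H0 + 7L) %/% 8L); W <- 8L * ((W0 + 7L) %/% 8L)
  img <- image[pmin(seq_len(H), H0), pmin(seq_len(W), W0), drop = FALSE]
  tape <- ad_tape(grad = FALSE)
  pw <- wrap_params(tape, model$params)
  fw <- nn_forward(tape, pw, img, model$config)
  mask_prob <- 1 / (1 + exp(-fw$mask_logits$val))
  fz <- fuse_queries(mask_prob, fw$class_logits$val, model$config$n_classes)
  prob <- matrix(fz$prob, H, W)[seq_len(H0), seq_len(W0), drop = FALSE]
  label <- matrix(fz$label, H, W)[seq_len(H0), seq_len(W0), drop = FALSE]
  structure(list(prob = prob, label = label, query_masks = mask_prob,
                 class_logits = fw$class_logits$val, queries = fw$queries$val),
            class = "segmentation_result")
}
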