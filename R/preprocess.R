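#' 3x3 filter kernels
#'
#' `filter_kernel()` validates a 3x3 stencil given as 9 row-major weights
#' (`w[5]` is the centre). `laplacian_kernel()` is the 8-connected
#' edge-detection stencil (-1 ring around a +8 centre; weights sum to 0) and
#' `sharpening_kernel()` the contrast-sharpening stencil (-1 ring around a +9
#' centre; weights sum to 1) obtained by adding the identity to it.
#'
#' @param weights numeric vector of 9 weights, row-major over the 3x3
#'   neighbourhood.
#' @return A `filter_kernel` object (numeric 3x3 matrix).
#' @export
filter_kernel <- function(weights) {
  weights <- as.numeric(weights)
  if (length(weights) != 9L || !all(is.finite(weights)))
    stop("a 3x3 kernel needs exactly 9 finite weights", call. = FALSE)
  structure(matrix(weights, 3, 3, byrow = TRUE), class = c("filter_kernel", "matrix"))
}

#' @rdname filter_kernel
#' @export
laplacian_kernel <- function() filter_kernel(c(-1, -1, -1, -1, 8, -1, -1, -1, -1))

#' @rdname filter_kernel
#' @export
sharpening_kernel <- function() filter_kernel(c(-1, -1, -1, -1, 9, -1, -1, -1, -1))

#' Correlate an image with a 3x3 kernel (replicate-padded borders)
#'
#' @param image numeric matrix, at least 3x3.
#' @param kernel a [filter_kernel] or 3x3 matrix.
#' @return Matrix of the same size as `image`.
#' @export
convolve3x3 <- function(image, kernel) {
  if (!is.matrix(image) || nrow(image) < 3L || ncol(image) < 3L)
    stop("`image` must be a matrix of at least 3x3", call. = FALSE)
  k <- unclass(kernel)
  if (!identical(dim(k), c(3L, 3L))) stop("`kernel` must be 3x3", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  # replicate padding via clamped index vectors
  ri <- function(off) pmin(pmax(seq_len(h) + off, 1L), h)
  ci <- function(off) pmin(pmax(seq_len(w) + off, 1L), w)
  out <- matrix(0, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    out <- out + k[dr + 2L, dc + 2L] * image[ri(dr), ci(dc)]
  }
  out
}

#' Laplacian edge response and Laplacian-based sharpening
#'
#' `laplacian_filter()` returns the 8-connected discrete Laplacian
#' \eqn{\nabla^2 g} of a slice (sum of the 8 neighbours minus 8 times the
#' centre), which is zero on constant and affine images. `sharpen()` applies
#' the derived contrast-sharpening stencil \eqn{h(s,t) = 9\,\omega_5 -
#' \sum_{j \ne 5} \omega_j}, i.e. `image - laplacian_filter(image)`, which
#' boosts high-frequency content while preserving flat regions and linear
#' ramps. Borders use replicate padding.
#'
#' @inheritParams convolve3x3
#' @return Matrix of the same size as `image`.
#' @export
laplacian_filter <- function(image) {
  convolve3x3(image, matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3))
}

#' @rdname laplacian_filter
#' @export
sharpen <- function(image) {
  convolve3x3(image, unclass(sharpening_kernel()))
}

#' Percentile clipping specification
#'
#' @param lower_percentile,upper_percentile clip bounds in percent; HU values
#'   outside the corresponding percentile interval are clamped to it.
#' @param region `"volume"` computes percentiles over all voxels,
#'   `"foreground"` over the voxels of a label mask supplied to
#'   [clip_and_standardize()].
#' @return A `clip_spec` object.
#' @export
clip_spec <- function(lower_percentile = 0.55, upper_percentile = 99.4,
                      region = c("volume", "foreground")) {
  region <- match.arg(region)
  if (!(lower_percentile >= 0 && lower_percentile < upper_percentile &&
        upper_percentile <= 100))
    stop("need 0 <= lower < upper <= 100", call. = FALSE)
  structure(list(lower_percentile = lower_percentile,
                 upper_percentile = upper_percentile,
                 region = region),
            class = "clip_spec")
}

#' Percentile clipping and standardization
#'
#' Clamps intensities to the `[p_lower, p_upper]` percentile interval
#' (percentiles by linear interpolation between order statistics) and then
#' standardizes the clipped volume to zero mean and unit variance. A constant
#' volume cannot be standardized and is returned as all zeros with a warning.
#'
#' @param vol a [volume_image] or numeric array.
#' @param spec a [clip_spec].
#' @param mask optional binary mask; with `spec$region == "foreground"` the
#'   percentiles are estimated over `mask > 0` voxels only.
#' @return Same type as `vol`, clipped and standardized.
#' @export
clip_and_standardize <- function(vol, spec = clip_spec(), mask = NULL) {
  is_vi <- is_volume_image(vol)
  x <- if (is_vi) vol$voxels else vol
  ref <- x
  if (identical(spec$region, "foreground")) {
    if (is.null(mask)) stop("foreground clipping requires `mask`", call. = FALSE)
    if (!sum(mask > 0)) stop("foreground clipping with an empty mask", call. = FALSE)
    ref <- x[mask > 0]
  }
  if (length(unique(as.vector(ref))) < 2L || stats::sd(x) == 0) {
    warning("constant volume: standardization undefined, returning zeros")
    out <- array(0, dim(as.array(x)))
    dim(out) <- dim(x)
  } else {
    b <- stats::quantile(ref, c(spec$lower_percentile, spec$upper_percentile) / 100,
                         names = FALSE, type = 7)
    out <- pmin(pmax(x, b[1]), b[2])
    s <- stats::sd(out)
    if (s == 0) {
      warning("volume constant after clipping: returning zeros")
      out[] <- 0
    } else {
      out <- (out - mean(out)) / s
    }
  }
  if (is_vi) volume_image(out, vol$spacing, vol$orientation) else out
}

# cubic-spline interpolation of a sampled sequence onto new coordinates
# (natural cubic spline through the sample points; exact on linear data)
.interp_cubic <- function(y, xout) {
  n <- length(y)
  if (n == 1L) return(rep(y, length(xout)))
  xout <- pmin(pmax(xout, 0), n - 1)
  if (n < 4L) return(stats::approx(0:(n - 1), y, xout)$y)
  stats::spline(0:(n - 1), y, xout = xout, method = "natural")$y
}

.interp_nearest <- function(y, xout) {
  n <- length(y)
  idx <- pmin(pmax(round(xout) + 1, 1), n)
  y[idx]
}

# target grid coordinates (in source index units) for one axis
.resample_axis <- function(n, old, new) {
  m <- max(1L, as.integer(round(n * old / new)))
  list(m = m, coord = (seq_len(m) - 1) * new / old)
}

#' Resample a CT volume to a target voxel spacing
#'
#' In-plane (height/width) values are interpolated with cubic splines; the
#' depth axis uses nearest-neighbour interpolation, as appropriate for the
#' coarse slice direction of abdominal CT. Label masks (`is_mask = TRUE`) are
#' resampled with nearest-neighbour interpolation on all axes so labels stay
#' binary.
#'
#' @param vol a [volume_image].
#' @param target_spacing numeric length-3 target spacing in mm,
#'   `(slice thickness, pixel height, pixel width)`.
#' @param is_mask resample as a label volume (nearest neighbour everywhere).
#' @return A [volume_image] with spacing `target_spacing`.
#' @export
resample_volume <- function(vol, target_spacing, is_mask = FALSE) {
  stopifnot(is_volume_image(vol))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("`target_spacing` must be 3 positive values (mm)", call. = FALSE)
  x <- vol$voxels
  d <- dim(x)
  ax <- lapply(1:3, function(i) .resample_axis(d[i], vol$spacing[i], target_spacing[i]))
  interp_plane <- if (is_mask) .interp_nearest else .interp_cubic
  # depth: nearest neighbour always
  zsrc <- pmin(pmax(round(ax[[1]]$coord) + 1, 1), d[1])
  out <- array(0, c(ax[[1]]$m, ax[[2]]$m, ax[[3]]$m))
  for (z in seq_len(ax[[1]]$m)) {
    sl <- x[zsrc[z], , , drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, d[2], d[3])
    # separable interpolation: along width for each row, then along height
    tmp <- t(apply(sl, 1, interp_plane, xout = ax[[3]]$coord))
    if (ax[[3]]$m == 1L) tmp <- matrix(tmp, nrow = d[2])
    res <- apply(tmp, 2, interp_plane, xout = ax[[2]]$coord)
    out[z, , ] <- matrix(res, ax[[2]]$m, ax[[3]]$m)
  }
  volume_image(out, target_spacing, vol$orientation)
}

#' Augmentation specification
#'
#' Geometric training-time augmentation: rescaling, zooming, horizontal
#' flipping and shearing, applied as a single affine transform about the
#' image centre. The image is interpolated with a cubic kernel, the mask with
#' nearest neighbour, and all random draws are fully determined by `seed`.
#'
#' @param rescale,zoom length-2 multiplicative scale ranges (both are drawn
#'   and composed).
#' @param flip_prob probability of a horizontal flip.
#' @param shear length-2 shear-angle range in degrees.
#' @param seed integer RNG seed.
#' @return An `augment_spec` object.
#' @export
augment_spec <- function(rescale = c(0.9, 1.1), zoom = c(0.9, 1.1),
                         flip_prob = 0.5, shear = c(-5, 5), seed = 1L) {
  stopifnot(length(rescale) == 2L, rescale[1] <= rescale[2],
            length(zoom) == 2L, zoom[1] <= zoom[2],
            length(shear) == 2L, shear[1] <= shear[2],
            flip_prob >= 0, flip_prob <= 1)
  structure(list(rescale = rescale, zoom = zoom, flip_prob = flip_prob,
                 shear = shear, seed = as.integer(seed)),
            class = "augment_spec")
}

# Keys cubic-convolution kernel (a = -0.5); exact at integer offsets
.cubic_weight <- function(t) {
  t <- abs(t)
  ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

# sample `image` at (possibly fractional) row/col coordinate matrices
.sample_cubic <- function(image, rr, cc) {
  h <- nrow(image); w <- ncol(image)
  rr <- pmin(pmax(rr, 1), h); cc <- pmin(pmax(cc, 1), w)
  out <- matrix(0, nrow(rr), ncol(rr))
  r0 <- floor(rr); c0 <- floor(cc)
  for (dr in -1:2) for (dc in -1:2) {
    ri <- pmin(pmax(r0 + dr, 1), h)
    ci <- pmin(pmax(c0 + dc, 1), w)
    wgt <- .cubic_weight(rr - (r0 + dr)) * .cubic_weight(cc - (c0 + dc))
    out <- out + wgt * matrix(image[cbind(as.vector(ri), as.vector(ci))], nrow(rr))
  }
  out
}

.sample_nearest <- function(image, rr, cc) {
  h <- nrow(image); w <- ncol(image)
  ri <- pmin(pmax(round(rr), 1), h)
  ci <- pmin(pmax(round(cc), 1), w)
  matrix(image[cbind(as.vector(ri), as.vector(ci))], nrow(rr))
}

#' Apply a seeded geometric augmentation to an image/mask pair
#'
#' @param image numeric matrix (one 2-D slice).
#' @param mask congruent label matrix.
#' @param spec an [augment_spec].
#' @return List with fields `image` and `mask` after the identical transform.
#' @export
augment <- function(image, mask, spec = augment_spec()) {
  if (!identical(dim(image), dim(mask)))
    stop("`image` and `mask` must have identical shapes", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  s <- stats::runif(1, spec$rescale[1], spec$rescale[2]) *
    stats::runif(1, spec$zoom[1], spec$zoom[2])
  sh <- tan(stats::runif(1, spec$shear[1], spec$shear[2]) * pi / 180)
  flip <- stats::runif(1) < spec$flip_prob
  h <- nrow(image); w <- ncol(image)
  cr <- (h + 1) / 2; cw <- (w + 1) / 2
  # forward transform (about the centre): scale, shear in x, optional x flip;
  # sample by mapping output coordinates through its inverse
  fw <- matrix(c(s, 0, s * sh, s), 2, 2) # rows: (row', col') from (row, col)
  if (flip) fw[, 2] <- -fw[, 2]
  inv <- solve(fw)
  grid <- expand.grid(r = seq_len(h) - cr, c = seq_len(w) - cw)
  src <- cbind(grid$r, grid$c) %*% t(inv)
  rr <- matrix(src[, 1] + cr, h, w)
  cc <- matrix(src[, 2] + cw, h, w)
  list(image = .sample_cubic(image, rr, cc),
       mask = .sample_nearest(mask, rr, cc))
}

#' Gaussian importance weights for sliding-window fusion
#'
#' Separable Gaussian centred in a patch, scaled so the maximum weight is 1.
#' Patch outputs fused with these weights emphasise patch centres and
#' suppress the less reliable borders.
#'
#' @param patch_shape integer vector of patch side lengths (any rank).
#' @param sigma_scale Gaussian sigma as a fraction of each side length.
#' @return Array of strictly positive weights with `dim == patch_shape`.
#' @export
gaussian_patch_weights <- function(patch_shape, sigma_scale = 1 / 8) {
  patch_shape <- as.integer(patch_shape)
  if (any(patch_shape < 1L) || sigma_scale <= 0)
    stop("positive patch shape and sigma_scale required", call. = FALSE)
  axes <- lapply(patch_shape, function(n) {
    if (n == 1L) return(1)
    ctr <- (n + 1) / 2
    sigma <- sigma_scale * n
    exp(-0.5 * ((seq_len(n) - ctr) / sigma)^2)
  })
  w <- Reduce(function(a, b) outer(a, b), axes)
  w <- array(w, patch_shape)
  w / max(w)
}

# start offsets covering [1, n] with patches of size p and stride s
.window_starts <- function(n, p, s) {
  if (p >= n) return(1L)
  st <- seq(1L, n - p + 1L, by = s)
  if (st[length(st)] != n - p + 1L) st <- c(st, n - p + 1L)
  st
}

#' Sliding-window inference with Gaussian-weighted fusion
#'
#' Tiles a volume into overlapping patches (stride one half of the patch size
#' by default), applies `predictor` to every patch and fuses the overlapping
#' outputs as a weighted average with [gaussian_patch_weights()]; the
#' accumulated weight is divided out at every voxel, so constant predictions
#' are reproduced exactly. Volumes smaller than the patch are replicate-padded
#' and cropped back.
#'
#' @param vol a [volume_image] or rank-3 array.
#' @param predictor function mapping a patch (rank-3 array) to an equal-shape
#'   array of per-voxel values (e.g. probabilities).
#' @param patch_size integer length-3 patch shape `(depth, height, width)`.
#' @param stride integer length-3 stride; default `patch_size / 2`
#'   (semi-patch), minimum 1.
#' @param sigma_scale fusion Gaussian width, see [gaussian_patch_weights()].
#' @return Rank-3 array of fused predictions, same shape as the input.
#' @export
sliding_window_predict <- function(vol, predictor, patch_size,
                                   stride = NULL, sigma_scale = 1 / 8) {
  x <- if (is_volume_image(vol)) vol$voxels else vol
  stopifnot(is.array(x), length(dim(x)) == 3L)
  patch_size <- as.integer(patch_size)
  stopifnot(length(patch_size) == 3L, all(patch_size >= 1L))
  if (is.null(stride)) stride <- pmax(1L, patch_size %/% 2L)
  stride <- pmax(1L, as.integer(stride))
  d0 <- dim(x)
  # replicate-pad up to the patch size if needed
  pad <- pmax(0L, patch_size - d0)
  if (any(pad > 0L)) {
    idx <- lapply(1:3, function(i) pmin(seq_len(d0[i] + pad[i]), d0[i]))
    x <- x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  d <- dim(x)
  w <- gaussian_patch_weights(patch_size, sigma_scale)
  acc <- array(0, d); wsum <- array(0, d)
  for (z in .window_starts(d[1], patch_size[1], stride[1]))
    for (r in .window_starts(d[2], patch_size[2], stride[2]))
      for (cl in .window_starts(d[3], patch_size[3], stride[3])) {
        zi <- z:(z + patch_size[1] - 1L)
        ri <- r:(r + patch_size[2] - 1L)
        ci <- cl:(cl + patch_size[3] - 1L)
        p <- predictor(x[zi, ri, ci, drop = FALSE])
        if (!identical(dim(as.array(p)), patch_size))
          stop("predictor output shape does not match the patch", call. = FALSE)
        acc[zi, ri, ci] <- acc[zi, ri, ci] + as.vector(w * p)
        wsum[zi, ri, ci] <- wsum[zi, ri, ci] + as.vector(w)
      }
  out <- acc / wsum
  out[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
}

#' Standard CT conditioning pipeline
#'
#' Resamples to the target spacing, sharpens each axial slice with the
#' Laplacian-derived stencil, then clips and standardizes — the order used
#' before feeding slices to the segmentation model. Fat quantification must
#' use the raw HU volume, never this output.
#'
#' @inheritParams resample_volume
#' @param clip a [clip_spec].
#' @param do_sharpen apply [sharpen()] slice-wise.
#' @return A preprocessed [volume_image] (standardized intensities).
#' @export
preprocess_volume <- function(vol, target_spacing = c(3, 1, 1),
                              clip = clip_spec(), do_sharpen = TRUE) {
  out <- resample_volume(vol, target_spacing)
  if (do_sharpen) {
    for (z in seq_len(dim(out$voxels)[1]))
      out$voxels[z, , ] <- sharpen(out$voxels[z, , ])
  }
  clip_and_standardize(out, clip)
}
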