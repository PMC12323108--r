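#' Region-overlap segmentation metrics
#'
#' Dice, Jaccard, precision and recall between binary masks, in percent.
#' Two empty masks agree perfectly by convention (100); a single empty mask
#' yields 0. Dice and Jaccard obey `J = D / (2 - D)` (as fractions).
#'
#' @param pred,gt congruent binary masks (any shape).
#' @return Percentage in `[0, 100]`.
#' @export
dice <- function(pred, gt) {
  p <- pred > 0; g <- gt > 0
  if (!sum(p) && !sum(g)) return(100)
  100 * 2 * sum(p & g) / (sum(p) + sum(g))
}

#' @rdname dice
#' @export
jaccard <- function(pred, gt) {
  p <- pred > 0; g <- gt > 0
  if (!sum(p) && !sum(g)) return(100)
  100 * sum(p & g) / sum(p | g)
}

#' @rdname dice
#' @export
precision <- function(pred, gt) {
  p <- pred > 0; g <- gt > 0
  if (!sum(p) && !sum(g)) return(100)
  if (!sum(p)) return(0)
  100 * sum(p & g) / sum(p)
}

#' @rdname dice
#' @export
recall <- function(pred, gt) {
  p <- pred > 0; g <- gt > 0
  if (!sum(p) && !sum(g)) return(100)
  if (!sum(g)) return(0)
  100 * sum(p & g) / sum(g)
}

# surface voxels: mask voxels with at least one face-adjacent background
# neighbour (the array border counts as background)
mask_surface <- function(mask) {
  m <- as.array(mask) > 0
  d <- dim(m)
  r <- length(d)
  interior <- array(TRUE, d)
  for (ax in seq_len(r)) {
    n <- d[ax]
    lo <- hi <- m
    idx <- lapply(d, seq_len)
    # neighbour along -ax: shift; border treated as background (FALSE)
    sel_lo <- idx; sel_lo[[ax]] <- c(1L, seq_len(n - 1L))
    lo <- do.call(`[`, c(list(m), sel_lo))
    dim(lo) <- d
    edge <- idx; edge[[ax]] <- 1L
    eg <- array(FALSE, d); eg <- do.call(`[<-`, c(list(eg), edge, list(TRUE)))
    lo[eg] <- FALSE
    sel_hi <- idx; sel_hi[[ax]] <- c(seq_len(n - 1L) + 1L, n)
    hi <- do.call(`[`, c(list(m), sel_hi))
    dim(hi) <- d
    eg <- array(FALSE, d)
    edge[[ax]] <- n
    eg <- do.call(`[<-`, c(list(eg), edge, list(TRUE)))
    hi[eg] <- FALSE
    interior <- interior & lo & hi
  }
  m & !interior
}

# physical (mm) coordinates of TRUE voxels
.surface_coords <- function(surf, spacing) {
  w <- which(surf, arr.ind = TRUE)
  if (is.vector(w)) w <- matrix(w, ncol = 1L)
  sweep(w, 2L, spacing, "*")
}

# for each row of a: distance to the nearest row of b (chunked brute force;
# per-axis differences, no a^2+b^2-2ab cancellation)
.nearest_dists <- function(a, b, chunk = 1024L) {
  n <- nrow(a)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    ac <- a[s:e, , drop = FALSE]
    d2 <- 0
    for (k in seq_len(ncol(a)))
      d2 <- d2 + outer(ac[, k], b[, k], "-")^2
    out[s:e] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Symmetric surface distances (HD95 and ASSD)
#'
#' Extracts the boundary voxels of both masks (face-adjacency surface
#' definition), computes spacing-scaled Euclidean nearest-surface distances
#' in both directions, pools them, and reports the 95th percentile (HD95,
#' linear-interpolation percentile), their mean (ASSD) and the maximum
#' (`hd_max`). If either mask is empty the distances are undefined: `Inf`
#' with `empty = TRUE`, never a silent 0.
#'
#' @param pred,gt congruent binary masks.
#' @param spacing voxel spacing in mm (one value per array axis).
#' @return List with `hd95`, `assd`, `hd_max`, `empty`.
#' @export
surface_distances <- function(pred, gt, spacing = NULL) {
  p <- as.array(pred); g <- as.array(gt)
  if (!identical(dim(p), dim(g)))
    stop("masks must be congruent", call. = FALSE)
  r <- length(dim(p))
  if (is.null(spacing)) spacing <- rep(1, r)
  stopifnot(length(spacing) == r, all(spacing > 0))
  if (!sum(p > 0) || !sum(g > 0)) {
    warning("empty mask: surface distances undefined")
    return(list(hd95 = Inf, assd = Inf, hd_max = Inf, empty = TRUE))
  }
  ca <- .surface_coords(mask_surface(p), spacing)
  cb <- .surface_coords(mask_surface(g), spacing)
  pooled <- c(.nearest_dists(ca, cb), .nearest_dists(cb, ca))
  list(hd95 = stats::quantile(pooled, 0.95, names = FALSE, type = 7),
       assd = mean(pooled), hd_max = max(pooled), empty = FALSE)
}

#' Relative volume prediction error
#'
#' `E_v = (V_predicted - V_real) / V_real` (signed fraction).
#'
#' @param v_pred,v_real predicted and true volumes (ml), `v_real > 0`.
#' @return Signed relative error.
#' @export
relative_volume_error <- function(v_pred, v_real) {
  if (!is.finite(v_real) || v_real <= 0)
    stop("`v_real` must be positive", call. = FALSE)
  (v_pred - v_real) / v_real
}

#' Full metric report for one volume
#'
#' @param pred,gt congruent binary masks.
#' @param spacing voxel spacing in mm.
#' @param id optional case identifier.
#' @return A one-row tibble with dice/jaccard/precision/recall (%), hd95 and
#'   assd (mm), and the relative volume error.
#' @export
evaluate_segmentation <- function(pred, gt, spacing = NULL, id = NA_character_) {
  sd_ <- if (sum(pred > 0) && sum(gt > 0)) {
    surface_distances(pred, gt, spacing)
  } else list(hd95 = Inf, assd = Inf, empty = TRUE)
  vr <- if (sum(gt > 0)) relative_volume_error(sum(pred > 0), sum(gt > 0)) else NA_real_
  tibble::tibble(
    id = id,
    dice = dice(pred, gt), jaccard = jaccard(pred, gt),
    precision = precision(pred, gt), recall = recall(pred, gt),
    hd95 = sd_$hd95, assd = sd_$assd,
    volume_error = vr
  )
}

#' Aggregate per-case metric rows into mean and standard deviation
#'
#' @param reports tibble of rows from [evaluate_segmentation()].
#' @return Tibble with one row per metric: mean and sd.
#' @export
aggregate_metrics <- function(reports) {
  num <- reports[vapply(reports, is.numeric, logical(1))]
  tibble::tibble(
    metric = names(num),
    mean = unname(vapply(num, function(x) mean(x[is.finite(x)]), numeric(1))),
    sd = unname(vapply(num, function(x) stats::sd(x[is.finite(x)]), numeric(1)))
  )
}
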