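# Seeded CT-like phantoms: an ellipsoidal "pancreas" of parenchymal HU with
# injected sub-threshold fat voxels at a controlled fraction, embedded in a
# noisy abdominal background with air and bone distractors. The ground truth
# (mask, volume, fat fraction) is known by construction, which makes the
# phantoms the test bed for segmentation, thresholding and volume code.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Phantom specification
#'
#' Describes one synthetic abdominal CT phantom. HU regimes follow typical
#' tissue attenuation: pancreatic parenchyma around 40 +/- 10 HU, fat around
#' -60 +/- 15 HU (well below the -20 HU fat threshold, so threshold recovery
#' is testable with an explicit Gaussian-tail margin), soft-tissue background
#' in 0..100 HU, air pockets near -1000 HU and bone distractors above
#' 400 HU.
#'
#' @param shape volume shape `(depth, height, width)` in voxels.
#' @param spacing voxel spacing `(slice, row, column)` in mm.
#' @param center ellipsoid centre in voxel coordinates (default: volume
#'   centre).
#' @param semi_axes_mm ellipsoid semi-axes in mm, `(depth, height, width)`.
#' @param rotation_deg in-plane rotation of the ellipsoid, degrees.
#' @param parenchyma_hu,parenchyma_sd mean/sd of parenchymal HU.
#' @param fat_hu,fat_sd mean/sd of injected fat-voxel HU.
#' @param fat_fraction target fat fraction of in-mask voxels, in `[0, 1]`.
#' @param noise_sd global additive Gaussian noise sd (HU).
#' @param n_air,n_bone number of air-pocket / bone distractor spheres.
#' @param seed RNG seed; the generated phantom is a pure function of the
#'   spec including this seed.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(24L, 64L, 64L), spacing = c(3, 1, 1),
                         center = NULL, semi_axes_mm = c(15, 20, 12),
                         rotation_deg = 20,
                         parenchyma_hu = 40, parenchyma_sd = 10,
                         fat_hu = -60, fat_sd = 15,
                         fat_fraction = 0.1, noise_sd = 5,
                         n_air = 2L, n_bone = 2L, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            fat_fraction >= 0, fat_fraction <= 1,
            all(semi_axes_mm > 0), noise_sd >= 0)
  if (is.null(center)) center <- (shape + 1) / 2
  # the ellipsoid must fit inside the volume
  half_extent_mm <- shape * spacing / 2
  if (any(semi_axes_mm > half_extent_mm))
    stop("ellipsoid semi-axes exceed the volume extent", call. = FALSE)
  structure(list(
    shape = shape, spacing = spacing, center = center,
    semi_axes_mm = semi_axes_mm, rotation_deg = rotation_deg,
    parenchyma_hu = parenchyma_hu, parenchyma_sd = parenchyma_sd,
    fat_hu = fat_hu, fat_sd = fat_sd, fat_fraction = fat_fraction,
    noise_sd = noise_sd, n_air = as.integer(n_air), n_bone = as.integer(n_bone),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# binary sphere helper on the voxel grid (radius in mm)
.sphere_mask <- function(shape, spacing, center, radius_mm) {
  z <- (seq_len(shape[1]) - center[1]) * spacing[1]
  y <- (seq_len(shape[2]) - center[2]) * spacing[2]
  x <- (seq_len(shape[3]) - center[3]) * spacing[3]
  d2 <- outer(outer(z^2, y^2, "+"), x^2, "+")
  d2 <= radius_mm^2
}

#' Generate a CT phantom with known pancreas mask and fat fraction
#'
#' Voxelizes the spec's ellipsoid on the grid, assigns parenchymal HU to the
#' mask, replaces exactly `round(fat_fraction * M)` seeded-random in-mask
#' voxels with fat-distribution HU, builds the noisy background with air and
#' bone distractors, and adds global noise. The returned truth is computed
#' from the realized mask (voxel count times voxel volume) and the exact
#' injected fat-voxel count.
#'
#' @param spec a [phantom_spec].
#' @return List with `ct` (a [volume_image] in raw HU), `mask` (binary
#'   array) and `truth` (list: `volume_ml`, `fat_fraction`,
#'   `fat_voxel_count`, `pancreas_voxels`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    sh <- spec$shape; sp <- spec$spacing
    # rotated ellipsoid in physical coordinates
    th <- spec$rotation_deg * pi / 180
    z <- (seq_len(sh[1]) - spec$center[1]) * sp[1]
    y <- (seq_len(sh[2]) - spec$center[2]) * sp[2]
    x <- (seq_len(sh[3]) - spec$center[3]) * sp[3]
    g <- expand.grid(z = z, y = y, x = x)
    yr <- cos(th) * g$y - sin(th) * g$x
    xr <- sin(th) * g$y + cos(th) * g$x
    inside <- (g$z / spec$semi_axes_mm[1])^2 + (yr / spec$semi_axes_mm[2])^2 +
      (xr / spec$semi_axes_mm[3])^2 <= 1
    mask <- array(as.numeric(inside), sh)
    M <- sum(mask > 0)
    if (M == 0) stop("degenerate spec: empty ellipsoid", call. = FALSE)
    # background: soft tissue with distractors
    ct <- array(stats::rnorm(prod(sh), mean = 50, sd = 20), sh)
    ct <- pmin(pmax(ct, 0), 100)
    for (i in seq_len(spec$n_air)) {
      c_ <- c(stats::runif(1, 1, sh[1]), stats::runif(1, 1, sh[2]),
              stats::runif(1, 1, sh[3]))
      ct[.sphere_mask(sh, sp, c_, stats::runif(1, 3, 8))] <- -1000
    }
    for (i in seq_len(spec$n_bone)) {
      c_ <- c(stats::runif(1, 1, sh[1]), stats::runif(1, 1, sh[2]),
              stats::runif(1, 1, sh[3]))
      ct[.sphere_mask(sh, sp, c_, stats::runif(1, 2, 6))] <-
        stats::runif(1, 400, 1000)
    }
    # pancreas parenchyma, then exact fat injection
    idx <- which(mask > 0)
    ct[idx] <- stats::rnorm(M, spec$parenchyma_hu, spec$parenchyma_sd)
    n_fat <- round(spec$fat_fraction * M)
    fat_idx <- if (n_fat > 0) sample(idx, n_fat) else integer(0)
    if (n_fat > 0) ct[fat_idx] <- stats::rnorm(n_fat, spec$fat_hu, spec$fat_sd)
    if (spec$noise_sd > 0) ct <- ct + stats::rnorm(prod(sh), 0, spec$noise_sd)
    list(
      ct = volume_image(ct, sp),
      mask = mask,
      truth = list(
        volume_ml = M * prod(sp) / 1000,
        fat_fraction = n_fat / M,
        fat_voxel_count = as.integer(n_fat),
        pancreas_voxels = as.integer(M)
      )
    )
  })
}

#' Toy 2-D training set
#'
#' Seeded set of small 2-D slices, each with one elliptical foreground blob
#' of higher, HU-like intensity on a noisy background, with its binary mask.
#' Intended for fast CPU training and overfitting checks.
#'
#' @param n number of slices.
#' @param size slice side length in pixels.
#' @param seed RNG seed.
#' @param fg_hu,bg_hu foreground/background mean intensity.
#' @param noise_sd additive noise sd.
#' @return List of `n` elements, each a list with `image` and `mask`
#'   matrices.
#' @export
make_toy2d_dataset <- function(n, size = 32L, seed = 1L,
                               fg_hu = 60, bg_hu = 0, noise_sd = 8) {
  stopifnot(n >= 1L, size >= 16L)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- stats::runif(1, size / 6, size / 3.5)
      b <- stats::runif(1, size / 6, size / 3.5)
      cx <- stats::runif(1, size / 3, 2 * size / 3)
      cy <- stats::runif(1, size / 3, 2 * size / 3)
      th <- stats::runif(1, 0, pi)
      r <- matrix(seq_len(size), size, size)
      c_ <- t(r)
      xr <- cos(th) * (r - cy) + sin(th) * (c_ - cx)
      yr <- -sin(th) * (r - cy) + cos(th) * (c_ - cx)
      mask <- ((xr / a)^2 + (yr / b)^2 <= 1) * 1
      img <- matrix(stats::rnorm(size^2, bg_hu, noise_sd), size, size)
      img[mask > 0] <- stats::rnorm(sum(mask > 0), fg_hu, noise_sd)
      list(image = img, mask = mask)
    })
  })
}

#' Write a small fixed benchmark fixture set
#'
#' Two 24 x 64 x 64 phantoms at fat fractions 0.05 and 0.20 plus one toy
#' training set of 8 slices, written as NIfTI volumes with a JSON truth file
#' per case.
#'
#' @param dir output directory (created if missing).
#' @param seed RNG seed.
#' @return Invisibly, the list of per-case truth records.
#' @export
make_benchmark_suite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fractions <- c(0.05, 0.20)
  truths <- list()
  for (i in seq_along(fractions)) {
    ph <- make_phantom(phantom_spec(fat_fraction = fractions[i],
                                    seed = seed + i - 1L))
    case <- file.path(dir, sprintf("phantom_%02d", i))
    dir.create(case, showWarnings = FALSE)
    write_nifti_volume(ph$ct, file.path(case, "ct.nii.gz"))
    write_nifti_volume(ph$mask, file.path(case, "mask.nii.gz"),
                       spacing = ph$ct$spacing)
    jsonlite::write_json(ph$truth, file.path(case, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    truths[[i]] <- ph$truth
  }
  toy <- make_toy2d_dataset(8L, seed = seed + 100L)
  toy_dir <- file.path(dir, "toy2d")
  dir.create(toy_dir, showWarnings = FALSE)
  for (i in seq_along(toy)) {
    write_nifti_volume(array(toy[[i]]$image, c(1L, dim(toy[[i]]$image))),
                       file.path(toy_dir, sprintf("slice_%02d.nii.gz", i)))
    write_nifti_volume(array(toy[[i]]$mask, c(1L, dim(toy[[i]]$mask))),
                       file.path(toy_dir, sprintf("mask_%02d.nii.gz", i)))
  }
  invisible(truths)
}
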