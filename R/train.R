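# Training: Adam on the Hungarian-matched mask-classification objective.
# Each batch builds one autodiff tape over all its slices, so parameter
# gradients accumulate across the batch before the update.

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(flat)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    flat[[k]] <- flat[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

rebuild_params <- function(template, flat) {
  out <- template
  for (k in names(flat)) {
    path <- strsplit(k, ".", fixed = TRUE)[[1]]
    out <- .assign_path(out, path, flat[[k]])
  }
  out
}

.assign_path <- function(node, path, value) {
  key <- path[1]
  if (is.null(names(node)) || grepl("^[0-9]+$", key)) key <- as.integer(key)
  if (length(path) == 1L) { node[[key]] <- value; return(node) }
  node[[key]] <- .assign_path(node[[key]], path[-1], value)
  node
}

# semantic ground-truth instances for one slice: one mask per present class
slice_instances <- function(mask) {
  m <- as.numeric(mask > 0)
  inst <- list(list(mask = 1 - m, class = 1)) # background
  if (sum(m) > 0) inst <- c(inst, list(list(mask = m, class = 2)))
  inst
}

# tape loss for one slice given a forward result
nn_slice_loss <- function(tape, fw, instances, cfg, loss_cfg) {
  mask_prob <- 1 / (1 + exp(-fw$mask_logits$val))
  mt <- hungarian_match(mask_prob, fw$class_logits$val, instances, loss_cfg)
  X <- nrow(mask_prob)
  npairs <- nrow(mt$pairs)
  l_mask <- ad_const(tape, matrix(0, 1, 1))
  if (npairs > 0) {
    for (k in seq_len(npairs)) {
      tgt <- instances[[mt$pairs[k, "target"]]]
      row <- ad_gather_rows(tape, fw$mask_logits, mt$pairs[k, "query"])
      gt <- matrix(tgt$mask, 1L)
      l_mask <- ad_add(tape, l_mask,
                       ad_add(tape, ad_bce_logits(tape, row, gt),
                              ad_dice_logits(tape, row, gt)))
    }
    l_mask <- ad_mul(tape, l_mask, 1 / npairs)
  }
  target <- rep(ncol(fw$class_logits$val), X)
  weights <- rep(loss_cfg$no_object_weight, X)
  if (npairs > 0) {
    target[mt$pairs[, "query"]] <-
      vapply(mt$pairs[, "target"], function(g) instances[[g]]$class, numeric(1))
    weights[mt$pairs[, "query"]] <- 1
  }
  l_clas <- ad_softmax_xent(tape, fw$class_logits, target, weights)
  ad_add(tape, ad_mul(tape, l_mask, loss_cfg$alpha),
         ad_mul(tape, l_clas, loss_cfg$beta))
}

#' Train a segmentation model
#'
#' Optimizes the Hungarian-matched mask-classification objective
#' `L = alpha (L_ce + L_dice) + beta L_clas` with Adam over 2-D slices.
#' Slices are conditioned with [condition_slice()] (sharpening, percentile
#' clip, zero mean/unit variance) before entering the network; optional
#' seeded geometric augmentation can be applied per epoch. Training is deterministic for a fixed seed on CPU.
#'
#' @param model a `pancseg_model` from [init_model()].
#' @param dataset list of slices, each a list with `image` and `mask`
#'   matrices (e.g. from [make_toy2d_dataset()]).
#' @param epochs maximum epochs.
#' @param lr Adam learning rate.
#' @param batch_size slices per parameter update.
#' @param loss_cfg a [loss_config].
#' @param augmentation optional [augment_spec]; `NULL` disables augmentation.
#' @param seed RNG seed controlling data order (and augmentation offsets).
#' @param eval_every compute training Dice every this many epochs.
#' @param early_stop_dice stop when training Dice reaches this value
#'   (fraction); `NULL` disables early stopping.
#' @param val_data optional held-out slices evaluated at `eval_every`.
#' @param abort_below_dice abandon the run (returning with field
#'   `aborted = TRUE`) if training Dice is still below this value at the
#'   first evaluation at or after `abort_after` epochs — used for cheap
#'   seeded restarts around poor optimization basins; `NULL` disables.
#' @param abort_after epoch from which `abort_below_dice` applies.
#' @param sharpen_slices condition slices with [condition_slice()] (sharpen
#'   + standardize); disable to standardize only.
#' @param verbose print per-epoch progress.
#' @return The trained model with a `history` tibble (epoch, loss,
#'   train_dice, val_dice) attached.
#' @export
train_model <- function(model, dataset, epochs = 200L, lr = 1e-3,
                        batch_size = 2L, loss_cfg = loss_config(),
                        augmentation = NULL, seed = 1L, eval_every = 5L,
                        early_stop_dice = 0.995, val_data = NULL,
                        abort_below_dice = NULL, abort_after = 40L,
                        sharpen_slices = TRUE, verbose = FALSE) {
  cfg <- model$config
  norm <- fit_slice_norm(dataset, sharpen_slices)
  model$norm <- norm
  prep <- lapply(dataset, function(d) {
    list(image = condition_slice(d$image, norm),
         mask = (d$mask > 0) * 1)
  })
  flat <- flatten_params(model$params)
  state <- adam_init(flat)
  history <- list()
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(seq_along(prep))
      data_ep <- prep[ord]
      if (!is.null(augmentation)) {
        data_ep <- lapply(seq_along(data_ep), function(i) {
          sp <- augmentation
          sp$seed <- augmentation$seed + ep * 1000L + i
          a <- augment(dataset[[ord[i]]]$image, dataset[[ord[i]]]$mask, sp)
          list(image = condition_slice(a$image, norm),
               mask = (a$mask > 0) * 1)
        })
      }
      ep_loss <- 0
      nb <- 0L
      for (s in seq(1L, length(data_ep), by = batch_size)) {
        batch <- data_ep[s:min(s + batch_size - 1L, length(data_ep))]
        params <- rebuild_params(model$params, flat)
        tape <- ad_tape(grad = TRUE)
        pw <- wrap_params(tape, params)
        loss <- ad_const(tape, matrix(0, 1, 1))
        for (b in batch) {
          fw <- nn_forward(tape, pw, b$image, cfg)
          loss <- ad_add(tape, loss,
                         nn_slice_loss(tape, fw, slice_instances(b$mask),
                                       cfg, loss_cfg))
        }
        loss <- ad_mul(tape, loss, 1 / length(batch))
        ad_backward(tape, loss)
        grads <- flatten_params(collect_grads(name_like(pw, params)))
        upd <- adam_step(flat, grads, state, lr)
        flat <- upd$flat; state <- upd$state
        ep_loss <- ep_loss + loss$val[1]
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      tr_dice <- va_dice <- NA_real_
      if (ep %% eval_every == 0L || ep == epochs) {
        model$params <- rebuild_params(model$params, flat)
        tr_dice <- mean(vapply(prep, function(d) {
          r <- segment_slice(model, d$image)
          dice(r$label, d$mask) / 100
        }, numeric(1)))
        if (!is.null(val_data)) {
          va_dice <- mean(vapply(val_data, function(d) {
            r <- segment_slice(model, condition_slice(d$image, norm))
            dice(r$label, d$mask) / 100
          }, numeric(1)))
        }
      }
      history[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss,
                                      train_dice = tr_dice, val_dice = va_dice)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  dice %s", ep, ep_loss,
                        ifelse(is.na(tr_dice), "-", sprintf("%.3f", tr_dice))))
      if (!is.null(early_stop_dice) && !is.na(tr_dice) &&
          tr_dice >= early_stop_dice) break
      if (!is.null(abort_below_dice) && !is.na(tr_dice) &&
          ep >= abort_after && tr_dice < abort_below_dice) {
        model$aborted <- TRUE
        break
      }
    }
  })
  model$params <- rebuild_params(model$params, flat)
  model$history <- do.call(rbind, history)
  model
}

standardize_slice <- function(image) {
  v <- clip_and_standardize(array(image, c(1L, dim(image))), clip_spec())
  matrix(v[1, , ], dim(image)[1], dim(image)[2])
}

#' Condition one slice for the network
#'
#' The per-slice arm of the preprocessing pipeline: Laplacian-based
#' sharpening, clipping to the percentile interval of the labelled-organ HU
#' range, and standardization. When `norm` (the normalization constants a
#' trained model carries, see [train_model()]) is supplied, its clip bounds
#' and moments are applied, so inference slices are conditioned exactly as
#' the training slices were; without it the slice is clipped/standardized on
#' its own statistics. Training and sliding-window inference both route
#' slices through this function.
#'
#' @param image numeric matrix (one raw-HU slice).
#' @param norm normalization constants (`lo`, `hi`, `mean`, `sd`,
#'   `sharpen`), usually `model$norm` of a trained model.
#' @param do_sharpen apply [sharpen()] first (ignored when `norm` is given,
#'   which records its own choice).
#' @return Conditioned slice matrix.
#' @export
condition_slice <- function(image, norm = NULL, do_sharpen = TRUE) {
  if (!is.null(norm)) {
    if (isTRUE(norm$sharpen)) image <- sharpen(image)
    x <- pmin(pmax(image, norm$lo), norm$hi)
    return((x - norm$mean) / norm$sd)
  }
  if (do_sharpen) image <- sharpen(image)
  standardize_slice(image)
}

# dataset-level normalization constants: clip bounds from the percentile
# interval of the labelled-organ (foreground) HU values across the training
# slices, moments from the clipped slices
fit_slice_norm <- function(dataset, sharpen_slices = TRUE,
                           clip = clip_spec()) {
  sharp <- lapply(dataset, function(d)
    if (sharpen_slices) sharpen(d$image) else d$image)
  fg <- unlist(mapply(function(s, d) s[d$mask > 0], sharp, dataset,
                      SIMPLIFY = FALSE))
  if (!length(fg)) stop("cannot fit normalization: no labelled voxels",
                        call. = FALSE)
  b <- stats::quantile(fg, c(clip$lower_percentile, clip$upper_percentile) / 100,
                       names = FALSE, type = 7)
  clipped <- unlist(lapply(sharp, function(s) pmin(pmax(s, b[1]), b[2])))
  sdv <- stats::sd(clipped)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  list(lo = b[1], hi = b[2], mean = mean(clipped), sd = sdv,
       sharpen = isTRUE(sharpen_slices))
}

#' @export
glance.pancseg_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_params = sum(vapply(flatten_params(x$params), length, numeric(1))),
    epochs = if (is.null(h)) 0L else max(h$epoch),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    final_train_dice = if (is.null(h)) NA_real_ else {
      td <- h$train_dice[!is.na(h$train_dice)]
      if (length(td)) td[length(td)] else NA_real_
    }
  )
}

#' Plot the training history of a model
#'
#' @param object a trained `pancseg_model`.
#' @param ... unused.
#' @return ggplot with loss and training-Dice curves over epochs.
#' @export
autoplot.pancseg_model <- function(object, ...) {
  h <- object$history
  if (is.null(h)) stop("model has no training history", call. = FALSE)
  df <- tibble::tibble(
    epoch = c(h$epoch, h$epoch),
    value = c(h$loss, h$train_dice),
    series = rep(c("loss", "train Dice"), each = nrow(h))
  )
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding the weights and the
#' embedded model configuration.
#'
#' @param model a `pancseg_model`.
#' @param path checkpoint file path.
#' @return `load_checkpoint()` returns the restored `pancseg_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params,
               history = model$history, norm = model$norm), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config[setdiff(names(ck$config), character(0))])
  m <- structure(list(config = cfg, params = ck$params), class = "pancseg_model")
  m$history <- ck$history
  m$norm <- ck$norm
  m
}

#' Segment a CT volume with sliding-window inference
#'
#' Runs the model on overlapping 2-D patches of a raw-HU volume (optionally
#' resampled first). Every patch slice is conditioned with
#' [condition_slice()] — exactly the transform seen in training — and the
#' overlapping outputs are fused with Gaussian weights
#' ([sliding_window_predict()], stride one half patch); the fused pancreas
#' probability is binarized at 0.5.
#'
#' @param model a trained `pancseg_model`.
#' @param vol a [volume_image] in raw HU.
#' @param patch in-plane patch side length (pixels).
#' @param target_spacing optional spacing to resample to before inference.
#' @param threshold probability cutoff for the output mask.
#' @return List with `prob` (fused probability array), `mask` (binary
#'   array) and `spacing`.
#' @export
predict_volume <- function(model, vol, patch = 32L, target_spacing = NULL,
                           threshold = 0.5, sharpen_slices = TRUE) {
  stopifnot(is_volume_image(vol))
  work <- if (!is.null(target_spacing)) resample_volume(vol, target_spacing) else vol
  predictor <- function(p) {
    sl <- matrix(p[1, , ], dim(p)[2], dim(p)[3])
    r <- segment_slice(model, condition_slice(sl, norm = model$norm,
                                              do_sharpen = sharpen_slices))
    array(r$prob, dim(p))
  }
  d <- dim(work$voxels)
  prob <- sliding_window_predict(work$voxels, predictor,
                                 patch_size = c(1L, min(patch, d[2]), min(patch, d[3])))
  list(prob = prob, mask = (prob >= threshold) * 1, spacing = work$spacing)
}
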