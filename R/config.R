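#' Run configuration
#'
#' Bundles the training hyperparameters (batch size 2, crop 40 x 224 x 224,
#' learning rate 3e-4, Adam, loss weights alpha 0.7 / beta 0.3 by default)
#' with a [model_config], seed and epoch budget. `read_run_config()` loads a
#' YAML file with the same field names; missing fields keep their defaults.
#'
#' @param batch_size slices per optimizer step.
#' @param crop patch/crop size `(depth, height, width)` used at the data
#'   layer; the 2-D network consumes the in-plane crop slice-wise.
#' @param lr learning rate.
#' @param optimizer optimizer name (only `"adam"` is implemented).
#' @param alpha,beta loss weights, see [loss_config()].
#' @param no_object_weight see [loss_config()].
#' @param epochs training epochs.
#' @param seed global RNG seed.
#' @param model a [model_config] (or a list of its fields in YAML).
#' @return A `run_config` object.
#' @export
run_config <- function(batch_size = 2L, crop = c(40L, 224L, 224L),
                       lr = 3e-4, optimizer = "adam",
                       alpha = 0.7, beta = 0.3, no_object_weight = 0.1,
                       epochs = 200L, seed = 1L, model = model_config()) {
  stopifnot(batch_size >= 1L, all(crop >= 1L), lr > 0, epochs >= 1L)
  if (!identical(tolower(optimizer), "adam"))
    stop("only the Adam optimizer is implemented", call. = FALSE)
  if (is.list(model) && !inherits(model, "model_config"))
    model <- do.call(model_config, model)
  structure(list(batch_size = as.integer(batch_size), crop = as.integer(crop),
                 lr = lr, optimizer = "adam", alpha = alpha, beta = beta,
                 no_object_weight = no_object_weight,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 model = model),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(run_config, y)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$model <- unclass(y$model)
  yaml::write_yaml(y, path)
  invisible(path)
}
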