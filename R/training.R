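# Mini-batch momentum-SGD training of a single branch.

#' Training configuration
#'
#' Defaults follow the published recipe: mini-batch SGD with batch size 10,
#' initial learning rate 4e-4 decaying exponentially (factor
#' `lr_decay_factor`, default 0.1, the factor itself being a package choice)
#' every 10000 iterations, momentum 0.9, weight decay 0.009, 40000
#' iterations.  Desk-scale runs override `iterations` (see
#' [desk_train_config()]).
#'
#' @param batch_size samples per SGD step.
#' @param initial_lr initial learning rate.
#' @param momentum momentum coefficient.
#' @param weight_decay L2 penalty applied to convolution / FC / SE weights
#'   (not to BN scale-shift or biases).
#' @param iterations number of SGD steps.
#' @param lr_decay_every decay period in iterations.
#' @param lr_decay_factor multiplicative decay per period.
#' @param seed RNG seed for batch sampling.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 10L, initial_lr = 4e-4,
                         momentum = 0.9, weight_decay = 0.009,
                         iterations = 40000L, lr_decay_every = 10000L,
                         lr_decay_factor = 0.1, seed = 1L) {
  stopifnot(batch_size >= 1, initial_lr >= 0, momentum >= 0, momentum < 1,
            weight_decay >= 0, iterations >= 1, lr_decay_every >= 1,
            lr_decay_factor > 0)
  structure(list(batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, momentum = momentum,
                 weight_decay = weight_decay,
                 iterations = as.integer(iterations),
                 lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' The configuration used by the stochastic desk tests: batch 10 and (by
#' default) 1000 iterations on toy-width models.  Pass a smaller
#' `iterations` to trade accuracy for runtime.
#'
#' @param iterations SGD steps (default 1000).
#' @param initial_lr learning rate (default 0.005; the full-scale 4e-4 is
#'   too slow for a few hundred iterations from scratch).
#' @param weight_decay L2 penalty (default 1e-4 at desk scale).
#' @param ... forwarded to [train_config()].
#' @export
desk_train_config <- function(iterations = 1000L, initial_lr = 0.005,
                              weight_decay = 1e-4, ...) {
  train_config(iterations = iterations, initial_lr = initial_lr,
               weight_decay = weight_decay, lr_decay_every = 400L,
               lr_decay_factor = 0.5, ...)
}

#' Save / load a training configuration as YAML
#'
#' @param cfg a [train_config()].
#' @param path YAML file path.
#' @export
save_train_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "train_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname save_train_config
#' @export
load_train_config <- function(path) {
  do.call(train_config, yaml::read_yaml(path))
}

.is_decayed <- function(name) {
  # weight decay applies to multiplicative weights only
  grepl("\\.W[12]?$", name)
}

#' Train one branch with momentum SGD
#'
#' Cross-entropy training of a single branch.  `data$x` holds the input
#' tensor (`(H, W, N, 3)` or a list of images) and `data$y` 1-based integer
#' class labels.  Batches are drawn uniformly with replacement when the
#' dataset is smaller than the batch size, without replacement otherwise.
#' Training aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model a `sep_model`.
#' @param data list with elements `x` and `y`.
#' @param cfg a [train_config()].
#' @return list with the trained `model` and the per-iteration `loss_trace`.
#' @export
train_branch <- function(model, data, cfg = desk_train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  x <- as_batch(data$x)
  y <- as.integer(data$y)
  n <- dim(x)[3]
  if (n < 1) stop("empty training manifest")
  if (length(y) != n) stop("labels and samples disagree in length")
  set.seed(cfg$seed)
  params <- model$params
  vel <- lapply(params, function(p) p * 0)
  decayed <- .is_decayed(names(params))
  loss_trace <- numeric(cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    lr <- cfg$initial_lr *
      cfg$lr_decay_factor^((it - 1) %/% cfg$lr_decay_every)
    idx <- if (n >= cfg$batch_size) sample.int(n, cfg$batch_size)
           else sample.int(n, cfg$batch_size, replace = TRUE)
    xb <- x[, , idx, , drop = FALSE]
    yb <- y[idx]
    model$params <- params
    fw <- forward_graph(model, xb, train = TRUE, want_cache = TRUE)
    model$state <- fw$state
    l <- ce_loss(fw$out, yb)
    if (!is.finite(l$loss))
      stop("training diverged: non-finite loss at iteration ", it)
    loss_trace[it] <- l$loss
    grads <- backward_graph(model, fw, l$dlogits)
    for (nm in names(grads)) {
      g <- grads[[nm]]
      if (decayed[[match(nm, names(params))]])
        g <- g + cfg$weight_decay * params[[nm]]
      vel[[nm]] <- cfg$momentum * vel[[nm]] - lr * g
      params[[nm]] <- params[[nm]] + vel[[nm]]
    }
  }
  model$params <- params
  model <- calibrate_bn(model, x)
  list(model = model, loss_trace = loss_trace)
}

#' Recalibrate batch-norm running statistics
#'
#' Replaces every BN layer's running mean / variance with the statistics of
#' one pass over (up to `max_samples` of) the given data.  Small-batch
#' training leaves the momentum-averaged running statistics noisy; this
#' recalibration makes inference-mode behavior consistent with the trained
#' weights and is applied automatically at the end of [train_branch()].
#'
#' @param model a `sep_model`.
#' @param x input tensor or image list.
#' @param max_samples cap on the number of samples used (default 128).
#' @return the model with updated BN state.
#' @export
calibrate_bn <- function(model, x, max_samples = 128L) {
  x <- as_batch(x)
  n <- dim(x)[3]
  if (n > max_samples) x <- x[, , seq_len(max_samples), , drop = FALSE]
  # momentum 0: running statistics become exactly this pass's batch stats
  fw <- forward_graph(model, x, train = TRUE, bn_momentum = 0)
  model$state <- fw$state
  model
}

#' Load a manifest's images as an in-memory dataset
#'
#' Reads (optionally a subset of) a cohort's images into the tensor layout
#' used for training, resizing each image to `side` pixels for the global
#' branch.
#'
#' @param manifest a `manifest`.
#' @param dir directory the manifest paths are relative to.
#' @param side square input side; images are bilinearly resized.
#' @param reference optional `color_stats`; when given every image is stain
#'   normalized to it first.
#' @param indices optional record subset.
#' @return list with `x` (tensor), `y` (1-based labels, ordered by the
#'   manifest's class set) and `records`.
#' @export
load_dataset <- function(manifest, dir, side = 64L, reference = NULL,
                         indices = NULL) {
  cls <- class_names(manifest)
  df <- as.data.frame(manifest)
  if (!is.null(indices)) df <- df[indices, , drop = FALSE]
  imgs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    img <- read_image(file.path(dir, df$path[i]))
    if (!is.null(reference)) img <- stain_normalize(img, reference)
    imgs[[i]] <- bilinear_resize(img, side, side)
  }
  list(x = stack_images(imgs), y = match(df$label, cls), records = df)
}
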