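# Model checkpoints: R's native serialization plus a JSON shape manifest so
# a checkpoint's architecture can be cross-checked without loading it.

#' Save / load a model checkpoint
#'
#' `save_model()` writes the model with [saveRDS()] and a companion
#' `<path>.shapes.json` manifest (per-stage output shapes and the weight /
#' FLOP counts) for cross-checking.  `load_model()` restores the model and
#' verifies its class.
#'
#' @param model a `sep_model`.
#' @param path checkpoint path (conventionally `.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sep_model"))
  saveRDS(model, path)
  aud <- architecture_audit(model)
  cp <- count_params_flops(model)
  jsonlite::write_json(
    list(input_side = model$arch$input_side,
         width_multiplier = model$arch$width_multiplier,
         n_classes = model$arch$n_classes,
         weights = unname(cp[["weights"]]), flops = unname(cp[["flops"]]),
         shapes = aud),
    paste0(path, ".shapes.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sep_model"))
    stop("not a sepnet model checkpoint: ", path)
  model
}

#' Save prune masks or a loop report as JSON
#'
#' @param masks named list of `prune_mask` (as from [select_masks()]).
#' @param path output JSON path.
#' @export
save_prune_masks <- function(masks, path) {
  jsonlite::write_json(lapply(masks, unclass), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_prune_masks
#' @param report the `report` data frame of [prune_retrain_loop()].
#' @export
save_loop_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE)
  invisible(path)
}
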