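# Local patch voting, lambda-weighted hybrid fusion and the multi-model
# bagging ensemble.  All fusion operates on post-softmax probabilities.

#' Local-branch prediction by patch voting
#'
#' Runs the local model on every patch and merges the per-patch probability
#' vectors.  `"sum"` rule: arithmetic mean.  `"max"` rule: majority vote
#' over per-patch argmax labels; the returned vector is the mean over the
#' patches that voted for the winner, and ties fall back to the sum rule.
#'
#' @param model the local-branch `sep_model`.
#' @param patches non-empty list of patch images (or a tensor).
#' @param rule `"sum"` (default) or `"max"`.
#' @return probability vector `P_L`.
#' @export
predict_local <- function(model, patches, rule = c("sum", "max")) {
  rule <- match.arg(rule)
  if (is.list(patches) && !length(patches)) stop("empty patch list")
  probs <- predict_model(model, patches)
  vote_rows(probs, rule)
}

# Merge rows of a probability matrix under the sum / max voting rule.
vote_rows <- function(probs, rule) {
  if (!nrow(probs)) stop("no predictions to merge")
  if (rule == "sum" || nrow(probs) == 1L) return(colMeans(probs))
  lab <- max.col(probs, ties.method = "first")
  tab <- tabulate(lab, nbins = ncol(probs))
  winners <- which(tab == max(tab))
  if (length(winners) > 1L) return(colMeans(probs))   # tie -> sum rule
  colMeans(probs[lab == winners, , drop = FALSE])
}

#' Hybrid fusion of the two branch predictions
#'
#' `P = lambda * P_L + (1 - lambda) * P_G`: a convex combination of the
#' local patch-voting prediction and the global whole-image prediction.
#' The published operating point is `lambda = 0.6`.
#'
#' @param P_L,P_G probability vectors of equal length, each summing to 1.
#' @param lambda local-branch weight in `[0, 1]`.
#' @return object of class `hybrid_prediction`: list with `P_L`, `P_G`,
#'   `lambda`, fused `P` and `label` (argmax index).
#' @export
predict_hybrid <- function(P_L, P_G, lambda = 0.6) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (length(P_L) != length(P_G)) stop("branch predictions differ in length")
  for (v in list(P_L, P_G))
    if (any(v < -1e-9) || abs(sum(v) - 1) > 1e-6)
      stop("branch predictions must be probability vectors summing to 1")
  P <- lambda * P_L + (1 - lambda) * P_G
  structure(list(P_L = P_L, P_G = P_G, lambda = lambda, P = P,
                 label = which.max(P)), class = "hybrid_prediction")
}

#' Full hybrid prediction for one image
#'
#' Downsamples the image for the global branch, tiles it for the local
#' branch, and fuses the two branch predictions with weight `lambda`.
#'
#' @param global_model,local_model the two branch models.
#' @param img `H x W x 3` image array.
#' @param spec a [tiling_spec()].
#' @param lambda fusion weight (default 0.6).
#' @param rule local patch-voting rule.
#' @return a `hybrid_prediction`.
#' @export
hybrid_predict_image <- function(global_model, local_model, img,
                                 spec = tiling_spec(), lambda = 0.6,
                                 rule = c("sum", "max")) {
  rule <- match.arg(rule)
  P_G <- as.numeric(predict_model(global_model, downsample_global(img, spec)))
  P_L <- predict_local(local_model, tile(img, spec), rule)
  predict_hybrid(P_L, P_G, lambda)
}

#' Fuse per-model probability vectors of an ensemble
#'
#' `"sum"` rule: mean of the per-model probability vectors.  `"max"` rule:
#' majority vote on per-model argmax labels (ties fall back to the sum
#' rule).  The ensemble label is the argmax of the fused vector.
#'
#' @param probs matrix with one row per model.
#' @param rule `"sum"` (default) or `"max"`.
#' @return list with fused probability vector `P` and `label`.
#' @export
ensemble_fuse <- function(probs, rule = c("sum", "max")) {
  rule <- match.arg(rule)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (!nrow(probs)) stop("empty model list")
  P <- vote_rows(probs, rule)
  list(P = P, label = which.max(P))
}

#' Ensemble prediction for one image
#'
#' Each model (a single branch, or a `list(global=, local=)` hybrid pair)
#' yields a probability vector; the vectors are fused across models.
#'
#' @param models non-empty list of models.
#' @param img `H x W x 3` image array.
#' @param rule fusion rule across models.
#' @param spec tiling spec for hybrid members.
#' @param lambda hybrid fusion weight.
#' @return list with fused `P` and `label`.
#' @export
ensemble_predict <- function(models, img, rule = c("sum", "max"),
                             spec = tiling_spec(), lambda = 0.6) {
  rule <- match.arg(rule)
  if (!length(models)) stop("empty model list")
  probs <- t(vapply(models, function(m) {
    if (inherits(m, "sep_model"))
      as.numeric(predict_model(m, m_input(m, img)))
    else
      hybrid_predict_image(m$global, m$local, img, spec, lambda)$P
  }, numeric(n_classes_of(models[[1]]))))
  ensemble_fuse(probs, rule)
}

m_input <- function(model, img) {
  side <- model$arch$input_side
  bilinear_resize(img, side, side)
}

n_classes_of <- function(m) {
  if (inherits(m, "sep_model")) m$arch$n_classes else m$global$arch$n_classes
}

#' Write predictions to CSV
#'
#' Standard prediction export with columns
#' `path,patient_id,true_label,P_benign,P_malignant,pred_label`.
#'
#' @param df data frame with those columns.
#' @param path output CSV path.
#' @export
save_predictions <- function(df, path) {
  need <- c("path", "patient_id", "true_label", "P_benign", "P_malignant",
            "pred_label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("prediction table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  utils::write.csv(df[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_predictions
#' @export
load_predictions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
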