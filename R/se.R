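# Public squeeze / excitation / scale operations of the SE block, on plain
# H x W x C feature maps.  These are the reference forms the network's
# internal batched implementation must agree with.

#' SE squeeze: global average pooling per channel
#'
#' `z_i` is the mean of channel `i` over the `H x W` grid.
#'
#' @param X `H x W x C` numeric array of activations.
#' @return numeric `C`-vector `z`.
#' @export
se_squeeze <- function(X) {
  d <- dim(X)
  stopifnot(length(d) == 3L, all(d >= 1L), all(is.finite(X)))
  colMeans(matrix(X, nrow = d[1] * d[2]))
}

#' SEP block parameters
#'
#' The two bias-free FC layers of the excitation bottleneck: `W1` is
#' `(C/r) x C` (with width floored at 1), `W2` is `C x (C/r)`; the
#' activations are ReLU then sigmoid.
#'
#' @param C channel count.
#' @param r reduction ratio (default 16).
#' @param W1,W2 optional explicit weight matrices; random He draws otherwise.
#' @param seed RNG seed for the random draw.
#' @return object of class `sep_block_params`.
#' @export
sep_block_params <- function(C, r = 16L, W1 = NULL, W2 = NULL, seed = 1L) {
  b <- .se_bottleneck(C, r)
  if (is.null(W1) || is.null(W2)) {
    set.seed(seed)
    if (is.null(W1)) W1 <- matrix(rnorm(b * C, 0, sqrt(2 / C)), b, C)
    if (is.null(W2)) W2 <- matrix(rnorm(C * b, 0, sqrt(1 / b)), C, b)
  }
  if (!is.matrix(W1)) W1 <- matrix(W1, nrow = b)
  if (!is.matrix(W2)) W2 <- matrix(W2, ncol = nrow(W1))
  if (ncol(W1) != C || nrow(W2) != C || nrow(W1) != ncol(W2))
    stop("inconsistent SE weight shapes for C = ", C)
  structure(list(C = as.integer(C), r = as.integer(r), W1 = W1, W2 = W2),
            class = "sep_block_params")
}

#' SE excitation: per-channel activation factors
#'
#' `s = sigmoid(W2 %*% relu(W1 %*% z))`; no bias terms.  Every component
#' lies strictly in (0, 1).
#'
#' @param z `C`-vector from [se_squeeze()].
#' @param params a [sep_block_params()].
#' @return numeric `C`-vector `s`.
#' @export
se_excite <- function(z, params) {
  stopifnot(inherits(params, "sep_block_params"))
  if (length(z) != params$C)
    stop("z has length ", length(z), " but params expect C = ", params$C)
  as.numeric(plogis(params$W2 %*% pmax(params$W1 %*% z, 0)))
}

#' SE scale: reweight feature maps channel-wise
#'
#' Channel `i` of `X` is multiplied elementwise by `s_i`.
#'
#' @param X `H x W x C` array.
#' @param s `C`-vector of activation factors.
#' @return reweighted array of the same shape.
#' @export
se_scale <- function(X, s) {
  d <- dim(X)
  stopifnot(length(d) == 3L)
  if (d[3] != length(s))
    stop("X has ", d[3], " channels but s has length ", length(s))
  X * rep(s, each = d[1] * d[2])
}
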