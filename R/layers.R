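# Low-level layer primitives.  Activations are numeric arrays with
# dim = c(H, W, N, C): spatial grid, batch, channels.  Convolution weights
# are (k*k*Cin) x Cout matrices whose row order matches im2col_cpp
# (kernel row fastest, then kernel column, then input channel).

.tensor_dims <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  list(H = d[1], W = d[2], N = d[3], C = d[4])
}

# Stack a list of H x W x C images into an (H, W, N, C) batch tensor.
#' Stack images into a batch tensor
#'
#' Converts a list of `H x W x C` image arrays into the internal
#' `(H, W, N, C)` activation layout used by the network.
#'
#' @param imgs list of equally sized `H x W x C` arrays.
#' @return numeric array `H x W x N x C`.
#' @export
stack_images <- function(imgs) {
  stopifnot(length(imgs) >= 1L)
  d <- dim(imgs[[1]])
  n <- length(imgs)
  out <- array(0, c(d[1], d[2], n, d[3]))
  for (i in seq_len(n)) out[, , i, ] <- imgs[[i]]
  out
}

conv_fw <- function(x, W, k, stride, pad, cache = FALSE) {
  d <- .tensor_dims(x)
  cin <- nrow(W) / (k * k)
  if (cin != d$C) stop("conv input channel mismatch: ", d$C, " vs ", cin)
  P <- im2col_cpp(x, d$H, d$W, d$N, d$C, k, stride, pad)
  oH <- (d$H + 2 * pad - k) %/% stride + 1
  oW <- (d$W + 2 * pad - k) %/% stride + 1
  out <- crossprod(P, W)
  dim(out) <- c(oH, oW, d$N, ncol(W))
  if (cache) list(out = out, P = P, in_dims = d) else list(out = out)
}

conv_bw <- function(dout, cache, W, k, stride, pad) {
  d <- cache$in_dims
  od <- .tensor_dims(dout)
  dmat <- matrix(dout, ncol = od$C)          # (oH*oW*N) x Cout
  dW <- cache$P %*% dmat
  dP <- tcrossprod(W, dmat)
  dx <- col2im_cpp(dP, d$H, d$W, d$N, d$C, k, stride, pad)
  dim(dx) <- c(d$H, d$W, d$N, d$C)
  list(dx = dx, dW = dW)
}

bn_fw <- function(x, gamma, beta, rmean, rvar, eps = 1e-5, momentum = 0.9,
                  train = FALSE, cache = FALSE) {
  d <- .tensor_dims(x)
  n <- d$H * d$W * d$N
  m <- matrix(x, ncol = d$C)
  if (train) {
    mu <- .colMeans(m, n, d$C)
    xc <- m - rep(mu, each = n)
    va <- .colMeans(xc * xc, n, d$C)
    rmean <- momentum * rmean + (1 - momentum) * mu
    rvar <- momentum * rvar + (1 - momentum) * va
  } else {
    mu <- rmean
    va <- rvar
    xc <- m - rep(mu, each = n)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(istd, each = n)
  out <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  dim(out) <- c(d$H, d$W, d$N, d$C)
  res <- list(out = out, rmean = rmean, rvar = rvar)
  if (cache) { res$xhat <- xhat; res$istd <- istd; res$dims <- d }
  res
}

bn_bw <- function(dout, cache, gamma) {
  d <- cache$dims
  dm <- matrix(dout, ncol = d$C)
  n <- nrow(dm)
  C <- d$C
  dgamma <- .colSums(dm * cache$xhat, n, C)
  dbeta <- .colSums(dm, n, C)
  # standard batch-norm gradient (batch statistics)
  dxhat <- dm * rep(gamma, each = n)
  sum_dxhat <- .colSums(dxhat, n, C)
  sum_dxhat_xhat <- .colSums(dxhat * cache$xhat, n, C)
  dx <- (dxhat - rep(sum_dxhat / n, each = n) -
           cache$xhat * rep(sum_dxhat_xhat / n, each = n)) *
    rep(cache$istd, each = n)
  dim(dx) <- c(d$H, d$W, d$N, d$C)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x) pmax(x, 0)
relu_bw <- function(dout, x) dout * (x > 0)

maxpool_fw <- function(x, k, stride, pad = 0L, ceil_mode = FALSE) {
  d <- .tensor_dims(x)
  r <- maxpool_fw_cpp(x, d$H, d$W, d$N, d$C, k, stride, pad, ceil_mode)
  out <- r$out
  dim(out) <- c(r$oH, r$oW, d$N, d$C)
  list(out = out, argmax = r$argmax, in_dims = d)
}

maxpool_bw <- function(dout, cache) {
  d <- cache$in_dims
  dx <- maxpool_bw_cpp(dout, cache$argmax,
                       as.numeric(d$H) * d$W * d$N * d$C)
  dim(dx) <- c(d$H, d$W, d$N, d$C)
  dx
}

# Global average pool: (H, W, N, C) -> N x C matrix.
gap_fw <- function(x) {
  d <- .tensor_dims(x)
  hw <- d$H * d$W
  z <- .colMeans(x, hw, d$N * d$C)                # over spatial, cols = N*C
  list(out = matrix(z, d$N, d$C), in_dims = d)
}

gap_bw <- function(dout, cache) {
  d <- cache$in_dims
  dx <- rep(as.numeric(dout) / (d$H * d$W), each = d$H * d$W)
  dim(dx) <- c(d$H, d$W, d$N, d$C)
  dx
}

# Squeeze-excitation: z = spatial mean, s = sigmoid(W2 relu(W1 z)),
# out = x scaled per channel by s.  W1 is (b x C), W2 is (C x b), no biases.
se_fw <- function(x, W1, W2, cache = FALSE) {
  d <- .tensor_dims(x)
  z <- matrix(.colMeans(x, d$H * d$W, d$N * d$C), d$N, d$C)
  a <- z %*% t(W1)
  h <- pmax(a, 0)
  s <- plogis(h %*% t(W2))
  out <- x * rep(as.numeric(s), each = d$H * d$W)
  res <- list(out = out, s = s)
  if (cache) { res$z <- z; res$a <- a; res$h <- h; res$x <- x; res$dims <- d }
  res
}

se_bw <- function(dout, cache, W1, W2) {
  d <- cache$dims
  hw <- d$H * d$W
  s <- cache$s
  ds <- matrix(.colSums(dout * cache$x, hw, d$N * d$C), d$N, d$C)
  dx <- dout * rep(as.numeric(s), each = hw)
  dpre <- ds * s * (1 - s)                  # N x C, pre-sigmoid grad
  dW2 <- t(dpre) %*% cache$h                # C x b
  dh <- dpre %*% W2                         # N x b
  da <- dh * (cache$a > 0)
  dW1 <- t(da) %*% cache$z                  # b x C
  dz <- da %*% W1                           # N x C
  dx <- dx + rep(as.numeric(dz) / hw, each = hw)
  list(dx = dx, dW1 = dW1, dW2 = dW2)
}

fc_fw <- function(z, W, b) {
  sweep(z %*% t(W), 2L, b, `+`)             # N x K
}

fc_bw <- function(dout, z, W) {
  list(dx = dout %*% W, dW = t(dout) %*% z, db = colSums(dout))
}

softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# Mean cross-entropy and its gradient w.r.t. logits; y is 1-based class index.
ce_loss <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}
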