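# Patch tiling for the local branch, whole-image downsampling for the global
# branch, and the 8-fold random augmentation policy.

#' Tiling specification
#'
#' @param resize_to `c(width, height)` the image is bilinearly resized to
#'   before tiling; default `c(1120, 672)`, which yields 15 non-overlapping
#'   224-pixel patches.
#' @param patch_side side of the square local-branch patches (default 224).
#' @param global_input_side side of the square global-branch input
#'   (default 224).
#' @return object of class `tiling_spec`.
#' @export
tiling_spec <- function(resize_to = c(1120L, 672L), patch_side = 224L,
                        global_input_side = 224L) {
  if (length(resize_to) != 2L || any(resize_to < 1))
    stop("resize_to must be c(width, height)")
  if (patch_side > min(resize_to))
    stop("patch_side exceeds the resized image dimensions")
  structure(list(resize_to = as.integer(resize_to),
                 patch_side = as.integer(patch_side),
                 global_input_side = as.integer(global_input_side)),
            class = "tiling_spec")
}

#' Tile an image into non-overlapping patches
#'
#' Resizes the image to `spec$resize_to` and cuts it row-major on a
#' non-overlapping grid of `floor(W/side) x floor(H/side)` square patches;
#' right and bottom remainders are discarded.
#'
#' @param img `H x W x 3` array.
#' @param spec a [tiling_spec()].
#' @return ordered list of `side x side x 3` patch arrays.
#' @export
tile <- function(img, spec = tiling_spec()) {
  stopifnot(inherits(spec, "tiling_spec"))
  w <- spec$resize_to[1]; h <- spec$resize_to[2]; s <- spec$patch_side
  img <- bilinear_resize(img, h, w)
  nx <- w %/% s; ny <- h %/% s
  if (nx < 1 || ny < 1)
    stop("image smaller than one patch after resize")
  patches <- vector("list", nx * ny)
  k <- 0L
  for (gy in seq_len(ny)) {        # row-major: rows of the grid first
    for (gx in seq_len(nx)) {
      k <- k + 1L
      patches[[k]] <- img[((gy - 1) * s + 1):(gy * s),
                          ((gx - 1) * s + 1):(gx * s), , drop = FALSE]
    }
  }
  patches
}

#' Downsample a whole image for the global branch
#'
#' @param img `H x W x 3` array.
#' @param spec a [tiling_spec()]; output is
#'   `global_input_side x global_input_side`.
#' @return square array.
#' @export
downsample_global <- function(img, spec = tiling_spec()) {
  stopifnot(inherits(spec, "tiling_spec"))
  s <- spec$global_input_side
  bilinear_resize(img, s, s)
}

#' Augmentation policy
#'
#' Each augmented output is an independently sampled affine transform:
#' rotation uniform in `rotation_range` (degrees), horizontal and vertical
#' flips each with probability 0.5, and a shear uniform in
#' `[-shear_range, shear_range]` degrees.  Rotation is continuous rather
#' than a fixed-angle set.  Borders are reflect-padded and the output keeps
#' the input size.
#'
#' @param n_outputs augmented images per input (default 8).
#' @param rotation_range `c(min, max)` rotation in degrees (default
#'   `c(0, 360)`).
#' @param flip enable the two Bernoulli(0.5) flips (default `TRUE`).
#' @param shear_range maximal absolute shear angle in degrees (default 15).
#' @param seed RNG seed.
#' @return object of class `augment_policy`.
#' @export
augment_policy <- function(n_outputs = 8L, rotation_range = c(0, 360),
                           flip = TRUE, shear_range = 15, seed = 1L) {
  if (n_outputs < 1) stop("n_outputs must be >= 1")
  if (length(rotation_range) != 2L || rotation_range[2] < rotation_range[1])
    stop("rotation_range must be c(min, max)")
  if (shear_range < 0) stop("shear_range must be >= 0")
  structure(list(n_outputs = as.integer(n_outputs),
                 rotation_range = as.numeric(rotation_range),
                 flip = isTRUE(flip), shear_range = as.numeric(shear_range),
                 seed = as.integer(seed)),
            class = "augment_policy")
}

#' Read / write an augmentation policy as YAML
#' @param policy an `augment_policy`.
#' @param path YAML file path.
#' @export
save_augment_policy <- function(policy, path) {
  stopifnot(inherits(policy, "augment_policy"))
  yaml::write_yaml(unclass(policy), path)
  invisible(path)
}

#' @rdname save_augment_policy
#' @export
load_augment_policy <- function(path) {
  do.call(augment_policy, yaml::read_yaml(path))
}

#' Randomly augment one image
#'
#' Draws `policy$n_outputs` independent affine transforms (flip, then
#' rotation, then shear, composed about the image center) and applies each
#' with bilinear sampling and reflect padding.  Deterministic under
#' `policy$seed`; the unmodified original is not included.
#'
#' @param img `H x W x 3` array.
#' @param policy an [augment_policy()].
#' @return list of `policy$n_outputs` arrays of the input size.
#' @export
augment <- function(img, policy = augment_policy()) {
  stopifnot(inherits(policy, "augment_policy"))
  set.seed(policy$seed)
  out <- vector("list", policy$n_outputs)
  for (i in seq_len(policy$n_outputs)) {
    theta <- runif(1, policy$rotation_range[1], policy$rotation_range[2]) *
      pi / 180
    fh <- policy$flip && runif(1) < 0.5
    fv <- policy$flip && runif(1) < 0.5
    phi <- if (policy$shear_range > 0)
      runif(1, -policy$shear_range, policy$shear_range) * pi / 180 else 0
    # forward transform on centered (row, col) coordinates
    Fl <- diag(c(if (fv) -1 else 1, if (fh) -1 else 1))
    Ro <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2,
                 byrow = TRUE)
    Sh <- matrix(c(1, tan(phi), 0, 1), 2, byrow = TRUE)
    A <- Sh %*% Ro %*% Fl
    out[[i]] <- .affine_warp(img, solve(A))
  }
  out
}
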