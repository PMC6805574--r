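# Reinhard-style statistical color transfer in the logarithmic lab
# (l-alpha-beta) opponent space.  The forward RGB -> LMS and log-LMS -> lab
# matrices below are the canonical constants of that method; the inverse
# matrices are obtained by solve() at load time so the round trip is exact to
# machine precision rather than to the 4 printed decimals.

.RGB2LMS <- matrix(c(
  0.3811, 0.5783, 0.0402,
  0.1967, 0.7244, 0.0782,
  0.0241, 0.1288, 0.8444), nrow = 3, byrow = TRUE)

.LOG2LAB <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1,
           1, 1, -2,
           1, -1, 0), nrow = 3, byrow = TRUE)

.LMS2RGB <- solve(.RGB2LMS)
.LAB2LOG <- solve(.LOG2LAB)

# Guard added before the log so black pixels stay finite.
.LOG_GUARD <- 1 / 255
# Floor applied to channel standard deviations.
.STD_EPS <- 1e-6

#' Convert an RGB image to the lab opponent space
#'
#' Applies RGB -> LMS, adds a small guard (1/255) before taking `log10`, and
#' rotates into the decorrelated l-alpha-beta opponent space.  `l` carries
#' achromatic intensity, `alpha` a yellow-blue axis and `beta` a red-green
#' axis; for HE-stained tissue most stain variation lives in `alpha`/`beta`.
#'
#' @param img `H x W x 3` RGB array in `[0, 1]`.
#' @return `H x W x 3` array of lab values.
#' @export
rgb_to_lab <- function(img) {
  d <- dim(img)
  stopifnot(length(d) == 3L, d[3] == 3L)
  m <- matrix(img, ncol = 3L)
  lms <- pmax(m %*% t(.RGB2LMS), 0) + .LOG_GUARD
  lab <- log10(lms) %*% t(.LOG2LAB)
  array(lab, d)
}

#' Convert a lab image back to RGB
#'
#' Exact inverse of [rgb_to_lab()] up to gamut clipping (`clip = TRUE` clamps
#' the result to `[0, 1]`).
#'
#' @param lab `H x W x 3` lab array.
#' @param clip clamp output into the valid RGB range (default `TRUE`).
#' @return `H x W x 3` RGB array.
#' @export
lab_to_rgb <- function(lab, clip = TRUE) {
  d <- dim(lab)
  stopifnot(length(d) == 3L, d[3] == 3L)
  m <- matrix(lab, ncol = 3L)
  lms <- 10^(m %*% t(.LAB2LOG)) - .LOG_GUARD
  rgb <- lms %*% t(.LMS2RGB)
  if (clip) rgb <- clip01(rgb)
  array(rgb, d)
}

#' Per-channel color statistics in lab space
#'
#' Computes the per-channel mean and standard deviation of an image in the
#' lab opponent space; these six numbers fully parameterize the Reinhard
#' color transfer.  Standard deviations are floored at `1e-6` so constant
#' (zero-variance) images normalize without failure.
#'
#' @param img `H x W x 3` RGB array in `[0, 1]`.
#' @return object of class `color_stats`: list with `mean` and `sd`
#'   (3-vectors, lab order `l, alpha, beta`).
#' @export
compute_stats <- function(img) {
  lab <- matrix(rgb_to_lab(img), ncol = 3L)
  mu <- colMeans(lab)
  # population standard deviation; a single pixel gives sd 0 -> floored
  sdv <- sqrt(colMeans(sweep(lab, 2L, mu)^2))
  sdv <- pmax(sdv, .STD_EPS)
  structure(list(mean = as.numeric(mu), sd = as.numeric(sdv)),
            class = "color_stats")
}

#' @export
print.color_stats <- function(x, ...) {
  cat("lab color statistics\n")
  cat("  mean:", format(x$mean, digits = 4), "\n")
  cat("  sd:  ", format(x$sd, digits = 4), "\n")
  invisible(x)
}

#' Impose reference color statistics on an image
#'
#' Reinhard color transfer: each lab channel is recentred and rescaled so the
#' output statistics match `reference`, then mapped back to RGB.  Source
#' standard deviations are floored, so a constant image maps to the constant
#' whose lab value is the reference mean.
#'
#' @param img `H x W x 3` RGB array in `[0, 1]`.
#' @param reference `color_stats` of the reference image (see
#'   [compute_stats()]), or an RGB array from which stats are computed.
#' @param clip clamp the output to `[0, 1]` (default `TRUE`); `FALSE` is
#'   useful to inspect pre-clip statistics.
#' @return normalized `H x W x 3` RGB array.
#' @export
stain_normalize <- function(img, reference, clip = TRUE) {
  if (!inherits(reference, "color_stats")) reference <- compute_stats(reference)
  src <- compute_stats(img)
  lab <- rgb_to_lab(img)
  d <- dim(lab)
  m <- matrix(lab, ncol = 3L)
  m <- sweep(m, 2L, src$mean)
  m <- sweep(m, 2L, reference$sd / src$sd, `*`)
  m <- sweep(m, 2L, reference$mean, `+`)
  lab_to_rgb(array(m, d), clip = clip)
}

#' Save / load color statistics as YAML
#'
#' @param stats a `color_stats` object.
#' @param path YAML file path.
#' @return `save_color_stats` returns `path` invisibly; `load_color_stats`
#'   returns a `color_stats` object.
#' @export
save_color_stats <- function(stats, path) {
  stopifnot(inherits(stats, "color_stats"))
  yaml::write_yaml(list(mean = stats$mean, sd = stats$sd), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname save_color_stats
#' @export
load_color_stats <- function(path) {
  v <- yaml::read_yaml(path)
  if (is.null(v$mean) || is.null(v$sd) || length(v$mean) != 3L ||
      length(v$sd) != 3L)
    stop("not a color-stats YAML file: ", path)
  structure(list(mean = as.numeric(v$mean), sd = pmax(as.numeric(v$sd), .STD_EPS)),
            class = "color_stats")
}
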