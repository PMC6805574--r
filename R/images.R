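# In-memory images are numeric arrays dim c(H, W, 3) with values in [0, 1].

#' Read an image file
#'
#' Reads a PNG or JPEG file into the package's in-memory representation, an
#' `H x W x 3` numeric array in `[0, 1]`.  Grayscale images are replicated to
#' three channels; an alpha channel, if present, is dropped.
#'
#' @param path file path (`.png`, `.jpg`/`.jpeg`).
#' @return numeric array `H x W x 3`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read JPEG files")
      jpeg::readJPEG(path)
    },
    stop("unsupported image extension: ", ext)
  )
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an image to PNG
#'
#' @param img `H x W x 3` numeric array in `[0, 1]` (values are clipped).
#' @param path output path, `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(length(dim(img)) == 3L)
  png::writePNG(pmin(pmax(img, 0), 1), target = path)
  invisible(path)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Bilinear sampling at fractional (row, col) positions, coordinates 0-based.
# `row`/`col` are equal-length vectors; returns matrix length(row) x C.
.bilinear_sample <- function(img, row, col) {
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  row <- pmin(pmax(row, 0), h - 1)
  col <- pmin(pmax(col, 0), w - 1)
  r0 <- floor(row); c0 <- floor(col)
  r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- row - r0; fc <- col - c0
  out <- matrix(0, length(row), nc)
  for (ch in seq_len(nc)) {
    m <- img[, , ch]
    v00 <- m[cbind(r0 + 1, c0 + 1)]; v01 <- m[cbind(r0 + 1, c1 + 1)]
    v10 <- m[cbind(r1 + 1, c0 + 1)]; v11 <- m[cbind(r1 + 1, c1 + 1)]
    out[, ch] <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
      fr * ((1 - fc) * v10 + fc * v11)
  }
  out
}

#' Bilinear image resize
#'
#' Resizes with bilinear interpolation under the pixel-center convention
#' (`src = (dst + 0.5) * scale - 0.5`, clamped at the borders).
#'
#' @param img `H x W x C` numeric array.
#' @param out_h,out_w output dimensions in pixels.
#' @return resized array `out_h x out_w x C`.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  if (out_h == h && out_w == w) return(img)
  sy <- h / out_h; sx <- w / out_w
  ry <- (seq_len(out_h) - 0.5) * sy - 0.5
  rx <- (seq_len(out_w) - 0.5) * sx - 0.5
  grid_r <- rep(ry, times = out_w)
  grid_c <- rep(rx, each = out_h)
  v <- .bilinear_sample(img, grid_r, grid_c)
  array(v, c(out_h, out_w, nc))
}

# Reflect (mirror) a 0-based coordinate into [0, n-1].
.reflect_coord <- function(x, n) {
  if (n == 1L) return(rep(0, length(x)))
  p <- 2 * (n - 1)
  x <- x %% p
  x[x > (n - 1)] <- p - x[x > (n - 1)]
  x
}

# Apply the inverse-mapped 2x2 affine `Ainv` (acting on centered (row, col)
# coordinates) with reflect padding and bilinear sampling.  Output has the
# same size as the input.
.affine_warp <- function(img, Ainv) {
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  gr <- rep(seq_len(h) - 1 - cy, times = w)
  gc <- rep(seq_len(w) - 1 - cx, each = h)
  src_r <- Ainv[1, 1] * gr + Ainv[1, 2] * gc + cy
  src_c <- Ainv[2, 1] * gr + Ainv[2, 2] * gc + cx
  src_r <- .reflect_coord(src_r, h)
  src_c <- .reflect_coord(src_c, w)
  v <- .bilinear_sample(img, src_r, src_c)
  array(v, c(h, w, nc))
}
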