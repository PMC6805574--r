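# Synthetic histology-like cohorts: textured blob fields on an eosin-pink
# base, with a per-patient texture offset and a per-image random color cast
# applied in the same lab space the stain normalizer works in.

# HE-like palette (RGB in [0,1])
.BASE_RGB <- c(0.91, 0.74, 0.84)   # eosin-pink background
.BLOB_RGB <- c(0.38, 0.22, 0.52)   # hematoxylin-purple nuclei-like blobs

# Class-conditional texture parameters.  Blob density is per 64x64-pixel
# tile and scales with image area; `separability` moves the malignant class
# away from the benign one in blob count (+20 % per unit) and blob radius
# (+6 % per unit).  At separability 0 both classes are identically
# distributed.
.BLOB_DENSITY <- 18
.BLOB_RADIUS <- 1.7
.DENSITY_EFFECT <- 0.22
.RADIUS_EFFECT <- 0.05
.PATIENT_SD <- 0.06   # lognormal sd of the per-patient texture offset
.PIXEL_NOISE <- 0.015

#' Specification of a synthetic two-class cohort
#'
#' Describes a cohort of synthetic HE-like images with patient grouping.
#' Every image of a patient shares that patient's class label, and patients
#' carry a small random texture offset so patient-level and image-level
#' accuracy can genuinely differ.
#'
#' @param n_patients number of patients (positive integer).
#' @param images_per_patient images generated per patient.
#' @param image_size `c(width, height)` in pixels.
#' @param class_balance fraction of patients labelled `malignant`, in
#'   `[0, 1]`.
#' @param separability class-separation scalar `>= 0`; `0` makes the two
#'   classes identically distributed, larger values shift the malignant
#'   class's blob density and radius upward.
#' @param stain_variation standard deviation of the per-image color cast,
#'   applied as an additive shift in lab space (`0` disables the cast).
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, images_per_patient,
                        image_size = c(64, 64), class_balance = 0.5,
                        separability = 1, stain_variation = 0.1,
                        seed = 1L) {
  if (length(n_patients) != 1L || n_patients < 1 || n_patients %% 1 != 0)
    stop("n_patients must be a positive integer")
  if (length(images_per_patient) != 1L || images_per_patient < 1 ||
      images_per_patient %% 1 != 0)
    stop("images_per_patient must be a positive integer")
  if (length(image_size) != 2L || any(image_size < 8))
    stop("image_size must be c(width, height) with both >= 8")
  if (class_balance < 0 || class_balance > 1)
    stop("class_balance must lie in [0, 1]")
  if (separability < 0) stop("separability must be >= 0")
  if (stain_variation < 0) stop("stain_variation must be >= 0")
  structure(list(
    n_patients = as.integer(n_patients),
    images_per_patient = as.integer(images_per_patient),
    image_size = as.integer(image_size),
    class_balance = class_balance,
    separability = separability,
    stain_variation = stain_variation,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Read / write a cohort spec as YAML
#' @param spec a `cohort_spec`.
#' @param path YAML file path.
#' @export
save_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname save_cohort_spec
#' @export
load_cohort_spec <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(cohort_spec, v)
}

# Render one image: Gaussian blob splats subtracted from the pink base.
.render_image <- function(h, w, n_blobs, radius) {
  dens <- matrix(0, h, w)
  if (n_blobs > 0) {
    # dart-throwing placement with a minimum center distance, so blobs stay
    # resolvable as distinct connected components
    min_d2 <- (3.2 * radius)^2
    cx <- numeric(n_blobs); cy <- numeric(n_blobs)
    placed <- 0L
    for (b in seq_len(n_blobs)) {
      for (try in 1:30) {
        px <- runif(1, 1, w); py <- runif(1, 1, h)
        if (placed == 0L ||
            min((cx[seq_len(placed)] - px)^2 +
                (cy[seq_len(placed)] - py)^2) >= min_d2) break
      }
      placed <- placed + 1L
      cx[placed] <- px; cy[placed] <- py
    }
    rad <- radius * exp(rnorm(n_blobs, 0, 0.15))
    for (b in seq_len(n_blobs)) {
      s <- rad[b] / 1.2
      win <- ceiling(3 * s)
      r0 <- max(1, floor(cy[b] - win)); r1 <- min(h, ceiling(cy[b] + win))
      c0 <- max(1, floor(cx[b] - win)); c1 <- min(w, ceiling(cx[b] + win))
      if (r0 > r1 || c0 > c1) next
      dr <- (r0:r1) - cy[b]
      dc <- (c0:c1) - cx[b]
      g <- exp(-outer(dr^2, dc^2, `+`) / (2 * s^2))
      dens[r0:r1, c0:c1] <- dens[r0:r1, c0:c1] + g
    }
  }
  dens <- pmin(dens, 1)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3)
    img[, , ch] <- .BASE_RGB[ch] + (.BLOB_RGB[ch] - .BASE_RGB[ch]) * dens
  img + array(rnorm(h * w * 3, 0, .PIXEL_NOISE), c(h, w, 3))
}

# Class-conditional blob parameters for one image of one patient.
.texture_params <- function(label, separability, area_scale,
                            patient_density_mult, patient_radius_mult) {
  shift <- if (label == "malignant") separability else 0
  lambda <- .BLOB_DENSITY * (1 + .DENSITY_EFFECT * shift) *
    patient_density_mult * area_scale
  radius <- .BLOB_RADIUS * (1 + .RADIUS_EFFECT * shift) * patient_radius_mult
  list(lambda = lambda, radius = radius)
}

#' Generate a synthetic cohort on disk
#'
#' Writes `n_patients * images_per_patient` PNG images plus a CSV manifest
#' (`path,patient_id,label,split`) under `out_dir`.  Images are textured
#' blob fields whose blob density and radius differ between classes in
#' proportion to `spec$separability`; each image additionally receives a
#' random global color cast of magnitude `spec$stain_variation` drawn in lab
#' space.  Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if missing).
#' @return the cohort [manifest] (invisibly written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  w <- spec$image_size[1]; h <- spec$image_size[2]
  area_scale <- (w * h) / (64 * 64)

  set.seed(spec$seed)
  n_mal <- round(spec$n_patients * spec$class_balance)
  labels_pat <- c(rep("malignant", n_mal),
                  rep("benign", spec$n_patients - n_mal))
  labels_pat <- labels_pat[sample.int(spec$n_patients)]

  rows <- vector("list", spec$n_patients * spec$images_per_patient)
  k <- 0L
  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%03d", p)
    dmult <- exp(rnorm(1, 0, .PATIENT_SD))
    rmult <- exp(rnorm(1, 0, .PATIENT_SD))
    for (i in seq_len(spec$images_per_patient)) {
      tp <- .texture_params(labels_pat[p], spec$separability, area_scale,
                            dmult, rmult)
      n_blobs <- rpois(1, tp$lambda)
      img <- .render_image(h, w, n_blobs, tp$radius)
      if (spec$stain_variation > 0) {
        cast <- rnorm(3, 0, spec$stain_variation)
        lab <- rgb_to_lab(clip01(img))
        for (ch in 1:3) lab[, , ch] <- lab[, , ch] + cast[ch]
        img <- lab_to_rgb(lab)
      }
      fn <- sprintf("%s_img%03d.png", pid, i)
      write_image(img, file.path(out_dir, fn))
      k <- k + 1L
      rows[[k]] <- data.frame(path = fn, patient_id = pid,
                              label = labels_pat[p], split = "unassigned",
                              stringsAsFactors = FALSE)
    }
  }
  man <- new_manifest(do.call(rbind, rows),
                      class_names = c("benign", "malignant"))
  save_manifest(man, file.path(out_dir, "manifest.csv"))
  man
}

#' Deterministic feature-map fixtures for SE / pruning unit tests
#'
#' @param height,width,channels positive dimensions of the activation grid.
#' @param pattern one of `"constant"`, `"ramp"`, `"zeros"`, `"random"`.
#'   `"ramp"` fills each channel with `1..height*width` in row-major order;
#'   `"random"` draws uniform values using `seed`.
#' @param value fill value for `pattern = "constant"` (default `1`).
#' @param seed RNG seed, used only by `pattern = "random"`.
#' @return numeric array `height x width x channels`.
#' @export
make_feature_fixture <- function(height, width, channels,
                                 pattern = c("constant", "ramp", "zeros",
                                             "random"),
                                 value = 1, seed = 1L) {
  if (height < 1 || width < 1 || channels < 1)
    stop("dimensions must be positive")
  pattern <- match.arg(pattern)
  n <- height * width
  plane <- switch(pattern,
    constant = rep(value, n),
    zeros = rep(0, n),
    # row-major ramp: value at (row m, col n) is (m-1)*width + n
    ramp = as.numeric(t(matrix(seq_len(n), nrow = width))),
    random = { set.seed(seed); runif(n * channels) }
  )
  if (pattern == "random") return(array(plane, c(height, width, channels)))
  array(rep(plane, channels), c(height, width, channels))
}
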