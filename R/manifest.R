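# Cohort bookkeeping: CSV manifests, patient-aware splitting, the 5-fold
# bagging partition and the augmentation/tiling data-plan arithmetic.

.MANIFEST_COLS <- c("path", "patient_id", "label", "split")
.SPLIT_LEVELS <- c("train", "val", "test", "unassigned")

#' Construct a manifest
#'
#' A manifest is a data frame of image records (`path`, `patient_id`,
#' `label`, `split`, plus arbitrary extra columns) with an ordered class-name
#' attribute.  Paths must be unique, patient ids non-empty, labels members of
#' the class set and splits one of `train`, `val`, `test`, `unassigned`.
#'
#' @param records data frame with at least the four required columns.
#' @param class_names ordered character vector of class names (`>= 2`);
#'   defaults to the sorted unique labels.
#' @return object of class `manifest` (a data frame).
#' @export
new_manifest <- function(records, class_names = NULL) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.MANIFEST_COLS, names(records))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(records$path))
    stop("manifest contains duplicate paths")
  if (any(!nzchar(records$patient_id)))
    stop("manifest contains empty patient_id values")
  if (is.null(class_names)) class_names <- sort(unique(records$label))
  if (length(class_names) < 2L)
    stop("a manifest needs at least 2 class names")
  bad <- setdiff(unique(records$label), class_names)
  if (length(bad))
    stop("unknown label(s) not in the class set: ", paste(bad, collapse = ", "))
  bad_split <- setdiff(unique(records$split), .SPLIT_LEVELS)
  if (length(bad_split))
    stop("invalid split tag(s): ", paste(bad_split, collapse = ", "))
  structure(records, class = c("manifest", "data.frame"),
            class_names = as.character(class_names))
}

#' @export
print.manifest <- function(x, ...) {
  cat(sprintf("manifest: %d records, %d patients, classes {%s}\n",
              nrow(x), length(unique(x$patient_id)),
              paste(attr(x, "class_names"), collapse = ", ")))
  tab <- table(x$split)
  cat("  splits:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' Class names of a manifest
#' @param manifest a `manifest`.
#' @export
class_names <- function(manifest) attr(manifest, "class_names")

#' Read / write manifests as CSV
#'
#' The CSV schema is `path,patient_id,label,split`; extra columns round-trip
#' unchanged.  A missing required column raises a schema error naming it.
#'
#' @param csv_path CSV file path.
#' @param class_names optional ordered class set; labels outside it raise a
#'   validation error.  Default: inferred (sorted unique labels).
#' @return `load_manifest` returns a `manifest`; `save_manifest` returns the
#'   path invisibly.
#' @export
load_manifest <- function(csv_path, class_names = NULL) {
  if (!file.exists(csv_path)) stop("manifest file not found: ", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  new_manifest(df, class_names = class_names)
}

#' @rdname load_manifest
#' @param manifest a `manifest`.
#' @export
save_manifest <- function(manifest, csv_path) {
  stopifnot(inherits(manifest, "manifest"))
  utils::write.csv(as.data.frame(manifest), csv_path, row.names = FALSE,
                   quote = FALSE)
  invisible(csv_path)
}

#' Patient-level train/test split
#'
#' Assigns whole patients to train or test so that no patient contributes
#' images to both sides.  The number of train patients is
#' `ceiling(train_fraction * n_patients)` (fractions round toward train),
#' bounded so both sides keep at least one patient.
#'
#' @param manifest a `manifest`.
#' @param train_fraction fraction of patients assigned to train, in (0, 1).
#' @param seed RNG seed controlling the patient shuffle.
#' @return the manifest with `split` set to `"train"` / `"test"`.
#' @export
patient_split <- function(manifest, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(manifest, "manifest"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  patients <- unique(manifest$patient_id)
  if (length(patients) < 2L)
    stop("patient_split needs at least 2 patients")
  set.seed(seed)
  patients <- patients[sample.int(length(patients))]
  n_train <- ceiling(train_fraction * length(patients) - 1e-9)
  n_train <- max(1L, min(length(patients) - 1L, n_train))
  train_set <- patients[seq_len(n_train)]
  manifest$split <- ifelse(manifest$patient_id %in% train_set,
                           "train", "test")
  manifest
}

#' 5-fold bagging partition of a training pool
#'
#' Randomly splits the records of a training pool into `n_folds`
#' non-overlapping subsets of as-equal-as-possible size (earlier folds take
#' the remainder records).  Model `i` validates on fold `i` and trains on
#' the remaining folds.
#'
#' @param training_pool a `manifest` (or data frame) of training records.
#' @param n_folds number of folds / models (default 5).
#' @param seed RNG seed for the record shuffle.
#' @return object of class `fold_plan`: list with `n_folds`, `assignments`
#'   (fold index per record) and `seed`.
#' @export
bagging_partition <- function(training_pool, n_folds = 5L, seed = 1L) {
  n <- nrow(training_pool)
  if (n < n_folds)
    stop("training pool (", n, ") is smaller than n_folds (", n_folds, ")")
  set.seed(seed)
  ord <- sample.int(n)
  base <- n %/% n_folds
  extra <- n %% n_folds
  sizes <- rep(base, n_folds) + c(rep(1L, extra), rep(0L, n_folds - extra))
  assignments <- integer(n)
  assignments[ord] <- rep(seq_len(n_folds), times = sizes)
  structure(list(n_folds = as.integer(n_folds),
                 assignments = assignments, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Training / validation record indices for one bagged model
#'
#' @param plan a [bagging_partition()] result.
#' @param fold model index in `1..n_folds`; validation = that fold, training
#'   = all other folds.
#' @return list with integer index vectors `train` and `val`.
#' @export
fold_members <- function(plan, fold) {
  stopifnot(inherits(plan, "fold_plan"), fold >= 1, fold <= plan$n_folds)
  list(train = which(plan$assignments != fold),
       val = which(plan$assignments == fold))
}

#' Save / load a fold plan as JSON
#' @param plan a `fold_plan`.
#' @param path JSON file path.
#' @export
save_fold_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fold_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_fold_plan
#' @export
load_fold_plan <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(n_folds = as.integer(v$n_folds),
                 assignments = as.integer(v$assignments),
                 seed = as.integer(v$seed)), class = "fold_plan")
}

#' Augmentation / tiling data-plan arithmetic
#'
#' Sizes the training manifests of the experimental protocol without
#' materializing any pixels: each base image yields `augment_factor`
#' augmented images, and each augmented image yields `patches_per_image`
#' local-branch patches.
#'
#' @param base_count number of base training images.
#' @param augment_factor augmented images per base image (default 8).
#' @param patches_per_image tiled patches per augmented image (default 15).
#' @return object of class `data_plan` with derived `image_count` and
#'   `patch_count`.
#' @export
build_data_plan <- function(base_count, augment_factor = 8L,
                            patches_per_image = 15L) {
  if (base_count < 1 || augment_factor < 1 || patches_per_image < 1)
    stop("data-plan counts must be positive integers")
  image_count <- base_count * augment_factor
  structure(list(base_count = base_count,
                 augment_factor = augment_factor,
                 patches_per_image = patches_per_image,
                 image_count = image_count,
                 patch_count = image_count * patches_per_image),
            class = "data_plan")
}

#' @export
print.data_plan <- function(x, ...) {
  cat(sprintf("data plan: %d base x %d augment = %d images; x %d patches = %d patch entries\n",
              x$base_count, x$augment_factor, x$image_count,
              x$patches_per_image, x$patch_count))
  invisible(x)
}

#' Read a BreaKHis-style directory layout into a manifest
#'
#' Convenience adapter for the `class/magnification/image` folder convention
#' (`<root>/<class>/<magnification>/<file>`).  The patient id is taken from
#' the leading `<id>_`-prefix of the file name when present, otherwise from
#' the file name stem.
#'
#' @param root directory whose first level is class folders.
#' @return a `manifest` with an extra `magnification` column.
#' @export
read_class_tree <- function(root) {
  if (!dir.exists(root)) stop("directory not found: ", root)
  classes <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  if (length(classes) < 2L) stop("need at least 2 class directories under ", root)
  rows <- list()
  for (cl in classes) {
    mags <- list.dirs(file.path(root, cl), recursive = FALSE,
                      full.names = FALSE)
    if (!length(mags)) mags <- ""
    for (mg in mags) {
      dirp <- if (nzchar(mg)) file.path(root, cl, mg) else file.path(root, cl)
      files <- list.files(dirp, pattern = "\\.(png|jpe?g|tiff?)$",
                          ignore.case = TRUE)
      for (f in files) {
        stem <- tools::file_path_sans_ext(f)
        pid <- sub("_.*$", "", stem)
        rows[[length(rows) + 1L]] <- data.frame(
          path = if (nzchar(mg)) file.path(cl, mg, f) else file.path(cl, f),
          patient_id = pid, label = cl, split = "unassigned",
          magnification = mg, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no image files found under ", root)
  new_manifest(do.call(rbind, rows), class_names = sort(classes))
}
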