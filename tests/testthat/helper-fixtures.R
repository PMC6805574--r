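# Shared helpers and independent oracles for the test suite.

# Flood-fill connected-component counter (4-connectivity) used as the
# independent oracle for blob counting; deliberately naive.
count_components <- function(img, dark_threshold = 0.62) {
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  mask <- gray < dark_threshold
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  cur
}

# Small architectures for fast unit tests.
mini_arch <- function(input_side = 32L)
  network_architecture(width_multiplier = 1 / 16, input_side = input_side)

random_image <- function(h, w, lo = 0.1, hi = 0.9) {
  array(runif(h * w * 3, lo, hi), c(h, w, 3))
}

# A manifest without any files on disk (splitting / bagging tests).
fake_manifest <- function(n_patients, images_per_patient,
                          classes = c("benign", "malignant")) {
  pid <- rep(sprintf("P%04d", seq_len(n_patients)), each = images_per_patient)
  lab <- rep(classes[(seq_len(n_patients) %% 2) + 1L],
             each = images_per_patient)
  new_manifest(data.frame(
    path = sprintf("img%05d.png", seq_along(pid)),
    patient_id = pid, label = lab, split = "unassigned",
    stringsAsFactors = FALSE), class_names = classes)
}

# Cohort cached per session: several test files reuse it.
cached_cohort <- local({
  env <- new.env()
  function(separability = 3, stain_variation = 0.05, seed = 11L,
           n_patients = 10L, images_per_patient = 4L) {
    key <- paste(separability, stain_variation, seed, n_patients,
                 images_per_patient, sep = "_")
    if (is.null(env[[key]])) {
      dir <- file.path(tempdir(), paste0("cohort_", key))
      man <- generate_cohort(
        cohort_spec(n_patients, images_per_patient,
                    separability = separability,
                    stain_variation = stain_variation, seed = seed), dir)
      env[[key]] <- list(dir = dir, manifest = man)
    }
    env[[key]]
  }
})

# Accuracy of a model on an in-memory dataset.
model_accuracy <- function(model, data)
  mean(max.col(predict_model(model, data$x)) == data$y)

# Independent straightforward metric tallies (loops, no shared code with
# the package implementations).
naive_metrics <- function(true, pred, positive = "malignant") {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(true)) {
    if (true[i] == positive && pred[i] == positive) tp <- tp + 1L
    else if (true[i] != positive && pred[i] != positive) tn <- tn + 1L
    else if (true[i] != positive && pred[i] == positive) fp <- fp + 1L
    else fn <- fn + 1L
  }
  n <- tp + tn + fp + fn
  acc <- (tp + tn) / n
  acc_r <- ((tp + fp) / n) * ((tp + fn) / n) +
    ((tn + fn) / n) * ((tn + fp) / n)
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       kappa = if (abs(1 - acc_r) > 1e-12) (acc - acc_r) / (1 - acc_r)
               else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
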