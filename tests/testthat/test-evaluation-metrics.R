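# Patient-level / image-level accuracy, PPV, kappa, F1, ROC.

pred_df <- function(pid, true, pred, score = NULL) {
  df <- data.frame(patient_id = pid, true_label = true, pred_label = pred,
                   stringsAsFactors = FALSE)
  if (!is.null(score)) df$P_malignant <- score
  df
}

test_that("patient score and patient-level rate follow their definitions", {
  one <- pred_df(rep("P1", 4), rep("malignant", 4),
                 c("malignant", "malignant", "malignant", "benign"))
  r <- patient_level(one)
  expect_equal(r$patient_scores$PS, 0.75)
  expect_equal(r$PL, 0.75)

  two <- pred_df(c("P1", "P1", "P2"), rep("benign", 3),
                 c("benign", "malignant", "benign"))
  expect_equal(patient_level(two)$PL, 0.75)   # PS 0.5 and 1.0

  allc <- pred_df(c("P1", "P2"), c("benign", "malignant"),
                  c("benign", "malignant"))
  expect_equal(patient_level(allc)$PL, 1)
  expect_error(patient_level(pred_df(character(), character(), character())),
               "empty")
})

test_that("image-level rate pools over all images; PL differs when unbalanced", {
  df <- pred_df(rep("P1", 10), rep("benign", 10),
                rep(c("benign", "malignant"), c(8, 2)))
  expect_equal(image_level(df), 0.8)
  expect_equal(image_level(pred_df("P1", "benign", "malignant")), 0)

  # one patient with 9 images (8 correct), one with 1 image (0 correct):
  # IL = 8/10, PL = mean(8/9, 0) = 4/9
  un <- pred_df(c(rep("A", 9), "B"), rep("malignant", 10),
                c(rep("malignant", 8), "benign", "benign"))
  expect_equal(image_level(un), 0.8)
  expect_equal(patient_level(un)$PL, mean(c(8 / 9, 0)))
})

test_that("PL equals IL whenever every patient has equal image counts", {
  set.seed(40)
  for (i in 1:10) {
    npat <- sample(2:6, 1); per <- sample(1:5, 1)
    true <- sample(c("benign", "malignant"), npat * per, replace = TRUE)
    pred <- sample(c("benign", "malignant"), npat * per, replace = TRUE)
    df <- pred_df(rep(sprintf("P%d", 1:npat), each = per), true, pred)
    expect_equal(patient_level(df)$PL, image_level(df), tolerance = 1e-12)
  }
})

test_that("PPV handles its worked example and degenerate counts", {
  expect_equal(ppv(structure(list(TP = 40, TN = 0, FP = 10, FN = 0),
                             class = "eval_counts")), 0.8)
  expect_equal(ppv(confusion_counts(c("malignant", "benign"),
                                    c("malignant", "benign"))), 1)
  expect_equal(ppv(structure(list(TP = 0, TN = 0, FP = 5, FN = 0),
                             class = "eval_counts")), 0)
  expect_true(is.na(ppv(structure(list(TP = 0, TN = 3, FP = 0, FN = 2),
                                  class = "eval_counts"))))
})

test_that("kappa matches the hand-computed marginal chance correction", {
  k <- kappa(structure(list(TP = 40, TN = 40, FP = 10, FN = 10),
                       class = "eval_counts"))
  expect_equal(k, 0.6)   # Acc 0.8, Acc_r 0.5
  expect_equal(kappa(structure(list(TP = 30, TN = 20, FP = 0, FN = 0),
                               class = "eval_counts")), 1)
  expect_equal(kappa(structure(list(TP = 50, TN = 0, FP = 50, FN = 0),
                               class = "eval_counts")), 0)  # Acc = Acc_r
  expect_true(is.na(kappa(structure(list(TP = 5, TN = 0, FP = 0, FN = 0),
                                    class = "eval_counts"))))
})

test_that("F1 / precision / recall match their arithmetic", {
  f <- f1_precision_recall(structure(list(TP = 40, TN = 0, FP = 10, FN = 10),
                                     class = "eval_counts"))
  expect_equal(unname(f), c(0.8, 0.8, 0.8))
  f2 <- f1_precision_recall(structure(list(TP = 30, TN = 0, FP = 10, FN = 20),
                                      class = "eval_counts"))
  expect_equal(f2[["precision"]], 0.75)
  expect_equal(f2[["recall"]], 0.6)
  expect_equal(f2[["F1"]], 2 / 3)
  f3 <- f1_precision_recall(structure(list(TP = 7, TN = 3, FP = 0, FN = 0),
                                      class = "eval_counts"))
  expect_equal(unname(f3), c(1, 1, 1))
})

test_that("ROC sweep: perfect, reversed and label-free scores", {
  lab <- c(rep(TRUE, 20), rep(FALSE, 20))
  sc <- c(runif(20, 0.6, 1), runif(20, 0, 0.4))
  expect_equal(roc_points(sc, lab)$auc, 1)
  r <- roc_points(-sc, lab)
  expect_equal(r$auc, 1 - roc_points(sc, lab)$auc)
  set.seed(41)
  big_lab <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  big_sc <- runif(2000)
  expect_lt(abs(roc_points(big_sc, big_lab)$auc - 0.5), 0.05)
  expect_error(roc_points(runif(5), rep(TRUE, 5)), "one positive")
})

test_that("kappa stays in [-1, 1] and centers at 0 under label shuffles", {
  set.seed(42)
  true <- sample(c("benign", "malignant"), 200, replace = TRUE,
                 prob = c(0.4, 0.6))
  ks <- replicate(50, {
    pred <- sample(true)   # marginal-preserving shuffle
    kappa(confusion_counts(true, pred))
  })
  expect_true(all(ks >= -1 & ks <= 1))
  expect_lt(abs(mean(ks)), 0.05)
})

test_that("all metrics agree with independent tallies on 100 random tables", {
  set.seed(43)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    true <- sample(c("benign", "malignant"), n, replace = TRUE)
    pred <- sample(c("benign", "malignant"), n, replace = TRUE)
    counts <- confusion_counts(true, pred)
    ref <- naive_metrics(true, pred)
    expect_equal(counts$TP, ref$TP)
    expect_equal(counts$TN, ref$TN)
    expect_equal(counts$FP, ref$FP)
    expect_equal(counts$FN, ref$FN)
    expect_equal(ppv(counts), ref$ppv)
    expect_equal(kappa(counts), ref$kappa)
    f <- f1_precision_recall(counts)
    expect_equal(f[["precision"]], ref$precision)
    expect_equal(f[["recall"]], ref$recall)
  }
})

test_that("the metrics report aggregates and serializes", {
  set.seed(44)
  df <- pred_df(rep(sprintf("P%d", 1:5), each = 4),
                sample(c("benign", "malignant"), 20, replace = TRUE),
                sample(c("benign", "malignant"), 20, replace = TRUE),
                score = runif(20))
  rep <- metrics_report(df)
  expect_equal(rep$IL, image_level(df))
  expect_equal(rep$PL, patient_level(df)$PL)
  f <- tempfile(fileext = ".json")
  save_metrics_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$IL, rep$IL)
})
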