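# Branch training, patch voting, hybrid fusion, ensembling.

test_that("training configuration defaults match the published recipe", {
  cfg <- train_config()
  expect_equal(cfg$batch_size, 10L)
  expect_equal(cfg$initial_lr, 4e-4)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$weight_decay, 0.009)
  expect_equal(cfg$iterations, 40000L)
  expect_equal(cfg$lr_decay_every, 10000L)
})

test_that("training configs round-trip through YAML", {
  cfg <- desk_train_config(iterations = 123, seed = 9)
  f <- tempfile(fileext = ".yaml")
  save_train_config(cfg, f)
  expect_equal(load_train_config(f), cfg)
})

test_that("zero learning rate leaves all parameters unchanged", {
  m <- build_model(mini_arch(), seed = 1)
  set.seed(30)
  data <- list(x = array(runif(32 * 32 * 4 * 3), c(32, 32, 4, 3)),
               y = c(1L, 2L, 1L, 2L))
  tr <- train_branch(m, data, train_config(initial_lr = 0, iterations = 5,
                                           weight_decay = 0))
  expect_identical(tr$model$params, m$params)
})

test_that("training is deterministic under the config seed", {
  m <- build_model(mini_arch(), seed = 2)
  set.seed(31)
  data <- list(x = array(runif(32 * 32 * 6 * 3), c(32, 32, 6, 3)),
               y = rep(1:2, 3))
  cfg <- desk_train_config(iterations = 8, seed = 77)
  t1 <- train_branch(m, data, cfg)
  t2 <- train_branch(m, data, cfg)
  expect_identical(t1$loss_trace, t2$loss_trace)
  expect_identical(t1$model$params, t2$model$params)
  expect_length(t1$loss_trace, 8L)
})

test_that("a 20-sample toy cohort is overfit to 100% training accuracy", {
  # 3 seeds, majority pass; 300 iterations, desk profile, 32px inputs
  co <- cached_cohort(separability = 3, stain_variation = 0, seed = 23,
                      n_patients = 10, images_per_patient = 2)
  d <- load_dataset(co$manifest, co$dir, side = 32)
  hits <- 0L
  for (s in 1:3) {
    m <- build_model(mini_arch(), seed = s)
    tr <- train_branch(m, d, desk_train_config(iterations = 300, seed = s))
    if (model_accuracy(tr$model, d) == 1) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("patch voting merges probabilities under both rules", {
  probs <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.1, 0.9))
  expect_equal(sepnet:::vote_rows(probs, "sum"), c(0.5, 0.5))
  # argmax labels {1, 1, 2} (with the 0.5/0.5 tie to the first class):
  # majority class 1, mean over its voters
  expect_equal(sepnet:::vote_rows(probs, "max"), c(0.7, 0.3))
  # identical predictions: same result under either rule
  same <- rbind(c(0.8, 0.2), c(0.8, 0.2))
  expect_equal(sepnet:::vote_rows(same, "sum"), c(0.8, 0.2))
  expect_equal(sepnet:::vote_rows(same, "max"), c(0.8, 0.2))
  # a real model on identical patches agrees with its single prediction
  m <- build_model(mini_arch(), seed = 3)
  patch <- random_image(32, 32)
  pl <- predict_local(m, list(patch, patch, patch), rule = "max")
  expect_equal(pl, as.numeric(predict_model(m, patch)), tolerance = 1e-12)
  expect_error(predict_local(m, list()), "empty")
})

test_that("hybrid fusion is the lambda-weighted convex combination", {
  h <- predict_hybrid(c(1, 0), c(0, 1), lambda = 0.6)
  expect_equal(h$P, c(0.6, 0.4))
  expect_equal(h$label, 1L)
  expect_equal(predict_hybrid(c(0.3, 0.7), c(0.9, 0.1), lambda = 1)$P,
               c(0.3, 0.7))
  expect_equal(predict_hybrid(c(0.3, 0.7), c(0.9, 0.1), lambda = 0)$P,
               c(0.9, 0.1))
  expect_error(predict_hybrid(c(1, 0), c(0, 1), lambda = 1.2), "lambda")
  expect_error(predict_hybrid(c(1, 0), c(0.4, 0.4)), "summing to 1")
  # simplex preservation for random convex combinations
  set.seed(32)
  for (i in 1:20) {
    a <- runif(2); a <- a / sum(a)
    b <- runif(2); b <- b / sum(b)
    expect_equal(sum(predict_hybrid(a, b, runif(1))$P), 1, tolerance = 1e-6)
  }
})

test_that("ensemble fusion follows the sum and max voting rules", {
  probs <- rbind(c(0.8, 0.2), c(0.6, 0.4), c(0.4, 0.6), c(0.9, 0.1),
                 c(0.3, 0.7))
  r <- ensemble_fuse(probs, "sum")
  expect_equal(r$P, c(0.6, 0.4))
  expect_equal(r$label, 1L)
  # labels {1, 1, 2, 1, 2} -> majority class 1 under max rule
  expect_equal(ensemble_fuse(probs, "max")$label, 1L)
  # labels {1, 1, 2, 2, 2} -> class 2
  probs2 <- rbind(c(0.8, 0.2), c(0.6, 0.4), c(0.4, 0.6), c(0.1, 0.9),
                  c(0.3, 0.7))
  expect_equal(ensemble_fuse(probs2, "max")$label, 2L)
  # identical members: fused equals the single model under both rules
  same <- matrix(rep(c(0.7, 0.3), each = 5), 5)
  expect_equal(ensemble_fuse(same, "sum")$P, c(0.7, 0.3))
  expect_equal(ensemble_fuse(same, "max")$P, c(0.7, 0.3))
  expect_error(ensemble_fuse(matrix(0, 0, 2)), "empty")
})

test_that("hybrid and ensemble prediction run end to end on an image", {
  img <- random_image(64, 64)
  spec <- tiling_spec(resize_to = c(64, 64), patch_side = 32,
                      global_input_side = 32)
  mg <- build_model(mini_arch(), seed = 4)
  ml <- build_model(mini_arch(), seed = 5)
  h <- hybrid_predict_image(mg, ml, img, spec)
  expect_s3_class(h, "hybrid_prediction")
  expect_equal(sum(h$P), 1, tolerance = 1e-6)
  expect_equal(h$P, 0.6 * h$P_L + 0.4 * h$P_G)
  e <- ensemble_predict(list(mg, ml), img, spec = spec)
  expect_equal(sum(e$P), 1, tolerance = 1e-6)
  expect_true(e$label %in% 1:2)
})

test_that("prediction CSVs round-trip with the standard schema", {
  df <- data.frame(path = c("a.png", "b.png"), patient_id = c("P1", "P1"),
                   true_label = c("benign", "malignant"),
                   P_benign = c(0.8, 0.3), P_malignant = c(0.2, 0.7),
                   pred_label = c("benign", "malignant"))
  f <- tempfile(fileext = ".csv")
  save_predictions(df, f)
  expect_equal(load_predictions(f), df)
  expect_error(save_predictions(df[, -2], f), "patient_id")
})
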