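# Pruning schedule, importance statistics, channel selection and surgery.

test_that("geometric schedule closed form matches its printed values", {
  expect_equal(per_loop_proportion(0.5, 1), 0.5)
  expect_equal(round(per_loop_proportion(0.8, 2), 2), 0.55)
  expect_equal(round(per_loop_proportion(0.8, 3), 2), 0.42)
  expect_equal(round(per_loop_proportion(0.8, 4), 2), 0.33)
  expect_equal(per_loop_proportion(0, 7), 0)
  expect_error(per_loop_proportion(1, 2), "O must")
  expect_error(per_loop_proportion(0.5, 0), "R must")
})

test_that("geometric-series identity holds to 1e-12 for random schedules", {
  set.seed(11)
  for (i in 1:100) {
    O <- runif(1, 0, 0.99)
    R <- sample(1:8, 1)
    X <- per_loop_proportion(O, R)
    removed <- sum((1 - X)^(seq_len(R) - 1) * X)
    expect_lt(abs(removed - O), 1e-12)
  }
})

test_that("importance accumulation is a streaming mean of SE factors", {
  m <- build_model(mini_arch(), seed = 4)
  set.seed(12)
  x1 <- array(runif(32 * 32 * 1 * 3), c(32, 32, 1, 3))
  xN <- array(0, c(32, 32, 5, 3))
  for (i in 1:5) xN[, , i, ] <- x1[, , 1, ]      # 5 identical samples
  imp <- accumulate_importance(m, xN)
  s1 <- sepnet:::forward_graph(m, x1, capture_se = TRUE)$se
  for (nm in names(imp)) {
    expect_equal(imp[[nm]]$w, as.numeric(s1[[paste0("m", nm, ".sep")]]),
                 tolerance = 1e-12)
    expect_equal(imp[[nm]]$n_samples, 5L)
    expect_true(all(imp[[nm]]$w > 0 & imp[[nm]]$w < 1))
  }
  # streaming (batch 3) equals the stacked batch mean
  set.seed(13)
  xr <- array(runif(32 * 32 * 10 * 3), c(32, 32, 10, 3))
  a <- accumulate_importance(m, xr, batch_size = 3)
  b <- accumulate_importance(m, xr, batch_size = 32)
  for (nm in names(a)) expect_equal(a[[nm]]$w, b[[nm]]$w, tolerance = 1e-7)
  expect_error(accumulate_importance(m, xr[, , integer(), , drop = FALSE]),
               "empty")
})

test_that("two-sample importance is the forced arithmetic mean", {
  s <- rbind(c(0.2, 0.8), c(0.4, 0.6))
  expect_equal(colMeans(s), c(0.3, 0.7))   # the Eq. definition at N = 2
})

test_that("select_prune_set prunes the X lowest-importance channels", {
  mask <- select_prune_set(c(0.1, 0.4, 0.2, 0.3), 0.5)
  expect_equal(mask$kept, c(2L, 4L))
  expect_equal(mask$C_p, 2L)
  expect_equal(select_prune_set(c(0.5, 0.1), 0)$kept, 1:2)
  expect_equal(select_prune_set(0.9, 0.9)$kept, 1L)   # keep-one floor
  expect_error(select_prune_set(c(0.1, 0.2), 1), "X must")
})

test_that("select_prune_set agrees with a brute-force sort oracle", {
  brute <- function(w, X) {
    n_prune <- min(length(w) - 1, floor(X * length(w) + 0.5))
    ord <- order(w, seq_along(w))
    sort(setdiff(seq_along(w), ord[seq_len(max(0, n_prune))]))
  }
  set.seed(14)
  for (i in 1:200) {
    C <- sample(2:64, 1)
    w <- round(runif(C), sample(c(1, 2, 6), 1))   # rounded draws force ties
    X <- runif(1, 0, 0.99)
    expect_identical(select_prune_set(w, X)$kept, brute(w, X))
  }
})

test_that("threshold rule TH = mu + sigma + k behaves as printed", {
  m1 <- select_by_threshold(rep(0.4, 6), 0.1)   # sigma = 0, TH > mean
  expect_equal(m1$C_p, 1L)
  m2 <- select_by_threshold(c(0.9, 0.9, 0.9), 0.1)   # TH = 1.0
  expect_equal(m2$C_p, 1L)
  set.seed(15)
  w <- runif(32)
  n_low <- select_by_threshold(w, 0.1)$C_p
  n_high <- select_by_threshold(w, 0.5)$C_p
  expect_gte(n_low, n_high)   # pruned-set size non-decreasing in k
  expect_error(select_by_threshold(w, 0.6), "k must")
})

test_that("identity-coupled layers receive a shared mean-importance mask", {
  stub <- list(couples = list(c("a", "b")))
  imp <- list(
    a = structure(list(layer_id = "a", w = c(0.9, 0.1, 0.8, 0.2),
                       n_samples = 1L), class = "channel_importance"),
    b = structure(list(layer_id = "b", w = c(0.1, 0.9, 0.2, 0.8),
                       n_samples = 1L), class = "channel_importance"))
  masks <- select_masks(stub, imp, 0.5)
  expect_identical(masks$a$kept, masks$b$kept)
  # mean importance is flat 0.5 -> ties by index: prune channels 1, 2
  expect_identical(masks$a$kept, c(3L, 4L))
})

test_that("all-keep surgery is a no-op for the forward pass", {
  m <- build_model(mini_arch(), seed = 6)
  set.seed(16)
  x <- array(runif(32 * 32 * 2 * 3), c(32, 32, 2, 3))
  masks <- select_masks(m, accumulate_importance(m, x), 0)
  m2 <- apply_pruning(m, masks)
  expect_lt(max(abs(predict_model(m2, x) - predict_model(m, x))), 1e-6)
})

test_that("pruning identically-zero channels never changes the forward pass", {
  set.seed(17)
  for (rep in 1:3) {
    m <- build_model(mini_arch(), seed = 20 + rep)
    mod <- sample(c("3a", "3b", "4a", "4b", "4c"), 1)
    branch <- sample(c("b1", "b3"), 1)
    key <- sprintf("m%s.%s.conv.W", mod, branch)
    w_dim <- dim(m$params[[key]])
    kill <- sort(sample(w_dim[2], min(2, w_dim[2] - 1)))
    # non-positive filters + ReLU => exactly-zero activations on any input
    m$params[[key]][, kill] <- -abs(m$params[[key]][, kill]) - 0.1
    m$params[[sprintf("m%s.%s.bn.beta", mod, branch)]][kill] <- 0
    x <- array(runif(32 * 32 * 2 * 3), c(32, 32, 2, 3))
    # global channel indices of the killed branch channels
    br <- m$arch$modules[[which(vapply(m$arch$modules, `[[`, "", "name") == mod)]]$branches
    offset <- if (branch == "b1") 0L else br$b1
    C <- sepnet:::.module_out_channels(
      m$arch$modules[[which(vapply(m$arch$modules, `[[`, "", "name") == mod)]])
    masks <- list(structure(list(layer_id = mod,
                                 kept = setdiff(seq_len(C), offset + kill),
                                 C = C, C_p = C - length(kill)),
                            class = "prune_mask"))
    names(masks) <- mod
    m2 <- apply_pruning(m, masks)
    expect_lt(max(abs(predict_model(m2, x) - predict_model(m, x))), 1e-6)
  }
})

test_that("50% surgery halves the producing filters and consumer slices", {
  m <- build_model(toy_architecture(), seed = 7)
  br <- m$arch$modules[[1]]$branches            # module 3a
  C <- sepnet:::.module_out_channels(m$arch$modules[[1]])
  keep <- seq_len(C / 2) * 2L                   # keep every second channel
  masks <- list("3a" = structure(list(layer_id = "3a", kept = keep, C = C,
                                      C_p = length(keep)),
                                 class = "prune_mask"))
  m2 <- apply_pruning(m, masks)
  for (bn in c("b1", "b3", "b5", "pp")) {
    key <- sprintf("m3a.%s.conv.W", bn)
    kept_in_branch <- sum(masks[["3a"]]$kept %in%
                            (sum(unlist(br[c("b1", "b3", "b5", "pp")])[
                              seq_len(match(bn, c("b1", "b3", "b5", "pp")) - 1)]) +
                              seq_len(br[[bn]])))
    expect_equal(ncol(m2$params[[key]]), kept_in_branch)
    expect_equal(nrow(m2$params[[key]]), nrow(m$params[[key]]))
  }
  # consumers in 3b: input rows halved on the 1x1 entries
  for (bn in c("b1", "b3r", "b5r", "pp"))
    expect_equal(nrow(m2$params[[sprintf("m3b.%s.conv.W", bn)]]), C / 2)
  expect_lt(count_params_flops(m2)[["weights"]],
            count_params_flops(m)[["weights"]])
})

test_that("masks on the unpruned stem are rejected", {
  m <- build_model(mini_arch(), seed = 8)
  bad <- list(stem = structure(list(layer_id = "stem", kept = 1:4, C = 8,
                                    C_p = 4), class = "prune_mask"))
  expect_error(apply_pruning(m, bad), "non-prunable")
})

test_that("the prune-retrain loop follows round(X*C) channel trajectories", {
  set.seed(18)
  x <- array(runif(32 * 32 * 8 * 3), c(32, 32, 8, 3))
  data <- list(x = x, y = rep(1:2, 4))
  cfg <- desk_train_config(iterations = 3, seed = 1)

  # O = 0.5, R = 1: toy layer C = 32 -> 16 retained
  m <- build_model(mini_arch(), seed = 9)
  r1 <- prune_retrain_loop(m, data, prune_schedule(0.5, 1), cfg)
  row_4e <- r1$report[r1$report$layer == "4e", ]
  expect_equal(row_4e$channels_before, 117L)
  expect_equal(row_4e$channels_after, 58L)
  expect_true(all(r1$report$channels_after ==
                    r1$report$channels_before -
                    floor(r1$report$channels_before * 0.5 + 0.5)))

  # O = 0.75, R = 2 gives X = 0.5 per loop: 64-channel toy layer 64->32->16
  m2 <- build_model(mini_arch(), seed = 10)
  r2 <- prune_retrain_loop(m2, data, prune_schedule(0.75, 2), cfg)
  tr_4e <- r2$report[r2$report$layer == "4e", ]
  expect_equal(tr_4e$channels_before, c(117L, 58L))
  expect_equal(tr_4e$channels_after, c(58L, 29L))

  # weight count strictly decreases across loops whenever channels drop
  w0 <- count_params_flops(m2)[["weights"]]
  w_final <- count_params_flops(r2$model)[["weights"]]
  expect_lt(w_final, w0)

  # O = 0: architecture unchanged, only retrained
  m3 <- build_model(mini_arch(), seed = 11)
  r3 <- prune_retrain_loop(m3, data, prune_schedule(0, 2), cfg)
  expect_equal(r3$model$arch, m3$arch)
  expect_true(all(r3$report$channels_before == r3$report$channels_after))
})

test_that("training divergence aborts with a diagnostic", {
  m <- build_model(mini_arch(), seed = 12)
  bad <- list(x = array(NaN, c(32, 32, 2, 3)), y = c(1L, 2L))
  expect_error(train_branch(m, bad, desk_train_config(iterations = 2)),
               "non-finite")
})
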