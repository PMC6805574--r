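# SE computations, architecture construction, weight / FLOP counting.

test_that("se_squeeze matches forced arithmetic and a brute-force oracle", {
  expect_equal(se_squeeze(make_feature_fixture(2, 2, 1, "constant", 3)), 3)
  expect_equal(se_squeeze(make_feature_fixture(2, 2, 1, "ramp")), 2.5)
  X <- make_feature_fixture(5, 7, 3, "random", seed = 21)
  oracle <- numeric(3)
  for (c in 1:3) {
    s <- 0
    for (m in 1:5) for (n in 1:7) s <- s + X[m, n, c]
    oracle[c] <- s / 35
  }
  expect_equal(se_squeeze(X), oracle)
})

test_that("se_excite follows the two-FC bottleneck form", {
  pz <- sep_block_params(3, r = 16, W1 = matrix(0, 1, 3),
                         W2 = matrix(0, 3, 1))
  expect_equal(se_excite(c(1, 2, 3), pz), rep(0.5, 3))   # sigma(0) = 0.5

  p1 <- sep_block_params(1, W1 = matrix(2, 1, 1), W2 = matrix(1, 1, 1))
  expect_equal(se_excite(1, p1), plogis(2))

  set.seed(3)
  pr <- sep_block_params(8, seed = 5)
  s <- se_excite(rnorm(8), pr)
  expect_true(all(s > 0 & s < 1))
  expect_error(se_excite(rnorm(5), pr), "length")
})

test_that("se_scale reweights channels and composes linearly with squeeze", {
  X <- make_feature_fixture(3, 3, 2, "random", seed = 9)
  expect_equal(se_scale(X, c(1, 1)), X)
  expect_equal(se_scale(X, c(0, 0)), X * 0)
  expect_equal(se_scale(make_feature_fixture(2, 2, 1, "constant", 2), 0.5),
               array(1, c(2, 2, 1)))
  s <- c(0.3, 1.7)
  expect_equal(se_squeeze(se_scale(X, s)), s * se_squeeze(X))
  expect_error(se_scale(X, c(1, 2, 3)), "channels")
})

test_that("the internal batched SE agrees with the public reference ops", {
  X <- make_feature_fixture(4, 6, 5, "random", seed = 13)
  prm <- sep_block_params(5, seed = 2)
  xb <- array(X, c(4, 6, 1, 5))
  r <- sepnet:::se_fw(xb, prm$W1, prm$W2)
  s_ref <- se_excite(se_squeeze(X), prm)
  expect_equal(as.numeric(r$s), s_ref, tolerance = 1e-12)
  expect_equal(array(r$out[, , 1, ], c(4, 6, 5)), se_scale(X, s_ref),
               tolerance = 1e-12)
})

test_that("the compiled graph has 7 Inception modules each with a SEP block", {
  arch <- network_architecture()
  expect_length(arch$modules, 7L)
  m <- build_model(mini_arch(), seed = 1)   # same topology, mini widths
  ids <- vapply(m$nodes, `[[`, "", "id")
  seps <- grep("^m.*\\.sep$", ids, value = TRUE)
  concats <- grep("\\.concat$", ids, value = TRUE)
  expect_length(seps, 7L)
  expect_length(concats, 7L)
  # every concat is immediately followed by its SEP block
  expect_equal(match(seps, ids), match(concats, ids) + 1L)
  expect_equal(dim(m$params$head.fc.W)[1], 2L)
})

test_that("softmax outputs are probability vectors on random inputs", {
  m <- build_model(mini_arch(), seed = 2)
  set.seed(10)
  for (i in 1:5) {
    x <- array(runif(32 * 32 * 2 * 3), c(32, 32, 2, 3))
    p <- predict_model(m, x)
    expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("toy-profile forward succeeds and rejects bad multipliers", {
  m <- build_model(toy_architecture(), seed = 3)
  p <- predict_model(m, random_image(64, 64))
  expect_equal(dim(p), c(1L, 2L))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_error(network_architecture(width_multiplier = 0), "multiplier")
  expect_error(network_architecture(width_multiplier = 2), "multiplier")
})

test_that("weight and FLOP counting match hand counts", {
  # one 1x1 conv, 2 -> 3 channels, no bias, 4x4 input:
  # weights = 1*1*2*3 = 6; MACs = 4*4*3*2 = 96; FLOPs = 192
  toy <- list(
    arch = list(input_side = 4L, in_channels = 2L),
    nodes = list(sepnet:::.node("input", "input", character()),
                 sepnet:::.node("c1", "conv", "input", k = 1L, stride = 1L,
                                pad = 0L)),
    out_id = "c1",
    params = list(c1.W = matrix(rnorm(6), 2, 3)),
    state = list())
  expect_equal(count_params_flops(toy),
               c(weights = 6, flops = 192))
  empty <- list(arch = list(input_side = 4L), nodes = list(), params = list())
  expect_equal(count_params_flops(empty), c(weights = 0, flops = 0))
})

test_that("architecture specs round-trip through YAML", {
  arch <- mini_arch()
  f <- tempfile(fileext = ".yaml")
  save_architecture(arch, f)
  back <- load_architecture(f)
  expect_equal(back$stem, arch$stem)
  expect_equal(vapply(back$modules, sepnet:::.module_out_channels, 0),
               vapply(arch$modules, sepnet:::.module_out_channels, 0))
  # a model built from the restored spec is behaviorally identical
  x <- array(runif(32 * 32 * 1 * 3), c(32, 32, 1, 3))
  expect_equal(predict_model(build_model(back, seed = 5), x),
               predict_model(build_model(arch, seed = 5), x))
  expect_error(load_architecture({
    f2 <- tempfile(fileext = ".yaml"); yaml::write_yaml(list(a = 1), f2); f2
  }), "architecture")
})

test_that("width multiplier 1 reproduces the published module widths", {
  arch <- network_architecture()
  totals <- vapply(arch$modules, sepnet:::.module_out_channels, 0)
  expect_equal(totals, c(256, 480, 512, 512, 512, 528, 1856))
  expect_equal(arch$stem, list(c1 = 64L, c2r = 64L, c2 = 192L))
})
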