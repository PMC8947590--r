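# Architecture construction, forward-pass contracts, movement injection and
# per-layer activation summaries.

test_that("spec validation enforces the architecture contract", {
  spec <- cnn_spec(c(28L, 28L), n_classes = 3L)
  expect_equal(spec$channels, c(16L, 32L, 64L))
  expect_error(cnn_spec(c(28L, 28L), n_classes = 3L, injection_layer = 4L),
               "injection_layer")
  expect_error(cnn_spec(c(4L, 4L), n_classes = 3L), "too small")
  spec2 <- cnn_spec(c(21L, 21L), n_conv = 2L, n_classes = 10L)
  expect_equal(spec2$channels, c(16L, 32L))
})

test_that("trainable parameters live in conv/fc layers plus one bn block", {
  net <- build_network(cnn_spec(c(28L, 28L), n_classes = 3L), 1L)
  expect_setequal(names(net$params), c("conv1", "conv2", "conv3", "bn", "fc"))
  expect_equal(nrow(net$params$conv1$w), 16L)
  expect_equal(nrow(net$params$conv2$w), 32L)
  expect_equal(nrow(net$params$conv3$w), 64L)
  expect_equal(length(net$params$bn$gamma), 16L)   # bn follows conv-1
  # feature-image injection widens the receiving conv only
  netf <- build_network(cnn_spec(c(21L, 21L), n_classes = 10L,
                                 movement_mode = "feature_image",
                                 injection_layer = 2L), 1L)
  expect_equal(ncol(netf$params$conv2$w), 9L * 17L)
  expect_equal(ncol(netf$params$conv1$w), 9L * 1L)
  expect_equal(length(netf$params$bn$gamma), 32L)
})

test_that("outputs are class probabilities and reproducible under seed", {
  ds <- generate_fixational_dataset(60L, "constant", seed = 2L)
  net1 <- build_network(cnn_spec(c(28L, 28L), n_classes = 3L), 9L)
  net2 <- build_network(cnn_spec(c(28L, 28L), n_classes = 3L), 9L)
  expect_identical(net1$params, net2$params)
  p <- net_forward(net1, ds$train$x)$probs
  expect_equal(colSums(p), rep(1, 30L))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, net_forward(net1, ds$train$x)$probs)
})

test_that("untrained networks score at chance on balanced data", {
  ds <- generate_fixational_dataset(400L, "constant", seed = 3L)
  accs <- vapply(1:10, function(s) {
    net <- build_network(cnn_spec(c(28L, 28L), n_classes = 3L), s)
    evaluate_network(net, ds$test)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 1 / 3), 0.05)
})

test_that("global scalar injection is linear before normalization", {
  # bn placed on conv-1 so the layer-2 addition stage is directly observable
  spec <- cnn_spec(c(28L, 28L), n_classes = 3L,
                   movement_mode = "global_scalar", injection_layer = 2L,
                   bn_layer = 1L)
  net <- build_network(spec, 4L)
  x <- array(runif(28 * 28 * 2), c(28L, 28L, 1L, 2L))
  a1 <- net_forward(net, x, movement = c(5, 5), keep = "acts")$acts$L2
  a2 <- net_forward(net, x, movement = c(10, 10), keep = "acts")$acts$L2
  both_on <- a1 > 0 & a2 > 0
  expect_gt(sum(both_on), 0)
  expect_equal(unique(round(a2[both_on] - a1[both_on], 10)), 5)
})

test_that("movement plumbing errors are informative", {
  netf <- tiny_feature_net()
  x <- array(0, c(21L, 21L, 1L, 2L))
  expect_error(net_forward(netf, x), "movement input required")
  net0 <- build_network(cnn_spec(c(21L, 21L), n_classes = 10L), 1L)
  expect_error(net_forward(net0, x, movement = x), "movement_mode = none")
  expect_error(net_forward(netf, x, movement = array(0, c(5L, 5L, 1L, 2L))),
               "does not match")
})

test_that("channel means equal an explicit two-loop spatial average", {
  net <- tiny_feature_net()
  x <- array(runif(21 * 21 * 3, 0, 255), c(21L, 21L, 3L))
  mv <- array(0, c(21L, 21L, 3L))
  la <- layer_activations(net, x, mv, layer = 2L)
  expect_equal(dim(la$channel_mean), c(32L, 3L))
  for (ch in c(1L, 17L)) {
    for (n in 1:3) {
      acc <- 0
      for (i in seq_len(dim(la$tensor)[1])) {
        for (j in seq_len(dim(la$tensor)[2])) {
          acc <- acc + la$tensor[i, j, ch, n]
        }
      }
      expect_equal(la$channel_mean[ch, n],
                   acc / prod(dim(la$tensor)[1:2]))
    }
  }
  expect_error(layer_activations(net, x, mv, layer = 5L), "layer")
})
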