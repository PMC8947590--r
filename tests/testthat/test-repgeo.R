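# Embedding/readout decoding, activity-mode angles, gating and direction
# decoding on controlled synthetic activations.

test_that("well-separated clusters decode perfectly; shuffled labels at chance", {
  syn <- synthetic_clusters(k = 2L, n = 25L, sep = 6, seed = 1L)
  res <- embed_and_decode(syn$features, syn$labels, recipe = "pca",
                          readout = "svm_quadratic", seed = 2L)
  expect_equal(res$accuracy, 1)
  syn10 <- synthetic_clusters(k = 10L, n = 20L, sep = 5, seed = 2L)
  set.seed(3)
  shuffled <- sample(syn10$labels)
  chance <- embed_and_decode(syn10$features, shuffled, recipe = "pca",
                             readout = "svm_quadratic", seed = 2L)$accuracy
  se <- sqrt(0.1 * 0.9 / length(shuffled))
  expect_lt(chance, 0.1 + 4 * se)
  # confusion marginals: rows sum to per-class counts
  expect_equal(sum(res$confusion), 50L)
  expect_equal(length(res$per_fold), 5L)
})

test_that("lda readout is perfect on linearly separated activations", {
  syn <- synthetic_clusters(k = 6L, n = 20L, sep = 8, seed = 4L)
  res <- embed_and_decode(syn$features, syn$labels, recipe = "pca",
                          n_components = 3L, readout = "lda", seed = 5L)
  expect_equal(res$accuracy, 1)
})

test_that("pca and tsne readouts agree on clustered activations", {
  syn <- synthetic_clusters(k = 4L, n = 30L, sep = 2.2, seed = 6L)
  a_pca <- embed_and_decode(syn$features, syn$labels, recipe = "pca",
                            n_components = 2L, readout = "svm_quadratic",
                            seed = 7L)$accuracy
  a_tsne <- embed_and_decode(syn$features, syn$labels, recipe = "tsne",
                             n_components = 2L, readout = "svm_quadratic",
                             seed = 7L)$accuracy
  expect_lt(abs(a_pca - a_tsne), 0.1)
  expect_gt(a_tsne, 0.5)
})

test_that("tsne preserves cluster neighborhoods", {
  set.seed(8)
  X <- rbind(matrix(rnorm(40 * 3), 40), matrix(rnorm(40 * 3, mean = 8), 40))
  Y <- tsne_embed(X, seed = 9L)
  d <- as.matrix(dist(Y))
  within <- mean(d[1:40, 1:40])
  across <- mean(d[1:40, 41:80])
  expect_gt(across, 2 * within)
})

test_that("decoding conclusions are stable across embedding seeds", {
  syn <- synthetic_clusters(k = 3L, n = 25L, sep = 3, seed = 12L)
  accs <- vapply(1:3, function(s) {
    embed_and_decode(syn$features, syn$labels, recipe = "tsne",
                     readout = "svm_quadratic", seed = s)$accuracy
  }, 0)
  expect_true(all(accs > 0.6))
  expect_lt(diff(range(accs)), 0.25)
})

test_that("degenerate embedding input is rejected", {
  X <- matrix(1, nrow = 4L, ncol = 30L)
  expect_error(embed_and_decode(X, rep(1:2, 15L), recipe = "pca"),
               "degenerate")
})

test_that("mode angles: parallel 0, orthogonal 90, antiparallel 0", {
  A <- cbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0), c(0, 0, 0))
  B <- cbind(c(2, 0, 0), c(0, 3, 0), c(-1, 0, 0), c(1, 0, 0))
  ang <- activity_mode_angle(A, B)
  expect_equal(ang[1], 0)
  expect_equal(ang[2], 90)
  expect_equal(ang[3], 0)          # abs() folds antiparallel onto 0
  expect_true(is.na(ang[4]))       # zero vector excluded
  # via a network: zero visual input excludes every example
  net <- tiny_feature_net()
  zim <- array(0, c(21L, 21L, 3L))
  mv <- array(runif(21 * 21 * 3), c(21L, 21L, 3L))
  res <- mode_angle(net, zim, mv * 0, layer = 1L)
  expect_equal(res$n_excluded, 3L)
})

test_that("gating profile reports certain zeros for silent networks", {
  net <- tiny_feature_net()
  mv <- array(0, c(21L, 21L, 4L))
  g <- gating_profile(net, mv)
  expect_equal(g$p_zero, rep(1, 3))
  expect_equal(g$max_amp, rep(0, 3))
})

test_that("direction groups decode perfectly from raw movement images", {
  set.seed(10)
  n <- 90L
  shifts <- matrix(sample(c(-4:-1, 1:4), 2L * n, TRUE), ncol = 2L)
  S <- 21L
  mv <- array(0, c(S, S, n))
  for (j in seq_len(n)) {
    mv[, , j] <- make_movement_image(shifts[j, ], c(S, S), "congruent",
                                     scale = 2)
  }
  net <- tiny_feature_net()
  dd <- decode_directions(net, mv, shifts, seed = 11L)
  expect_equal(dd$accuracy[dd$layer == 0L], 1)
  expect_true(all(dd$accuracy >= 1 / 3 - 0.1))
  expect_error(decode_directions(net, mv, rbind(shifts, c(0L, 3L))),
               "cardinal")
})
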