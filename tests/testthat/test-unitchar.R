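# Probe construction, receptive-field window mapping, modulation
# classification, activation maximization and orientation analysis.

test_that("probe is a centred 5x5 square at the median image mean", {
  set.seed(41)
  imgs <- array(runif(21 * 21 * 40, 0, 255), c(21L, 21L, 40L))
  probe <- probe_stimulus(imgs)
  expect_equal(sum(probe != 0), 25L)
  expect_equal(attr(probe, "value"),
               median(apply(imgs, 3L, mean)))
  nz <- which(probe != 0, arr.ind = TRUE)
  expect_equal(range(nz[, 1]), c(9L, 13L))    # symmetric around centre 11
  expect_equal(range(nz[, 2]), c(9L, 13L))
})

test_that("probe-covering units are the only ones responding to the probe", {
  net <- tiny_feature_net()
  spec <- net$spec
  probe <- matrix(0, 21L, 21L)
  probe[9:13, 9:13] <- 120
  mv <- array(0, c(21L, 21L, 1L))
  a_probe <- net_forward(net, array(probe, c(21L, 21L, 1L)), mv,
                         keep = "acts")$acts
  a_zero <- net_forward(net, array(0, c(21L, 21L, 1L)), mv,
                        keep = "acts")$acts
  win <- probe_units(spec, 9:13, 9:13)
  for (l in 1:3) {
    d <- abs(a_probe[[l]] - a_zero[[l]])
    outside <- d
    outside[win[[l]]$rows, win[[l]]$cols, , ] <- 0
    expect_equal(max(outside), 0,
                 label = paste("layer", l, "response outside window"))
    expect_gt(max(d), 0)
  }
})

test_that("movement pool fills six amplitude bins with exactly 20 each", {
  mp <- movement_pool(4L, 6L, 20L, seed = 2L)
  expect_equal(as.vector(table(mp$bins)), rep(20L, 6L))
  expect_equal(nrow(mp$shifts), 120L)
  len <- sqrt(rowSums(mp$shifts^2))
  for (b in 1:6) {
    expect_true(all(len[mp$bins == b] <= mp$edges[b + 1L] + 1e-9))
  }
  expect_identical(mp, movement_pool(4L, 6L, 20L, seed = 2L))
})

test_that("modulation classes partition channels and match crafted profiles", {
  bins <- rbind(
    suppressed = rep(-0.5, 6),
    enhanced = rep(0.5, 6),
    gain = -(1:6) / 4,
    mixed = c(0.5, -0.4, 0.3, -0.2, 0.4, -0.5),
    silent = rep(0, 6))
  cl <- cdvis:::classify_modulation(bins)
  expect_equal(unname(cl[1:3]), c("suppressed", "enhanced", "gain"))
  expect_true(all(cl %in% c("suppressed", "enhanced", "gain", "mixed")))
})

test_that("modulation variability is zero for homogeneous channels", {
  mod <- list(layers = list(list(layer = 1L,
                                 delta = matrix(0.3, nrow = 8L, ncol = 12L),
                                 bins = rep(1:6, each = 2L))))
  v <- modulation_variability(mod)
  expect_equal(v$sd_mean, rep(0, 6))
  expect_true(all(v$ci_width >= 0))
})

test_that("zero-amplitude movement leaves probe responses unchanged", {
  fix <- trained_fixational()
  pool0 <- list(shifts = matrix(0L, 12L, 2L), bins = rep(1:6, each = 2L),
                edges = seq(0, 1, length.out = 7L))
  net <- study_pool()$congruent$nets[[1L]]
  probe <- probe_stimulus(study_pool()$congruent$ds$train$x)
  mod <- saccadic_modulation(net, probe, pool0, scale = 2)
  for (lay in mod$layers) {
    expect_equal(max(abs(lay$delta)), 0, tolerance = 1e-8)
  }
})

test_that("activation maximization increases the target channel activation", {
  fix <- trained_fixational()
  img1 <- maximize_activation(fix$net, layer = 1L, channel = 2L,
                              input_range = c(0, 1), seed = 3L)
  if (!attr(img1, "dead")) {
    expect_gte(attr(img1, "activation"), attr(img1, "activation_start"))
  }
  img2 <- maximize_activation(fix$net, layer = 1L, channel = 2L,
                              input_range = c(0, 1), seed = 3L)
  expect_equal(unclass(img1), unclass(img2), ignore_attr = TRUE)
  expect_equal(dim(img1), c(28L, 28L))
  expect_true(min(img1) >= 0 && max(img1) <= 1)
})

test_that("orientation analysis yields six-point tuning curves per channel", {
  net <- build_network(cnn_spec(c(21L, 21L), n_classes = 6L), 2L)
  set.seed(5)
  ori <- rep(1:6, each = 4L)
  imgs <- array(0, c(21L, 21L, length(ori)))
  for (j in seq_along(ori)) imgs[, , j] <- make_grating(ori[j])
  oa <- orientation_analysis(net, list(images = imgs, orientation = ori),
                             folds = 4L, seed = 6L)
  expect_equal(length(oa), 3L)
  t1 <- oa[[1L]]$tuning
  expect_equal(nrow(t1), 16L * 6L)
  expect_true(all(t1$hi >= t1$lo))
  expect_true(all(vapply(oa, function(l) l$prop_tuned, 0) >= 0))
  expect_true(all(vapply(oa, function(l) l$lda_accuracy, 0) <= 1))
})

test_that("visual-report probability sums the visual output channels", {
  cfg <- experiment_config("phosphene", seed = 2L)
  cfg$n_per_class <- 40L
  res <- run_experiment(cfg)
  spot <- make_focal_spot()
  p_vis <- visual_report_probability(res$net, spot)
  probs <- net_forward(res$net, array(spot, c(28L, 28L, 1L)))$probs[, 1L]
  expect_equal(unname(p_vis), sum(probs[1:4]))
  # the untrained focal pattern spreads probability over all channels
  expect_gt(min(probs), 0.01)
  expect_gt(p_vis, 0.1)
})
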