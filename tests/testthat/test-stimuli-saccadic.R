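# Framed-image preprocessing, the surrogate generator, saccadic shifts, the
# movement-image pixel code, and the enumerated direction-information bounds.

test_that("preprocessing frames the image and preserves the central content", {
  set.seed(31)
  src <- matrix(runif(32 * 32, 0, 255), 32)
  out <- preprocess_image(src)
  expect_equal(dim(out), c(42L, 42L))
  core <- 9:34                       # frame (5) + edge (3) offset
  expect_equal(out[core, core], src[4:29, 4:29])
  # different noise draws differ only outside the preserved core
  set.seed(1); o1 <- preprocess_image(src)
  set.seed(2); o2 <- preprocess_image(src)
  d <- o1 != o2
  expect_true(all(!d[core, core]))
  expect_true(any(d[-core, ]))
  expect_true(min(out) >= 0 && max(out) <= 255)
  # RGB sources are converted to luminance
  rgb <- array(runif(32 * 32 * 3, 0, 255), c(32L, 32L, 3L))
  expect_equal(dim(preprocess_image(rgb)), c(42L, 42L))
})

test_that("surrogate set is deterministic, balanced and in range", {
  s1 <- surrogate_dataset(12L, seed = 7L)
  s2 <- surrogate_dataset(12L, seed = 7L)
  expect_identical(s1, s2)
  expect_equal(as.vector(table(s1$labels)), rep(12L, 10L))
  expect_equal(dim(s1$images)[1:2], c(21L, 21L))
  expect_true(all(s1$images >= 0 & s1$images <= 255))
})

test_that("shift dialects: circular shifts invert; noise fill keeps content", {
  set.seed(5)
  img <- matrix(runif(21 * 21, 0, 255), 21)
  expect_equal(apply_shift(img, c(0, 0), "circular"), img)
  sh <- c(3L, -2L)
  back <- apply_shift(apply_shift(img, sh, "circular"), -sh, "circular")
  expect_equal(back, img)
  out <- apply_shift(img, c(4L, 4L), "noise")
  expect_equal(out[5:21, 5:21], img[1:17, 1:17])   # translated content
  expect_error(apply_shift(img, c(9L, 0L), max_shift = 8L), "exceeds")
})

test_that("movement image obeys the 20/40/40 pixel split for every size", {
  set.seed(6)
  for (S in c(42L, 21L)) {
    npix <- S^2
    m <- make_movement_image(c(3L, -5L), c(S, S), "congruent", scale = 2)
    expect_equal(sum(m == 0), floor(0.2 * npix))
    rem <- npix - floor(0.2 * npix)
    expect_equal(sum(m == 2 * 3), ceiling(rem / 2))
    expect_equal(sum(m == 2 * -5), rem - ceiling(rem / 2))
    # the value histogram recovers the unordered encoded pair exactly
    expect_setequal(unique(as.vector(m)) / 2, c(0, 3, -5))
  }
  # degenerate equal-component shift collapses to a two-valued image
  m2 <- make_movement_image(c(5L, 5L), c(21L, 21L), "congruent")
  expect_equal(length(unique(as.vector(m2))), 2L)
})

test_that("incongruent movement images are independent of the applied shift", {
  set.seed(44)
  n <- 400L
  shifts <- matrix(sample(-4:4, 2L * n, TRUE), ncol = 2L)
  enc <- t(vapply(seq_len(n), function(i) {
    attr(make_movement_image(shifts[i, ], c(8L, 8L), "incongruent",
                             max_shift = 4L), "pair")
  }, integer(2)))
  # encoded sums are uncorrelated with the true shift sums
  expect_lt(abs(cor(rowSums(enc), rowSums(shifts))), 0.15)
  suppressWarnings(
    p <- chisq.test(table(sign(rowSums(enc)), sign(rowSums(shifts))))$p.value)
  expect_gt(p, 0.01)
})

test_that("quadrant grouping follows the unordered-pair geometry", {
  expect_equal(quadrant_group(c(3, 5)), "Q1")
  expect_equal(quadrant_group(c(-3, -5)), "Q3")
  expect_equal(quadrant_group(c(0, 4)), "cardinal")
  expect_equal(quadrant_group(c(4, 0)), "cardinal")
  expect_equal(quadrant_group(c(-2, 7)), quadrant_group(c(7, -2)))
  expect_equal(quadrant_group(c(-2, 7)), "Q2or4")
})

test_that("direction-information bounds: 75% four-way, 100% three-way", {
  expect_equal(saccade_direction_bound(8L, "four"), 0.75)
  expect_equal(saccade_direction_bound(8L, "three"), 1)
  expect_equal(saccade_direction_bound(4L, "four"), 0.75)
  expect_equal(saccade_direction_bound(4L, "three"), 1)
})

test_that("amplitude-range estimate is sane and deterministic", {
  net <- tiny_feature_net()
  s <- surrogate_dataset(10L, seed = 3L)
  tr <- generate_saccadic_trials(s, 4L, "congruent", scale = 2, seed = 4L)
  expect_equal(estimate_amplitude_range(net, tr, layer = 1L), range(tr$x))
  r1 <- estimate_amplitude_range(net, tr, layer = 2L, seed = 9L)
  r2 <- estimate_amplitude_range(net, tr, layer = 2L, seed = 9L)
  expect_identical(r1, r2)
  expect_lte(r1[1], r1[2])
  expect_error(estimate_amplitude_range(net, tr, layer = 7L), "layer")
})

test_that("gratings have six equally spaced orientations and mid luminance", {
  set.seed(12)
  g1 <- make_grating(3L)
  g2 <- make_grating(3L)
  expect_false(isTRUE(all.equal(g1, g2)))          # random phase and frame
  expect_equal(attr(g1, "orientation_index"), attr(g2, "orientation_index"))
  thetas <- vapply(1:6, function(k) attr(make_grating(k), "theta"), 0)
  expect_equal(diff(thetas), rep(pi / 6, 5))
  # phase-averaged mean luminance is mid-range
  mu <- mean(vapply(1:100, function(i) mean(make_grating(1L)), 0))
  expect_equal(mu, 127.5, tolerance = 0.03 * 127.5)
})

test_that("trial streams share visuals when only the condition differs", {
  base <- surrogate_dataset(10L, seed = 3L)
  vis <- generate_saccadic_trials(base, 4L, "none", seed = 6L)
  co <- add_movement_images(vis, "congruent", scale = 2, max_shift = 4L,
                            seed = 7L)
  inc <- add_movement_images(vis, "incongruent", scale = 2, max_shift = 4L,
                             seed = 8L)
  expect_identical(co$x, inc$x)
  expect_identical(co$shifts, inc$shifts)
  expect_false(isTRUE(all.equal(co$movement, inc$movement)))
  # congruent movement encodes the true shifts
  for (j in c(1L, 5L)) {
    expect_setequal(setdiff(unique(as.vector(co$movement[, , j])), 0) / 2,
                    setdiff(unique(co$shifts[j, ]), 0))
  }
})
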