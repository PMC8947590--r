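# Bar-localization stimulus geometry, the movement-amplitude code, the
# composition rule, and the enumerated ideal-observer oracle.

test_that("bar geometry: 7x20 bar, degenerate band placements", {
  img <- make_bar_image(2L, 0L)
  expect_equal(dim(img), c(28L, 28L))
  expect_equal(sum(img > 0), 7L * 20L)
  expect_equal(attr(img, "band"), 3L)           # central band, no movement
  # s1(0) is pixel-identical to s2(+2); s1(-1) to s2(+1)
  expect_equal(unclass(make_bar_image(1L, 0L)),
               unclass(make_bar_image(2L, 2L)), ignore_attr = TRUE)
  expect_equal(unclass(make_bar_image(1L, -1L)),
               unclass(make_bar_image(2L, 1L)), ignore_attr = TRUE)
  # every admissible pair keeps the full bar inside the frame
  pairs <- admissible_pairs("wrap")
  for (i in seq_len(nrow(pairs))) {
    expect_equal(sum(make_bar_image(pairs$location[i], pairs$shift[i]) > 0),
                 140L)
  }
})

test_that("restricted edge mode rejects out-of-range shifts with a message", {
  expect_error(make_bar_image(1L, 2L, edge_mode = "restrict"),
               "inadmissible")
  expect_error(make_bar_image(3L, -1L, edge_mode = "restrict"),
               "band")
  expect_silent(make_bar_image(1L, -2L, edge_mode = "restrict"))
  expect_equal(nrow(admissible_pairs("restrict")), 11L)
  expect_equal(nrow(admissible_pairs("wrap")), 15L)
})

test_that("movement amplitude code: constant vs signed injective modulation", {
  amps_const <- vapply(-2:2, function(s) {
    attr(make_movement_pattern(s, "constant"), "amplitude")
  }, 0)
  expect_equal(amps_const, rep(0.5, 5))
  amps_mod <- vapply(-2:2, function(s) {
    attr(make_movement_pattern(s, "modulated"), "amplitude")
  }, 0)
  expect_equal(length(unique(amps_mod)), 5L)          # injective
  expect_equal(amps_mod, c(0.1, 0.3, 0.5, 0.7, 0.9))
  # antisymmetric around the 0.5 reference
  for (s in 1:2) {
    expect_equal(amps_mod[3 + s] - 0.5, -(amps_mod[3 - s] - 0.5))
  }
  # pattern geometry: 21 x 20 rectangle, 12 columns shared with the bars
  m <- make_movement_pattern(0L, "constant")
  expect_equal(sum(m != 0), 21L * 20L)
  bar_cols <- which(colSums(make_bar_image(2L, 0L)) > 0)
  mov_cols <- which(colSums(m != 0) > 0)
  expect_equal(length(intersect(bar_cols, mov_cols)), 12L)
})

test_that("composition clips overlapping pixels to the larger signal", {
  v <- matrix(0, 28, 28); v[5, 5] <- 0.8; v[6, 6] <- 0.3
  m <- matrix(0, 28, 28); m[5, 5] <- 0.5; m[7, 7] <- 0.4
  comp <- compose_stimuli(v, m)
  expect_equal(comp[5, 5], 0.8)     # overlap: max wins
  expect_equal(comp[6, 6], 0.3)     # visual only
  expect_equal(comp[7, 7], 0.4)     # movement only
  expect_equal(unclass(compose_stimuli(v, m)), unclass(compose_stimuli(m, v)),
               ignore_attr = TRUE)
  zero <- matrix(0, 28, 28)
  expect_equal(unclass(compose_stimuli(zero, m)), m, ignore_attr = TRUE)
  expect_error(compose_stimuli(v, matrix(0, 10, 10)), "shape mismatch")
})

test_that("dataset generation is deterministic, balanced and 50/50 split", {
  d1 <- generate_fixational_dataset(300L, "constant", seed = 5L)
  d2 <- generate_fixational_dataset(300L, "constant", seed = 5L)
  expect_identical(d1, d2)
  expect_equal(dim(d1$train$x)[3], 150L)
  expect_equal(dim(d1$test$x)[3], 150L)
  combo <- table(c(d1$train$y, d1$test$y), c(d1$train$shifts, d1$test$shifts))
  expect_equal(length(unique(as.vector(combo))), 1L)   # exactly balanced
})

test_that("constant mode contains identical images with different labels", {
  ds <- generate_fixational_dataset(150L, "constant", seed = 8L)
  imgs <- matrix(ds$train$x, ncol = dim(ds$train$x)[3])
  key <- apply(imgs, 2L, function(v) paste(which(v != 0), collapse = ","))
  dup <- split(ds$train$y, key)
  expect_true(any(vapply(dup, function(l) length(unique(l)) > 1L, TRUE)))
})

test_that("modulated mode maps every (location, shift) to a distinct image", {
  pairs <- admissible_pairs("wrap")
  imgs <- lapply(seq_len(nrow(pairs)), function(i) {
    compose_stimuli(make_bar_image(pairs$location[i], pairs$shift[i]),
                    make_movement_pattern(pairs$shift[i], "modulated"))
  })
  keys <- vapply(imgs, function(m) paste(round(m, 10), collapse = ","), "")
  expect_equal(length(unique(keys)), nrow(pairs))
})

test_that("enumerated Bayes accuracy matches a brute-force image-space oracle", {
  # independent oracle: enumerate composite images directly, group identical
  # ones, and score the best deterministic classifier under pair weighting
  brute <- function(mode, edge_mode) {
    pairs <- admissible_pairs(edge_mode)
    key <- vapply(seq_len(nrow(pairs)), function(i) {
      img <- compose_stimuli(
        make_bar_image(pairs$location[i], pairs$shift[i], edge_mode = edge_mode),
        make_movement_pattern(pairs$shift[i], mode))
      paste(round(img, 10), collapse = ",")
    }, "")
    sum(vapply(split(pairs$location, key), function(labs) {
      max(table(labs)) / nrow(pairs)
    }, 0))
  }
  expect_equal(fixational_bayes_accuracy("constant", "wrap"), 1 / 3)
  expect_equal(brute("constant", "wrap"), 1 / 3)
  expect_equal(fixational_bayes_accuracy("modulated", "wrap"), 1)
  expect_equal(brute("modulated", "wrap"), 1)
  expect_equal(fixational_bayes_accuracy("constant", "restrict"), 5 / 11)
  expect_equal(brute("constant", "restrict"), 5 / 11)
  expect_equal(fixational_bayes_accuracy("constant", "restrict", "location"),
               5 / 9)
})

test_that("focal spot probe is small, high-contrast and unlike the patterns", {
  spot <- make_focal_spot()
  expect_equal(sum(spot != 0), 9L)
  expect_equal(max(spot), 1)
  expect_error(make_focal_spot(center = c(1L, 1L)), "outside")
  ps <- make_pattern_set(5L, seed = 2L)
  tpl <- cdvis:::pattern_templates()
  cos_sim <- vapply(tpl, function(t) {
    sum(spot * t) / sqrt(sum(spot^2) * sum(t^2))
  }, 0)
  expect_true(all(cos_sim < 0.2))
})

test_that("pattern set carries ten contrast levels and pixel noise", {
  ps <- make_pattern_set(30L, seed = 4L)
  expect_equal(sort(unique(ps$contrast_level)), 1:10)
  expect_equal(as.vector(table(ps$labels)), rep(30L, 6L))
  expect_identical(ps$is_visual, ps$labels <= 4L)
  # noise: background pixels are nonzero
  bg <- ps$images[1, 28, ]                 # corner pixel outside all patterns
  expect_true(all(bg >= 0) && any(bg > 0))
  expect_true(all(ps$images <= 1.05 + 1e-12))
})
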