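# Single-channel characterization: saccadic response modulation
# (suppression / enhancement / gain fields), modulation variability across
# layers, activation-maximization receptive fields, and grating tuning.

#' Central luminance-square probe
#'
#' A 5x5 px square centred in the frame, at the median of the per-image mean
#' amplitudes of the training set, on a zero background. Used to measure
#' visually evoked responses with and without concurrent movement inputs.
#'
#' @param train_images training images (H x W x N).
#' @param size probe side in px (odd).
#' @return H x W probe matrix with attribute `value`.
#' @export
probe_stimulus <- function(train_images, size = 5L) {
  stopifnot(size %% 2L == 1L)
  d <- dim(train_images)
  v <- stats::median(colMeans(matrix(train_images, ncol = d[3])))
  img <- matrix(0, d[1], d[2])
  c0 <- (d[1:2] + 1L) %/% 2L
  h <- size %/% 2L
  img[(c0[1] - h):(c0[1] + h), (c0[2] - h):(c0[2] + h)] <- v
  attr(img, "value") <- v
  img
}

#' Units covering an input region, per layer
#'
#' Propagates an input-pixel region through the stride/pooling geometry:
#' each 3x3 same convolution widens the covering set by one unit on each
#' side, each 2x2 pooling halves the coordinates. Returns, for every conv
#' layer, the (post-ReLU) unit rows/columns whose receptive field covers
#' the region.
#'
#' @param spec a [cnn_spec()].
#' @param rows,cols input region (integer ranges).
#' @return list per layer with `rows`, `cols`.
#' @export
probe_units <- function(spec, rows, cols) {
  r <- range(rows); cc <- range(cols)
  out <- vector("list", spec$n_conv)
  for (k in seq_len(spec$n_conv)) {
    sz <- spec$sizes[[k]]
    r <- c(max(1L, r[1] - 1L), min(sz[1], r[2] + 1L))     # conv widens
    cc <- c(max(1L, cc[1] - 1L), min(sz[2], cc[2] + 1L))
    out[[k]] <- list(rows = r[1]:r[2], cols = cc[1]:cc[2])
    r <- c((r[1] + 1L) %/% 2L, pmin(spec$sizes[[k + 1L]][1], (r[2] + 1L) %/% 2L))
    cc <- c((cc[1] + 1L) %/% 2L, pmin(spec$sizes[[k + 1L]][2], (cc[2] + 1L) %/% 2L))
  }
  out
}

window_response <- function(tensor, rows, cols) {
  sub <- tensor[rows, cols, , , drop = FALSE]
  d <- dim(sub)
  matrix(colMeans(matrix(sub, nrow = d[1] * d[2])), nrow = d[3])
}

#' Movement pool with equal-occupancy amplitude bins
#'
#' Draws saccadic shift vectors and retains `per_bin` per amplitude group,
#' the groups being linearly spaced in vector length from zero to the
#' maximum.
#'
#' @param shift_range saccadic range.
#' @param n_bins number of amplitude groups.
#' @param per_bin movements per group.
#' @param seed integer seed.
#' @return list with `shifts` (M x 2), `bins` (M), `edges`.
#' @export
movement_pool <- function(shift_range = 4L, n_bins = 6L, per_bin = 20L,
                          seed = 1L) {
  local_rng(seed)
  lmax <- sqrt(2) * shift_range
  edges <- seq(0, lmax, length.out = n_bins + 1L)
  got <- vector("list", n_bins)
  tries <- 0L
  while (any(vapply(got, length, 0L) < per_bin) && tries < 20000L) {
    s <- sample(seq(-shift_range, shift_range), 2L, replace = TRUE)
    l <- sqrt(sum(s^2))
    b <- min(n_bins, findInterval(l, edges, rightmost.closed = TRUE))
    b <- max(1L, b)
    if (length(got[[b]]) < per_bin) got[[b]] <- c(got[[b]], list(s))
    tries <- tries + 1L
  }
  if (any(vapply(got, length, 0L) < per_bin)) {
    stop("could not fill all amplitude bins with ", per_bin, " movements")
  }
  shifts <- do.call(rbind, unlist(got, recursive = FALSE))
  list(shifts = shifts, bins = rep(seq_len(n_bins), each = per_bin),
       edges = edges)
}

classify_modulation <- function(bin_means) {
  nb <- ncol(bin_means)
  apply(bin_means, 1L, function(d) {
    mad <- mean(abs(d))
    if (mad == 0) return("mixed")
    slope <- stats::coef(stats::lm(d ~ seq_len(nb)))[2]
    flat <- abs(slope) < 0.1 * mad
    if (flat && all(d < 0)) return("suppressed")
    if (flat && all(d > 0)) return("enhanced")
    rho <- suppressWarnings(
      stats::cor(seq_len(nb), abs(d), method = "spearman"))
    if (!is.na(rho) && abs(rho) >= 0.8) return("gain")
    "mixed"
  })
}

#' Saccadic modulation of probe responses
#'
#' Measures, per channel and layer, the response change to the luminance
#' probe when a movement input is present versus absent:
#' delta = mean response (visual + movement) - response (visual only),
#' where the response is the activity averaged across the units covering
#' the probe square. Movements are grouped into amplitude bins (equal
#' occupancy, linearly spaced in vector length); channels are classified as
#' suppressed or enhanced (sign-consistent and flat across bins), gain
#' (|delta| monotone with amplitude, Spearman |rho| >= 0.8), or mixed.
#'
#' @param net a trained `cnn_net` with feature-image movement input.
#' @param probe probe image from [probe_stimulus()].
#' @param pool movement pool from [movement_pool()].
#' @param scale movement amplitude scale.
#' @return list per layer: `delta` (channels x movements), `bins`,
#'   `bin_means` (channels x n_bins), `class` (per channel), plus
#'   `pool`.
#' @export
saccadic_modulation <- function(net, probe, pool, scale = 1) {
  spec <- net$spec
  d <- dim(probe)
  M <- nrow(pool$shifts)
  movement <- array(0, c(d[1], d[2], M))
  for (j in seq_len(M)) {
    movement[, , j] <- make_movement_image(pool$shifts[j, ], d, "congruent",
                                           scale = scale,
                                           max_shift = max(abs(pool$shifts)))
  }
  x_rep <- array(rep(probe, M), c(d[1], d[2], M))
  zeros_m <- array(0, c(d[1], d[2], 1L))
  c0 <- (d + 1L) %/% 2L
  win <- probe_units(spec, (c0[1] - 2L):(c0[1] + 2L), (c0[2] - 2L):(c0[2] + 2L))
  nb <- max(pool$bins)
  out <- vector("list", spec$n_conv)
  for (l in seq_len(spec$n_conv)) {
    base <- window_response(
      net_forward(net, array(probe, c(d, 1L)), zeros_m, keep = "acts")$acts[[paste0("L", l)]],
      win[[l]]$rows, win[[l]]$cols)[, 1L]
    withm <- window_response(
      net_forward(net, x_rep, movement, keep = "acts")$acts[[paste0("L", l)]],
      win[[l]]$rows, win[[l]]$cols)
    delta <- withm - base
    bin_means <- vapply(seq_len(nb), function(b) {
      rowMeans(delta[, pool$bins == b, drop = FALSE])
    }, numeric(nrow(delta)))
    out[[l]] <- list(layer = l, delta = delta, bins = pool$bins,
                     bin_means = bin_means,
                     class = classify_modulation(bin_means))
  }
  structure(list(layers = out, pool = pool), class = "saccadic_modulation")
}

#' Across-channel variability of saccadic modulation
#'
#' For each movement example, the standard deviation of the response change
#' across channels; per amplitude bin, the width of the 5th-95th percentile
#' interval of those s.d. values.
#'
#' @param mod a [saccadic_modulation()] result.
#' @return data.frame with `layer`, `bin`, `sd_mean`, `ci_width`; attribute
#'   `max_ci` gives the per-layer maximum CI width.
#' @export
modulation_variability <- function(mod) {
  rows <- list()
  for (lay in mod$layers) {
    sdm <- apply(lay$delta, 2L, stats::sd)
    for (b in sort(unique(lay$bins))) {
      v <- sdm[lay$bins == b]
      q <- stats::quantile(v, c(0.05, 0.95), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = lay$layer, bin = b, sd_mean = mean(v), ci_width = q[2] - q[1])
    }
  }
  df <- do.call(rbind, rows)
  attr(df, "max_ci") <- vapply(split(df$ci_width, df$layer), max, 0)
  df
}

bn_backward_eval <- function(dy, bf, gamma) {
  d <- dim(dy)
  HW <- d[1] * d[2]
  dym <- matrix(dy, nrow = HW)
  array(dym * chan_expand(gamma * bf$inv, HW), d)
}

# Gradient of a channel's mean activation (post-ReLU, layer `layer`) with
# respect to the visual input, in inference mode.
input_gradient <- function(net, x, layer, channel) {
  spec <- net$spec
  n <- dim(x)[4]
  mv <- if (spec$movement_mode == "feature_image") {
    array(0, c(spec$sizes[[spec$injection_layer]], 1L, n))
  } else if (spec$movement_mode == "global_scalar") {
    numeric(n)
  } else NULL
  fw <- net_forward(net, x, mv, train = FALSE, keep = "cache")
  cache <- fw$cache
  p <- net$params
  dx <- NULL
  for (k in rev(seq_len(layer))) {
    blk <- cache[[paste0("blk", k)]]
    if (k == layer) {
      da <- array(0, dim(blk$zb))
      da[, , channel, ] <- 1 / prod(dim(blk$zb)[1:2])
    } else {
      da <- pool_backward(dx, blk$pf)
    }
    dzb <- relu_backward(da, blk$zb)
    if (spec$bn_layer == k) {
      dzb <- bn_backward_eval(dzb, cache[[paste0("bn", k)]], p$bn$gamma)
    }
    cb <- conv_backward(blk$x_in, dzb, p[[paste0("conv", k)]]$w)
    dx <- cb$dx
    if (spec$movement_mode == "feature_image" && spec$injection_layer == k) {
      dx <- dx[, , seq_len(dim(blk$x_in)[3] - 1L), , drop = FALSE]
    }
  }
  dx
}

bilinear_resize <- function(img, H2, W2) {
  H <- nrow(img); W <- ncol(img)
  ri <- seq(1, H, length.out = H2)
  ci <- seq(1, W, length.out = W2)
  r0 <- pmin(floor(ri), H - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), W - 1L); fc <- ci - c0
  a <- img[r0, c0] * outer(1 - fr, 1 - fc) +
    img[r0 + 1L, c0] * outer(fr, 1 - fc) +
    img[r0, c0 + 1L] * outer(1 - fr, fc) +
    img[r0 + 1L, c0 + 1L] * outer(fr, fc)
  a
}

#' Activation-maximization receptive field
#'
#' Gradient-ascent image optimization of a channel's mean activation
#' through the visual path only (movement inputs held at zero), with an
#' image pyramid: the image is optimized at coarse scale, upsampled, and
#' refined (2 pyramid levels, a fixed number of ascent iterations each).
#' Deterministic under `seed`. Channels with an identically zero gradient
#' at initialization are flagged dead.
#'
#' @param net a trained `cnn_net`.
#' @param layer,channel target channel.
#' @param n_iter ascent iterations per pyramid level.
#' @param pyramid_levels number of pyramid levels.
#' @param step ascent step size as a fraction of the input range.
#' @param input_range numeric c(lo, hi) clip range of the optimized image.
#' @param seed integer seed.
#' @return optimized image matrix with attributes `activation` (final mean
#'   activation), `activation_start`, and `dead` (logical).
#' @export
maximize_activation <- function(net, layer, channel, n_iter = 10L,
                                pyramid_levels = 2L, step = 0.1,
                                input_range = c(0, 1), seed = 1L) {
  local_rng(seed)
  sz <- net$spec$input_size
  mid <- mean(input_range)
  amp <- diff(input_range)
  act_of <- function(img) {
    a <- net_forward(net, array(img, c(dim(img), 1L, 1L)),
                     movement_placeholder(net, 1L), keep = "acts"
    )$acts[[paste0("L", layer)]]
    mean(a[, , channel, 1L])
  }
  cur <- sz %/% (2L^(pyramid_levels - 1L))
  img <- matrix(stats::rnorm(prod(cur), mid, 0.05 * amp), cur[1], cur[2])
  dead <- FALSE
  start_act <- NULL
  for (lev in seq_len(pyramid_levels)) {
    if (lev > 1L) {
      tgt <- sz %/% (2L^(pyramid_levels - lev))
      img <- bilinear_resize(img, tgt[1], tgt[2])
    }
    for (i in seq_len(n_iter)) {
      xa <- array(img, c(dim(img), 1L, 1L))
      # optimize at the native size only on the final level; coarse levels
      # are optimized against an upsampled rendering
      xr <- if (all(dim(img) == sz)) xa else
        array(bilinear_resize(img, sz[1], sz[2]), c(sz, 1L, 1L))
      if (is.null(start_act)) start_act <- act_of(xr[, , 1L, 1L])
      g <- input_gradient(net, xr, layer, channel)[, , 1L, 1L]
      if (all(g == 0)) { dead <- TRUE; break }
      if (!all(dim(img) == sz)) g <- bilinear_resize(g, nrow(img), ncol(img))
      img <- img + step * amp * g / max(abs(g))
      img <- pmin(pmax(img, input_range[1]), input_range[2])
    }
  }
  if (!all(dim(img) == sz)) img <- bilinear_resize(img, sz[1], sz[2])
  img <- pmin(pmax(img, input_range[1]), input_range[2])
  structure(img, activation = act_of(img), activation_start = start_act,
            dead = dead)
}

movement_placeholder <- function(net, n) {
  spec <- net$spec
  switch(spec$movement_mode,
         none = NULL,
         global_scalar = numeric(n),
         feature_image = array(0, c(spec$sizes[[spec$injection_layer]], 1L, n)))
}

#' Orientation tuning and population decoding of gratings
#'
#' Per-channel tuning curves over the six orientations (mean and 5-95
#' percentile interval of the channel-mean response), the proportion of
#' tuned channels (maximum tuning-curve amplitude above `threshold`), and a
#' per-layer population readout: PCA to 3 components and 5-fold
#' cross-validated linear discriminant classification of the orientation.
#'
#' @param net a trained `cnn_net`.
#' @param gratings list with `images` (H x W x N) and `orientation` (1..6).
#' @param threshold tuned-channel amplitude threshold.
#' @param folds cross-validation folds.
#' @param seed integer seed.
#' @return list per layer: `tuning` (data.frame channel x orientation with
#'   mean, lo, hi), `prop_tuned`, `lda_accuracy`.
#' @export
orientation_analysis <- function(net, gratings, threshold = 0.1, folds = 5L,
                                 seed = 1L) {
  ori <- gratings$orientation
  out <- vector("list", net$spec$n_conv)
  for (l in seq_len(net$spec$n_conv)) {
    cm <- layer_activations(net, gratings$images,
                            movement_placeholder(net, length(ori)),
                            l)$channel_mean
    rows <- list()
    for (ch in seq_len(nrow(cm))) {
      for (o in sort(unique(ori))) {
        v <- cm[ch, ori == o]
        q <- stats::quantile(v, c(0.05, 0.95), names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ch, orientation = o, mean = mean(v), lo = q[1], hi = q[2])
      }
    }
    tuning <- do.call(rbind, rows)
    peak <- vapply(split(tuning$mean, tuning$channel), max, 0)
    lda_acc <- embed_and_decode(cm, ori, recipe = "pca", n_components = 3L,
                                readout = "lda", folds = folds,
                                seed = seed)$accuracy
    out[[l]] <- list(layer = l, tuning = tuning,
                     prop_tuned = mean(peak > threshold),
                     lda_accuracy = lda_acc)
  }
  out
}

#' Probability of reporting a visual input
#'
#' For a network trained to classify both visual and movement activity
#' patterns, the probability mass assigned to the visual channels: the sum
#' of output probabilities over the visual classes for each test image.
#'
#' @param net a trained `cnn_net`.
#' @param images input images (H x W x N).
#' @param visual_classes indices of the visual output channels.
#' @return numeric vector of visual-report probabilities.
#' @export
visual_report_probability <- function(net, images, visual_classes = 1:4) {
  if (length(dim(images)) == 2L) images <- array(images, c(dim(images), 1L))
  pr <- net_forward(net, images, movement_placeholder(net, dim(images)[3]))$probs
  colSums(pr[visual_classes, , drop = FALSE])
}
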