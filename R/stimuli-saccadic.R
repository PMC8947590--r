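# Saccadic-shift stimuli: framed natural-image surrogates, movement images
# encoding the (unordered) shift scalars, and grating probes.
#
# Visual amplitudes are in [0, 255]; movement images are the only inputs
# that may take negative values (scaled, signed shift scalars).

#' Convert a source image to a framed, noise-edged grayscale image
#'
#' The source (e.g. a 32x32 natural image, RGB or grayscale) is converted to
#' luminance, its outer `edge`-px border is replaced by i.i.d. uniform noise
#' in \[0, 255\], and a noise frame of width `frame` is added on every side.
#' Saccadic shifts displace the content relative to this noisy frame, so the
#' frame introduces an extra axis of variability the network must factor out.
#'
#' @param img source matrix (H x W) or RGB array (H x W x 3), values 0..255.
#' @param frame frame width in px (5 for the 32->42 px dialect).
#' @param edge width of the source border replaced by noise.
#' @return (H + 2 frame) x (W + 2 frame) matrix in \[0, 255\].
#' @export
preprocess_image <- function(img, frame = 5L, edge = 3L) {
  d <- dim(img)
  if (length(d) == 3L) {
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    d <- dim(img)
  }
  H <- d[1]; W <- d[2]
  out <- matrix(stats::runif((H + 2L * frame) * (W + 2L * frame), 0, 255),
                H + 2L * frame)
  inner <- img
  if (edge > 0L) {
    noise <- matrix(stats::runif(H * W, 0, 255), H)
    keep <- matrix(FALSE, H, W)
    keep[(edge + 1L):(H - edge), (edge + 1L):(W - edge)] <- TRUE
    inner <- ifelse(keep, img, noise)
  }
  out[frame + seq_len(H), frame + seq_len(W)] <- inner
  out
}

surrogate_shape_mask <- function(class, u, v) {
  r <- sqrt(u^2 + v^2)
  switch(class,
    abs(v) < 0.25,                                        # horizontal bar
    abs(u) < 0.25,                                        # vertical bar
    abs(u - v) < 0.35,                                    # diagonal bar
    abs(u) < 0.2 | abs(v) < 0.2,                          # cross
    r > 0.5 & r < 0.85,                                   # ring
    r < 0.45,                                             # disk
    (u > -0.6 & u < -0.2 & abs(v) < 0.8) |
      (v > 0.2 & v < 0.6 & abs(u) < 0.8),                 # L shape
    sin(3 * pi * u) * sin(3 * pi * v) > 0,                # checkerboard
    sqrt((u + 0.45)^2 + (v + 0.45)^2) < 0.3 |
      sqrt((u - 0.45)^2 + (v - 0.45)^2) < 0.3,            # two dots
    abs(u - v) < 0.25 | abs(u + v) < 0.25                 # X shape
  )
}

#' Synthetic surrogate image set
#'
#' A stand-in for a 10-class natural-image database so that every pipeline
#' stage is testable without any download: each class is a fixed procedural
#' shape (bars, cross, ring, disk, L, checkerboard, dots, X) rendered with
#' randomized position jitter (about 2 px), scale (about 30 percent),
#' in-plane rotation jitter, a wide per-image contrast range and strong
#' additive pixel noise, then passed through [preprocess_image()]. The
#' randomization is deliberately aggressive so that held-out classification
#' by the small CNN lands in the moderately-hard regime of a natural-image
#' benchmark rather than at ceiling. This is a synthetic surrogate, not
#' natural imagery.
#'
#' @param n_per_class images per class.
#' @param n_classes number of classes (2..10).
#' @param source_size side of the pre-framing source image in px.
#' @param frame,edge passed to [preprocess_image()]; the defaults give
#'   21x21 framed images from a 15x15 source.
#' @param seed integer seed.
#' @return list with `images` (S x S x N, values 0..255), `labels` (1..n),
#'   `size` S.
#' @export
surrogate_dataset <- function(n_per_class = 100L, n_classes = 10L,
                              source_size = 15L, frame = 3L, edge = 1L,
                              seed = 1L) {
  stopifnot(n_classes >= 2L, n_classes <= 10L)
  local_rng(seed)
  S <- source_size + 2L * frame
  n <- n_classes * n_per_class
  labels <- rep(seq_len(n_classes), each = n_per_class)
  images <- array(0, c(S, S, n))
  ax <- seq(-1, 1, length.out = source_size)
  for (j in seq_len(n)) {
    jit <- stats::runif(2, -2, 2) * (2 / source_size)
    scl <- stats::runif(1, 0.7, 1.3)
    rot <- stats::runif(1, -0.5, 0.5)
    u0 <- matrix(rep(ax, source_size), source_size) - jit[1]
    v0 <- matrix(rep(ax, each = source_size), source_size) - jit[2]
    u <- (cos(rot) * u0 + sin(rot) * v0) / scl
    v <- (-sin(rot) * u0 + cos(rot) * v0) / scl
    fg <- 255 * stats::runif(1, 0.2, 0.9)
    src <- surrogate_shape_mask(labels[j], u, v) * fg +
      matrix(stats::rnorm(source_size^2, 0, 110), source_size)
    src <- pmin(pmax(src, 0), 255)
    images[, , j] <- preprocess_image(src, frame = frame, edge = edge)
  }
  ord <- sample.int(n)
  list(images = images[, , ord, drop = FALSE], labels = labels[ord], size = S)
}

#' Apply a saccadic (x, y) shift to an image
#'
#' `shift = c(sx, sy)` moves the content `sx` px rightward and `sy` px
#' downward. Two dialects are provided: `"noise"` (default) translates the
#' content and fills the vacated strip with uniform noise in
#' `noise_range`, preserving the spatial coherence of the unwrapped content;
#' `"circular"` wraps pixels around the frame.
#'
#' @param img image matrix.
#' @param shift integer length-2 (sx, sy).
#' @param dialect `"noise"` or `"circular"`.
#' @param max_shift admissible shift magnitude.
#' @param noise_range fill range for the noise dialect.
#' @return shifted image matrix.
#' @export
apply_shift <- function(img, shift, dialect = c("noise", "circular"),
                        max_shift = 8L, noise_range = c(0, 255)) {
  dialect <- match.arg(dialect)
  sx <- as.integer(shift[1]); sy <- as.integer(shift[2])
  if (abs(sx) > max_shift || abs(sy) > max_shift) {
    stop("shift (", sx, ",", sy, ") exceeds the configured range [-",
         max_shift, ",+", max_shift, "]")
  }
  H <- nrow(img); W <- ncol(img)
  rows <- seq_len(H) - sy
  cols <- seq_len(W) - sx
  if (dialect == "circular") {
    out <- img[(rows - 1L) %% H + 1L, (cols - 1L) %% W + 1L]
  } else {
    out <- matrix(stats::runif(H * W, noise_range[1], noise_range[2]), H)
    rok <- rows >= 1L & rows <= H
    cok <- cols >= 1L & cols <= W
    out[rok, cok] <- img[rows[rok], cols[cok]]
  }
  out
}

split_2040 <- function(npix) {
  nz <- floor(0.2 * npix)
  rem <- npix - nz
  nx <- ceiling(rem / 2)
  c(zero = nz, x = nx, y = rem - nx)
}

#' Movement image encoding the shift scalars
#'
#' A spatially unstructured image whose pixels take exactly three values:
#' 20 percent are zero, 40 percent carry the scaled first shift scalar and
#' 40 percent the scaled second, at random pixel indices (counts follow the
#' deterministic rounding rule: zeros = floor(0.2 N), the remainder split
#' evenly with any extra pixel to the first-scalar set). Pixel positions
#' carry no information, and neither scalar is marked as horizontal or
#' vertical: only the unordered pair (hence the Cartesian quadrant, up to
#' the 2nd/4th ambiguity) is recoverable. In the congruent condition the
#' scalars are the shift actually applied to the paired visual image; in
#' the incongruent condition they are an independent random pair within the
#' saccadic range.
#'
#' @param shift integer (sx, sy) applied to the visual image.
#' @param shape output (rows, cols).
#' @param condition `"congruent"` or `"incongruent"`.
#' @param scale amplitude scale: pixel values are `scale * s`.
#' @param max_shift saccadic range for incongruent draws.
#' @return matrix with attributes `pair` (the encoded scalars) and
#'   `condition`.
#' @export
make_movement_image <- function(shift, shape, condition = c("congruent",
                                                            "incongruent"),
                                scale = 1, max_shift = 8L) {
  condition <- match.arg(condition)
  stopifnot(scale > 0)
  enc <- if (condition == "congruent") {
    as.integer(shift)
  } else {
    as.integer(sample(seq(-max_shift, max_shift), 2L, replace = TRUE))
  }
  npix <- prod(shape)
  cnt <- split_2040(npix)
  vals <- c(rep(0, cnt["zero"]), rep(scale * enc[1], cnt["x"]),
            rep(scale * enc[2], cnt["y"]))
  out <- matrix(vals[sample.int(npix)], shape[1], shape[2])
  attr(out, "pair") <- enc
  attr(out, "condition") <- condition
  out
}

#' Amplitude range of the image representation at a layer
#'
#' Runs a one-epoch initialization training pass (so that weights are in
#' their operating regime) and computes the minimum and maximum activation
#' amplitude of the representation a movement input would be injected into:
#' the raw images for layer 1, the pooled output of block `layer - 1`
#' otherwise. The range is used to set the movement scale to a fraction
#' (25 percent by default) of the image amplitudes at the injection layer.
#'
#' @param net a `cnn_net`.
#' @param data training data list with `x`, `y` (see [train_network()]).
#' @param layer injection layer.
#' @param init_epochs epochs of the initialization run.
#' @param seed integer seed for the initialization run.
#' @return numeric c(min, max).
#' @export
estimate_amplitude_range <- function(net, data, layer = 1L, init_epochs = 1L,
                                     seed = 1L) {
  spec <- net$spec
  if (layer < 1L || layer > spec$n_conv) stop("layer must be in 1..", spec$n_conv)
  if (layer == 1L) return(range(data$x))
  if (init_epochs > 0L) {
    cfg <- train_config(max_epochs = init_epochs, seed = seed,
                        validation_frequency = Inf)
    net <- train_network(net, list(train = data, test = data), cfg)$net
  }
  fw <- net_forward(net, data$x, data$movement, keep = "acts")
  a <- pool_forward(fw$acts[[paste0("L", layer - 1L)]])$y
  range(a)
}

#' Movement-image amplitude scale for an injection layer
#'
#' @param amp_range c(min, max) image amplitudes at the layer, e.g. from
#'   [estimate_amplitude_range()].
#' @param max_shift saccadic range.
#' @param fraction movement amplitude as a fraction of the image amplitude
#'   (0.25, with 0.10 and 0.05 as the smaller-amplitude variants).
#' @return scalar scale such that `scale * max_shift = fraction * max |amp|`.
#' @export
movement_scale <- function(amp_range, max_shift = 8L, fraction = 0.25) {
  fraction * max(abs(amp_range)) / max_shift
}

#' Saccade-direction group of a shift vector
#'
#' Groups follow the Cartesian quadrants, with the 2nd and 4th quadrants
#' merged because the movement image encodes only the unordered scalar
#' pair: `"cardinal"` for shifts along an axis, `"Q1"` (both positive),
#' `"Q3"` (both negative), `"Q2or4"` (opposite signs).
#'
#' @param shift integer (sx, sy).
#' @return character group label.
#' @export
quadrant_group <- function(shift) {
  sx <- shift[1]; sy <- shift[2]
  if (sx == 0 || sy == 0) return("cardinal")
  if (sx > 0 && sy > 0) return("Q1")
  if (sx < 0 && sy < 0) return("Q3")
  "Q2or4"
}

#' Ideal-observer bound for direction decoding from movement images
#'
#' Exhaustively enumerates shift pairs with both components nonzero,
#' sampled uniformly over the four open quadrants. The observable is the
#' unordered scalar pair (all a movement image reveals). The four-quadrant
#' Bayes accuracy is 3/4 (1st and 3rd quadrants are certain; the 2nd and
#' 4th collapse onto the same observable); merging the 2nd and 4th quadrant
#' into one group makes the three-group problem fully decodable.
#'
#' @param max_shift saccadic range.
#' @param groups `"four"` or `"three"`.
#' @return Bayes-optimal accuracy in \[0, 1\].
#' @export
saccade_direction_bound <- function(max_shift = 8L, groups = c("four", "three")) {
  groups <- match.arg(groups)
  s <- setdiff(seq(-max_shift, max_shift), 0L)
  g <- expand.grid(sx = s, sy = s)
  quad <- ifelse(g$sx > 0 & g$sy > 0, "Q1",
                 ifelse(g$sx < 0 & g$sy < 0, "Q3",
                        ifelse(g$sx > 0, "Q4", "Q2")))
  if (groups == "three") quad[quad %in% c("Q2", "Q4")] <- "Q2or4"
  key <- paste(pmin(g$sx, g$sy), pmax(g$sx, g$sy))
  tab <- table(key, quad)
  sum(apply(tab, 1L, max)) / nrow(g)
}

#' Sinusoidal grating probe
#'
#' A grating at one of six orientations equally spaced over \[0, pi), with
#' random spatial phase, rendered at the source size and framed exactly like
#' the natural images (noise edge and frame), amplitude range \[0, 255\].
#' Spatial frequency is fixed at 4 cycles per image width.
#'
#' @param orientation_index integer 1..6; angle is `(index - 1) * pi / 6`.
#' @param source_size,frame,edge framing geometry, as [surrogate_dataset()].
#' @param cycles spatial frequency in cycles per image width.
#' @return framed grating matrix with attributes `orientation_index`,
#'   `theta`, `phase`.
#' @export
make_grating <- function(orientation_index, source_size = 15L, frame = 3L,
                         edge = 1L, cycles = 4) {
  stopifnot(orientation_index %in% 1:6)
  theta <- (orientation_index - 1) * pi / 6
  phase <- stats::runif(1, 0, 2 * pi)
  ax <- seq(0, 1, length.out = source_size)
  u <- matrix(rep(ax, source_size), source_size)
  v <- matrix(rep(ax, each = source_size), source_size)
  src <- 127.5 * (1 + sin(2 * pi * cycles * (u * cos(theta) + v * sin(theta))
                          + phase))
  out <- preprocess_image(src, frame = frame, edge = edge)
  attr(out, "orientation_index") <- as.integer(orientation_index)
  attr(out, "theta") <- theta
  attr(out, "phase") <- phase
  out
}

#' Build a saccadic trial set from labelled base images
#'
#' Draws a shift per image uniformly over the configured range, shifts the
#' visual input, and pairs it with a movement image under the requested
#' condition. `condition = "none"` applies shifts without movement images
#' (or, with `shift_range = 0`, produces the unshifted stream).
#'
#' @param base list with `images` (S x S x N) and `labels`.
#' @param shift_range maximum shift magnitude (8; 4 or 2 for the smaller
#'   dialects).
#' @param condition `"congruent"`, `"incongruent"` or `"none"`.
#' @param scale movement amplitude scale (see [movement_scale()]).
#' @param dialect shift dialect, see [apply_shift()].
#' @param seed integer seed.
#' @return list with `x`, `y`, `movement` (or NULL), `shifts` (N x 2),
#'   `groups`.
#' @export
generate_saccadic_trials <- function(base, shift_range = 4L,
                                     condition = c("congruent", "incongruent",
                                                   "none"),
                                     scale = 1, dialect = "noise", seed = 1L) {
  condition <- match.arg(condition)
  local_rng(seed)
  n <- dim(base$images)[3]
  shifts <- matrix(sample(seq(-shift_range, shift_range), 2L * n,
                          replace = TRUE), ncol = 2L)
  if (shift_range == 0L) shifts[] <- 0L
  x <- array(0, dim(base$images))
  for (j in seq_len(n)) {
    x[, , j] <- apply_shift(base$images[, , j], shifts[j, ], dialect = dialect,
                            max_shift = max(shift_range, 1L))
  }
  trials <- list(x = x, y = base$labels, movement = NULL, shifts = shifts,
                 groups = apply(shifts, 1L, quadrant_group))
  if (condition == "none") return(trials)
  add_movement_images(trials, condition, scale = scale,
                      max_shift = max(shift_range, 1L),
                      seed = derive_seed(seed, "movement"))
}

#' Attach movement images to an existing trial set
#'
#' Pairs each (already shifted) visual image with a movement image, leaving
#' the visual stream untouched — this is how matched congruent/incongruent
#' test streams sharing identical visual inputs are built.
#'
#' @param trials result of [generate_saccadic_trials()] (any condition).
#' @param condition `"congruent"` or `"incongruent"`.
#' @param scale movement amplitude scale.
#' @param max_shift saccadic range (incongruent draws).
#' @param seed integer seed.
#' @return the trial list with `movement` replaced.
#' @export
add_movement_images <- function(trials, condition = c("congruent",
                                                      "incongruent"),
                                scale = 1, max_shift = 8L, seed = 1L) {
  condition <- match.arg(condition)
  local_rng(seed)
  d <- dim(trials$x)
  movement <- array(0, d)
  for (j in seq_len(d[3])) {
    movement[, , j] <- make_movement_image(trials$shifts[j, ], d[1:2],
                                           condition, scale = scale,
                                           max_shift = max_shift)
  }
  trials$movement <- movement
  trials$condition <- condition
  trials
}
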