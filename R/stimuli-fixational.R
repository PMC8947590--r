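# Fixational eye-movement stimuli: retinotopic bar-localization task.
#
# The 28x28 input frame is divided into five equally high, non-overlapping
# horizontal bands of 5 px (rows 3..27; 2 spare rows at the top margin, 1 at
# the bottom). A luminance bar (7 px high, 20 px wide, columns 1..20) is
# vertically centred on its band, overhanging the 5 px band by one row on
# each side. The three stimulus locations in visual space default to bands
# 1, 3 and 5; a discretized ocular shift s in {-2..+2} moves the evoked
# response by s bands. Sign convention (used everywhere): positive shift =
# upward eye movement = bar lands in a higher band (smaller band index).
#
# The corollary-discharge (movement) pattern is a 21x20 rectangle at the
# right side of the frame (rows 4..24, columns 9..28), overlapping the bar
# region by 12 columns. Its amplitude is either constant (0.5 for every
# shift) or modulated: a(s) = 0.5 + 0.2 s, an injective map of the signed
# shift with increments for upward and decrements for downward movements.

N_BANDS <- 5L
BAND_TOP <- 2L      # spare rows above band 1
BAND_H <- 5L
BAR_H <- 7L
BAR_W <- 20L
BAR_COLS <- 1:20
MOVE_ROWS <- 4:24   # 21 rows, vertically centred
MOVE_COLS <- 9:28   # 20 columns; 12-column overlap with BAR_COLS
FIX_SIZE <- 28L
DEFAULT_BAND <- c(1L, 3L, 5L)

band_rows <- function(band) {
  centre <- BAND_TOP + BAND_H * (band - 1L) + (BAND_H + 1L) %/% 2L
  (centre - BAR_H %/% 2L):(centre + BAR_H %/% 2L)
}

#' Admissible (location, shift) pairs
#'
#' With `edge_mode = "wrap"` the band index wraps around the frame, so every
#' location admits all five shifts and every location reaches all five bands
#' (the fully degenerate design: the band carries no information about the
#' location label beyond chance). With `edge_mode = "restrict"` the top
#' stimulus can only shift downward and the bottom stimulus only upward, so
#' the admissible shifts are {0,-1,-2}, {-2..+2} and {0,+1,+2} for locations
#' 1..3; the resulting band distributions then differ across locations and
#' the task is only partially degenerate (see [fixational_bayes_accuracy()]).
#'
#' @param edge_mode `"wrap"` or `"restrict"`.
#' @return data.frame with columns `location`, `shift`, `band`.
#' @export
admissible_pairs <- function(edge_mode = c("wrap", "restrict")) {
  edge_mode <- match.arg(edge_mode)
  g <- expand.grid(location = 1:3, shift = -2:2)
  g$band <- vapply(seq_len(nrow(g)), function(i) {
    shift_band(g$location[i], g$shift[i], edge_mode, check = FALSE)
  }, 0L)
  if (edge_mode == "restrict") {
    keep <- (g$location == 1L & g$shift <= 0L) |
      (g$location == 2L) |
      (g$location == 3L & g$shift >= 0L)
    g <- g[keep, ]
  }
  rownames(g) <- NULL
  g
}

shift_band <- function(location, shift, edge_mode = "wrap", check = TRUE) {
  band <- DEFAULT_BAND[location] - shift
  if (edge_mode == "wrap") {
    band <- ((band - 1L) %% N_BANDS) + 1L
  } else if (check && (band < 1L || band > N_BANDS ||
                       (location == 1L && shift > 0L) ||
                       (location == 3L && shift < 0L))) {
    stop("inadmissible (location = ", location, ", shift = ", shift,
         "): resulting band ", band, " is outside 1..", N_BANDS,
         " under the restricted edge mode")
  }
  as.integer(band)
}

new_stimulus <- function(mat, provenance, range = c(0, 1)) {
  structure(mat, provenance = provenance, amplitude_range = range)
}

#' Luminance-bar stimulus image
#'
#' Places the 7x20 px bar in the band determined by the stimulus location
#' and the ocular shift.
#'
#' @param location stimulus location in visual space, 1 (top) to 3 (bottom).
#' @param shift discretized ocular shift in -2..+2 (positive = upward).
#' @param amplitude bar amplitude in (0, 1]; 1 by default.
#' @param edge_mode band edge handling, see [admissible_pairs()].
#' @return 28x28 matrix with attributes `provenance`, `amplitude_range`,
#'   `band`.
#' @export
make_bar_image <- function(location, shift = 0L, amplitude = 1,
                           edge_mode = c("wrap", "restrict")) {
  edge_mode <- match.arg(edge_mode)
  stopifnot(location %in% 1:3, shift %in% -2:2,
            amplitude > 0, amplitude <= 1)
  band <- shift_band(location, shift, edge_mode)
  img <- matrix(0, FIX_SIZE, FIX_SIZE)
  img[band_rows(band), BAR_COLS] <- amplitude
  out <- new_stimulus(img, "visual")
  attr(out, "band") <- band
  out
}

#' Corollary-discharge activity pattern
#'
#' The movement signal is a 21x20 px rectangular pattern with a different
#' localization and shape than the visual bars (12 px of column overlap with
#' the bar region). With `mode = "constant"` its amplitude is 0.5 regardless
#' of the shift; with `mode = "modulated"` the amplitude is 0.5 + 0.2 s,
#' injective over the five shifts.
#'
#' @param shift discretized ocular shift in -2..+2.
#' @param mode `"constant"` or `"modulated"`.
#' @return 28x28 matrix with attribute `amplitude`.
#' @export
make_movement_pattern <- function(shift = 0L, mode = c("constant", "modulated")) {
  mode <- match.arg(mode)
  stopifnot(shift %in% -2:2)
  amp <- if (mode == "constant") 0.5 else 0.5 + 0.2 * shift
  img <- matrix(0, FIX_SIZE, FIX_SIZE)
  img[MOVE_ROWS, MOVE_COLS] <- amp
  out <- new_stimulus(img, "movement", range = c(-1.3, 1.3))
  attr(out, "amplitude") <- amp
  out
}

#' Compose visual and movement signals into one input image
#'
#' Visuo-motor summation is sub-linear; it is implemented as clipping to the
#' signal of larger magnitude wherever both signals are nonzero, and as the
#' identity elsewhere. Symmetric in its arguments.
#'
#' @param visual,movement same-shape stimulus matrices.
#' @return composite stimulus matrix.
#' @export
compose_stimuli <- function(visual, movement) {
  if (!identical(dim(visual), dim(movement))) {
    stop("shape mismatch: ", paste(dim(visual), collapse = "x"), " vs ",
         paste(dim(movement), collapse = "x"))
  }
  out <- unclass(visual) + unclass(movement)
  both <- visual != 0 & movement != 0
  vdom <- abs(visual) >= abs(movement)
  out[both & vdom] <- visual[both & vdom]
  out[both & !vdom] <- movement[both & !vdom]
  new_stimulus(matrix(out, nrow(visual)), "composite", range = c(-1.3, 1.3))
}

#' Fixational bar-localization dataset
#'
#' Generates `n` labelled composite images, balanced over the admissible
#' (location, shift) pairs, split 50/50 into training and test sets.
#'
#' @param n total number of trials (even).
#' @param mode movement-amplitude mode: `"constant"`, `"modulated"`, or
#'   `"none"` (no movement pattern in the image).
#' @param seed integer seed.
#' @param edge_mode see [admissible_pairs()].
#' @return object of class `fixational_dataset`: `train`/`test` lists with
#'   `x` (28 x 28 x n/2 image array), `y` (location labels), `shifts`,
#'   `bands`.
#' @export
generate_fixational_dataset <- function(n = 800L,
                                        mode = c("constant", "modulated", "none"),
                                        seed = 1L,
                                        edge_mode = c("wrap", "restrict")) {
  mode <- match.arg(mode)
  edge_mode <- match.arg(edge_mode)
  stopifnot(n %% 2L == 0L)
  local_rng(seed)
  pairs <- admissible_pairs(edge_mode)
  np <- nrow(pairs)
  half <- n %/% 2L
  # each split is balanced over admissible pairs independently, so the test
  # half's composition is not anti-correlated with the training half's
  balanced_seq <- function(m) {
    reps <- rep(seq_len(np), m %/% np)
    sample(c(reps, sample.int(np, m - length(reps))))
  }
  make_trial <- function(i) {
    loc <- pairs$location[i]; sh <- pairs$shift[i]
    bar <- make_bar_image(loc, sh, edge_mode = edge_mode)
    if (mode == "none") return(unclass(bar))
    unclass(compose_stimuli(bar, make_movement_pattern(sh, mode)))
  }
  split_set <- function(ord) {
    images <- array(0, c(FIX_SIZE, FIX_SIZE, length(ord)))
    for (j in seq_along(ord)) images[, , j] <- make_trial(ord[j])
    list(x = images, y = pairs$location[ord], shifts = pairs$shift[ord],
         bands = pairs$band[ord])
  }
  structure(list(train = split_set(balanced_seq(half)),
                 test = split_set(balanced_seq(half)),
                 mode = mode, edge_mode = edge_mode, seed = seed),
            class = "fixational_dataset")
}

#' Ideal-observer (Bayes) accuracy of the bar-localization task
#'
#' Enumerates the discrete stimulus space. With constant movement amplitude
#' the composite image is a deterministic function of the occupied band, so
#' the Bayes classifier observes the band; with modulated amplitudes the
#' image additionally reveals the shift, which disambiguates the location
#' completely (accuracy 1). The enumeration is exact, not simulated.
#'
#' @param mode `"constant"` or `"modulated"`.
#' @param edge_mode see [admissible_pairs()].
#' @param weighting `"pair"` (trials uniform over admissible pairs, the
#'   dataset generator's sampling) or `"location"` (labels balanced, shifts
#'   uniform within each location).
#' @return Bayes-optimal accuracy in \[0, 1\].
#' @export
fixational_bayes_accuracy <- function(mode = c("constant", "modulated"),
                                      edge_mode = c("wrap", "restrict"),
                                      weighting = c("pair", "location")) {
  mode <- match.arg(mode)
  edge_mode <- match.arg(edge_mode)
  weighting <- match.arg(weighting)
  pairs <- admissible_pairs(edge_mode)
  if (weighting == "pair") {
    pairs$mass <- 1 / nrow(pairs)
  } else {
    nl <- table(pairs$location)
    pairs$mass <- (1 / 3) / as.numeric(nl[as.character(pairs$location)])
  }
  # observable: band alone (constant) or (band, shift) (modulated)
  obs <- if (mode == "constant") pairs$band else paste(pairs$band, pairs$shift)
  sum(vapply(split(pairs$mass, list(obs, pairs$location), drop = FALSE),
             sum, 0) |> matrix(nrow = length(unique(obs))) |>
        apply(1L, max))
}

#' Focal-spot (phosphene) probe
#'
#' A small high-contrast activity pattern mimicking focal external
#' stimulation of visual cortex, dissimilar from all trained patterns.
#'
#' @param center pixel coordinates (row, col) of the spot centre.
#' @param size odd spot side length in px.
#' @param contrast_level integer 1..10; amplitude is `contrast_level / 10`.
#' @return 28x28 stimulus matrix.
#' @export
make_focal_spot <- function(center = c(14L, 14L), size = 3L,
                            contrast_level = 10L) {
  stopifnot(size %% 2L == 1L, contrast_level %in% 1:10)
  h <- size %/% 2L
  rows <- (center[1] - h):(center[1] + h)
  cols <- (center[2] - h):(center[2] + h)
  if (min(rows, cols) < 1L || max(rows, cols) > FIX_SIZE) {
    stop("focal spot at (", center[1], ",", center[2], ") of size ", size,
         " extends outside the 28x28 frame")
  }
  img <- matrix(0, FIX_SIZE, FIX_SIZE)
  img[rows, cols] <- contrast_level / 10
  new_stimulus(img, "probe")
}

pattern_templates <- function() {
  vis <- lapply(c(1L, 2L, 4L, 5L), function(b) {
    img <- matrix(0, FIX_SIZE, FIX_SIZE)
    img[band_rows(b), BAR_COLS] <- 1
    img
  })
  mv1 <- matrix(0, FIX_SIZE, FIX_SIZE)
  mv1[MOVE_ROWS, MOVE_COLS] <- 1
  mv2 <- matrix(0, FIX_SIZE, FIX_SIZE)
  mv2[MOVE_ROWS, MOVE_COLS - 6L] <- 1   # 14-column overlap with mv1
  c(vis, list(mv1, mv2))
}

#' Visual/movement pattern-classification set
#'
#' Six channels: four visual bar stimuli (bands 1, 2, 4, 5) and two
#' rectangular movement patterns (21x20, overlapping each other by 14 px).
#' Each image is drawn at one of ten contrast levels (amplitudes 0.1..1.0 in
#' 0.1 steps) and corrupted by i.i.d. uniform pixel noise of peak amplitude
#' 0.05 to reduce overfitting during training.
#'
#' @param n_per_class images per channel.
#' @param seed integer seed.
#' @param noise_peak peak amplitude of the uniform pixel noise.
#' @return list with `images` (28 x 28 x 6*n_per_class), `labels` (1..6;
#'   1..4 visual, 5..6 movement), `contrast_level`, `is_visual`.
#' @export
make_pattern_set <- function(n_per_class = 100L, seed = 1L, noise_peak = 0.05) {
  local_rng(seed)
  tpl <- pattern_templates()
  n <- 6L * n_per_class
  images <- array(0, c(FIX_SIZE, FIX_SIZE, n))
  labels <- rep(1:6, each = n_per_class)
  lev <- integer(n)
  for (j in seq_len(n)) {
    lev[j] <- sample.int(10L, 1L)
    img <- tpl[[labels[j]]] * (lev[j] / 10) +
      matrix(stats::runif(FIX_SIZE^2, 0, noise_peak), FIX_SIZE)
    images[, , j] <- img
  }
  ord <- sample.int(n)
  list(images = images[, , ord, drop = FALSE], labels = labels[ord],
       contrast_level = lev[ord], is_visual = labels[ord] <= 4L)
}
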