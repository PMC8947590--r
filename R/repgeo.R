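# Representational analyses: low-dimensional embeddings with classifier
# readouts, activity-mode angles, movement-signal gating, saccade-direction
# decoding, and congruent-vs-incongruent clustering of image classes.
#
# The population-analysis unit throughout is the channel mean: each
# channel's activity averaged across its entire unit grid (layer_activations).

#' Exact t-SNE embedding
#'
#' Plain (exact-gradient) t-distributed stochastic neighbor embedding with
#' Euclidean distances: per-point bandwidths from a binary search matching
#' the target perplexity, symmetrized affinities, early exaggeration, and
#' momentum gradient descent. O(n^2) per iteration, intended for the
#' analysis-set sizes used here (hundreds to ~1000 points).
#'
#' @param X numeric matrix, samples x features.
#' @param dims embedding dimensionality.
#' @param perplexity target perplexity (reduced automatically when the
#'   sample count is small).
#' @param max_iter gradient-descent iterations.
#' @param seed integer seed (embedding initialization).
#' @return samples x dims coordinate matrix.
#' @export
tsne_embed <- function(X, dims = 2L, perplexity = 30, max_iter = 350L,
                       seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 4L)
  perplexity <- min(perplexity, (n - 1) / 3)
  local_rng(seed)
  D2 <- as.matrix(stats::dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { p <- rep(1 / length(di), length(di)); break }
      p <- w / sw
      H <- -sum(p * log(pmax(p, 1e-300)))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n)
  V <- matrix(0, n, dims)
  exag <- 4
  for (it in seq_len(max_iter)) {
    Pe <- if (it <= 100L) P * exag else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    G <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(G)) - G) %*% Y
    mom <- if (it <= 100L) 0.5 else 0.8
    V <- mom * V - 100 * grad
    Y <- Y + V
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

#' PCA embedding (component scores)
#'
#' @param X samples x features matrix.
#' @param n_components number of principal components.
#' @return samples x n_components score matrix.
#' @export
pca_embed <- function(X, n_components = 3L) {
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$x))
  pr$x[, seq_len(k), drop = FALSE]
}

fit_readout <- function(train_x, train_y, readout) {
  df <- data.frame(train_x)
  df$.y <- factor(train_y)
  switch(readout,
    svm_quadratic = e1071::svm(.y ~ ., data = df, kernel = "polynomial",
                               degree = 2, coef0 = 1, scale = FALSE),
    svm_linear = e1071::svm(.y ~ ., data = df, kernel = "linear",
                            scale = FALSE),
    lda = MASS::lda(.y ~ ., data = df)
  )
}

predict_readout <- function(fit, test_x, readout) {
  df <- data.frame(test_x)
  if (readout == "lda") {
    as.character(stats::predict(fit, df)$class)
  } else {
    as.character(stats::predict(fit, df))
  }
}

stratified_folds <- function(labels, folds, seed) {
  local_rng(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    fold[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  fold
}

#' Embed population activity and decode labels by cross-validated readout
#'
#' Fits the embedding on the full analysis set, then cross-validates the
#' readout within it (the embedding itself is not refit per fold; the
#' cross-validation covers the classifier only, which is mirrored from the
#' original analysis recipe and acknowledged as optimistic).
#'
#' @param channel_means channels x samples activation matrix (or any
#'   features x samples matrix).
#' @param labels per-sample class labels.
#' @param recipe `"pca"` or `"tsne"`.
#' @param n_components embedding dimensionality (2 for t-SNE panels, 3 or
#'   20 for the PCA readouts).
#' @param readout `"svm_quadratic"`, `"svm_linear"` or `"lda"`.
#' @param folds cross-validation folds.
#' @param seed integer seed (folds and embedding).
#' @return object of class `decoding_result`: accuracy, confusion,
#'   per-fold accuracies, and the recipe metadata.
#' @export
embed_and_decode <- function(channel_means, labels, recipe = c("pca", "tsne"),
                             n_components = if (recipe == "tsne") 2L else 3L,
                             readout = c("svm_quadratic", "svm_linear", "lda"),
                             folds = 5L, seed = 1L) {
  recipe <- match.arg(recipe)
  readout <- match.arg(readout)
  X <- t(as.matrix(channel_means))     # samples x features
  labels <- as.vector(labels)
  stopifnot(length(labels) == nrow(X), length(unique(labels)) >= 2L,
            nrow(X) >= folds)
  if (stats::sd(X) == 0) stop("degenerate embedding input: all points identical")
  emb <- switch(recipe,
                pca = pca_embed(X, n_components),
                tsne = tsne_embed(X, dims = n_components, seed = seed))
  fold <- stratified_folds(labels, folds, seed = derive_seed(seed, "folds"))
  pred <- character(length(labels))
  for (f in seq_len(folds)) {
    te <- fold == f
    fit <- fit_readout(emb[!te, , drop = FALSE], labels[!te], readout)
    pred[te] <- predict_readout(fit, emb[te, , drop = FALSE], readout)
  }
  lev <- sort(unique(as.character(labels)))
  confusion <- table(factor(as.character(labels), lev), factor(pred, lev))
  per_fold <- vapply(seq_len(folds), function(f) {
    mean(pred[fold == f] == as.character(labels)[fold == f])
  }, 0)
  structure(list(accuracy = mean(pred == as.character(labels)),
                 confusion = unclass(confusion), per_fold = per_fold,
                 recipe = recipe, n_components = n_components,
                 readout = readout, folds = folds, embedding = emb),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding: %s(%d) + %s, %d-fold CV accuracy %.3f\n",
              x$recipe, x$n_components, x$readout, x$folds, x$accuracy))
  invisible(x)
}

unit_normalize_cols <- function(m) {
  nrm <- sqrt(colSums(m^2))
  ok <- nrm > 0
  m[, ok] <- sweep(m[, ok, drop = FALSE], 2L, nrm[ok], "/")
  list(m = m, ok = ok)
}

#' Angle between paired activity modes
#'
#' Column-wise angle acos(|A'B|) in degrees between paired channel-activation
#' vectors, after unit normalization (without which the product is not a
#' cosine). The absolute value folds antiparallel modes onto 0 degrees, so
#' angles lie in \[0, 90\]. Columns where either vector is all zero yield
#' `NA`.
#'
#' @param A,B matrices of identical shape, one activation vector per column.
#' @return numeric vector of angles in degrees.
#' @export
activity_mode_angle <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(identical(dim(A), dim(B)))
  ua <- unit_normalize_cols(A)
  ub <- unit_normalize_cols(B)
  ang <- acos(pmin(abs(colSums(ua$m * ub$m)), 1)) * 180 / pi
  ang[!(ua$ok & ub$ok)] <- NA_real_
  ang
}

#' Angle between movement-evoked and visual-evoked activity modes
#'
#' For each paired example, takes the channel-activation vector evoked by a
#' movement-only input (A) and by a visual-only input (B) at a layer, unit
#' normalizes both, and computes acos(|A'B|) in degrees (the absolute value
#' folds antiparallel modes onto 0). Examples where either vector is all
#' zero are excluded and counted.
#'
#' @param net a trained `cnn_net` (feature-image movement mode).
#' @param visual_images visual stimuli (H x W x N).
#' @param movement_images movement images (H x W x N), paired with visual.
#' @param layer conv layer.
#' @return list with `angles` (per kept example, degrees), `mean_angle`,
#'   `n_excluded`.
#' @export
mode_angle <- function(net, visual_images, movement_images, layer = 1L) {
  n <- dim(visual_images)[3]
  zeros_v <- array(0, dim(visual_images))
  zeros_m <- array(0, dim(movement_images))
  A <- layer_activations(net, zeros_v, movement_images, layer)$channel_mean
  B <- layer_activations(net, visual_images, zeros_m, layer)$channel_mean
  angles <- activity_mode_angle(A, B)
  keep <- !is.na(angles)
  list(angles = angles[keep], mean_angle = mean(angles[keep]),
       n_excluded = sum(!keep))
}

#' Movement-signal gating profile across layers
#'
#' Feeds movement-only inputs (zero visual image) and summarizes, per layer,
#' the distribution of channel-mean amplitudes and the probability that a
#' channel's response is gated away, i.e. below `zero_tol` times the layer's
#' maximum observed amplitude. When networks are compared (e.g. chance-level
#' vs above-chance), pass a common `ref_max` per layer: normalizing each
#' network by its own maximum would understate gating in networks whose
#' movement responses are weak overall.
#'
#' @param net a trained `cnn_net`.
#' @param movement_images movement images (H x W x N).
#' @param zero_tol zero-amplitude tolerance as a fraction of the layer max.
#' @param ref_max optional numeric vector of per-layer reference amplitudes
#'   (defaults to this network's own per-layer maximum).
#' @return data.frame with columns `layer`, `p_zero`, `mean_amp`, `max_amp`.
#' @export
gating_profile <- function(net, movement_images, zero_tol = 0.01,
                           ref_max = NULL) {
  zeros_v <- array(0, dim(movement_images))
  out <- lapply(seq_len(net$spec$n_conv), function(l) {
    cm <- layer_activations(net, zeros_v, movement_images, l)$channel_mean
    mx <- max(abs(cm))
    ref <- if (is.null(ref_max)) mx else ref_max[l]
    p0 <- if (ref == 0) 1 else mean(abs(cm) < zero_tol * ref)
    data.frame(layer = l, p_zero = p0, mean_amp = mean(abs(cm)),
               max_amp = mx)
  })
  do.call(rbind, out)
}

#' Decode saccade-direction groups across layers
#'
#' Decodes the three direction groups (1st quadrant, 3rd quadrant, merged
#' 2nd/4th quadrant) from movement-only activations at every layer: channel
#' means, PCA to 3 components, then a 5-fold cross-validated linear SVM.
#' Layer 0 is the ideal-observer readout from the raw movement images (the
#' min/max pixel values recover the unordered scalar pair exactly, so the
#' three groups are fully decodable there).
#'
#' @param net a trained `cnn_net`.
#' @param movement_images movement images (H x W x N), off-cardinal shifts.
#' @param shifts N x 2 matrix of the encoded shift pairs.
#' @param folds cross-validation folds.
#' @param seed integer seed.
#' @return data.frame with `layer` (0..n_conv) and `accuracy`.
#' @export
decode_directions <- function(net, movement_images, shifts, folds = 5L,
                              seed = 1L) {
  groups <- apply(shifts, 1L, quadrant_group)
  if (any(groups == "cardinal")) {
    stop("cardinal shifts present; direction decoding uses the three open-",
         "quadrant groups")
  }
  n <- dim(movement_images)[3]
  raw <- rbind(apply(movement_images, 3L, min), apply(movement_images, 3L, max))
  res <- list(data.frame(layer = 0L, accuracy = embed_and_decode(
    raw, groups, recipe = "pca", n_components = 2L, readout = "svm_linear",
    folds = folds, seed = seed)$accuracy))
  zeros_v <- array(0, dim(movement_images))
  for (l in seq_len(net$spec$n_conv)) {
    cm <- layer_activations(net, zeros_v, movement_images, l)$channel_mean
    acc <- if (max(abs(cm)) == 0 || stats::sd(cm) == 0) {
      max(table(groups)) / n
    } else {
      embed_and_decode(cm, groups, recipe = "pca", n_components = 3L,
                       readout = "svm_linear", folds = folds, seed = seed)$accuracy
    }
    res[[l + 1L]] <- data.frame(layer = l, accuracy = acc)
  }
  do.call(rbind, res)
}

#' Class decodability under congruent vs incongruent test movement
#'
#' For a network trained with congruent movement inputs, builds two test
#' streams that share the identical shifted visual images and differ only in
#' the movement images (congruent vs incongruent), then decodes the image
#' class per layer from channel means via PCA (20 components by default)
#' and a cross-validated quadratic SVM.
#'
#' @param net a congruently trained `cnn_net`.
#' @param base list with `images`, `labels` (held-out set).
#' @param shift_range saccadic range.
#' @param scale movement amplitude scale.
#' @param n_components PCA dimensionality.
#' @param folds cross-validation folds.
#' @param seed integer seed.
#' @return data.frame with `layer`, `condition`, `accuracy`.
#' @export
congruency_clustering <- function(net, base, shift_range = 4L, scale = 1,
                                  n_components = 20L, folds = 5L, seed = 1L) {
  vis <- generate_saccadic_trials(base, shift_range, condition = "none",
                                  seed = derive_seed(seed, "vis"))
  out <- list()
  for (cond in c("congruent", "incongruent")) {
    trials <- add_movement_images(vis, condition = cond, scale = scale,
                                  max_shift = shift_range,
                                  seed = derive_seed(seed, paste0("mv", cond)))
    for (l in seq_len(net$spec$n_conv)) {
      cm <- layer_activations(net, trials$x, trials$movement, l)$channel_mean
      k <- min(n_components, nrow(cm) - 1L)
      acc <- embed_and_decode(cm, trials$y, recipe = "pca", n_components = k,
                              readout = "svm_quadratic", folds = folds,
                              seed = seed)$accuracy
      out[[length(out) + 1L]] <- data.frame(layer = l, condition = cond,
                                            accuracy = acc)
    }
  }
  do.call(rbind, out)
}
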