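#' Declare a convolutional network architecture
#'
#' Describes the network variants used throughout the package: a stack of
#' `n_conv` blocks (3x3 convolution, stride 1, padding 1; ReLU; 2x2 max
#' pooling), followed by a fully connected layer and a softmax over
#' `n_classes`. Movement (corollary-discharge) signals can enter the network
#' in three ways:
#'
#' * `"none"`: the network sees only its visual input (movement information,
#'   if any, is already composed into the image, as in the fixational
#'   bar-localization task);
#' * `"feature_image"`: a movement image is concatenated as an extra input
#'   channel to the convolutional layer `injection_layer` (the saccadic
#'   experiments);
#' * `"global_scalar"`: a single per-trial scalar is added (broadcast) to all
#'   units of convolutional layer `injection_layer` through an addition
#'   stage (the deep-injection control for the fixational task).
#'
#' A trainable batch-normalization layer follows the convolution that
#' receives movement input (`bn_layer`, defaulting to `injection_layer`),
#' keeping the injected amplitudes from saturating downstream units.
#'
#' @param input_size integer length-2, spatial size (H, W) of the input image.
#' @param in_channels number of visual input channels (1 for grayscale).
#' @param n_conv number of convolutional blocks (2 or 3).
#' @param channels channel counts per block; defaults to 16, 32, 64.
#' @param n_classes number of output classes.
#' @param movement_mode one of `"none"`, `"feature_image"`, `"global_scalar"`.
#' @param injection_layer conv block receiving the movement signal.
#' @param bn_layer conv block followed by batch normalization; default
#'   `injection_layer`.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(input_size, in_channels = 1L, n_conv = 3L,
                     channels = c(16L, 32L, 64L)[seq_len(n_conv)],
                     n_classes, movement_mode = c("none", "feature_image",
                                                  "global_scalar"),
                     injection_layer = 1L, bn_layer = injection_layer) {
  movement_mode <- match.arg(movement_mode)
  stopifnot(length(input_size) == 2L, n_conv %in% c(2L, 3L),
            length(channels) == n_conv, n_classes >= 2L)
  if (injection_layer > n_conv) {
    stop("injection_layer (", injection_layer, ") exceeds n_conv (", n_conv, ")")
  }
  sizes <- vector("list", n_conv + 1L)
  sizes[[1L]] <- as.integer(input_size)
  for (k in seq_len(n_conv)) {
    sizes[[k + 1L]] <- sizes[[k]] %/% 2L
  }
  if (any(sizes[[n_conv + 1L]] < 1L)) stop("input too small for ", n_conv, " pooling stages")
  structure(list(
    input_size = as.integer(input_size), in_channels = as.integer(in_channels),
    n_conv = as.integer(n_conv), channels = as.integer(channels),
    n_classes = as.integer(n_classes), movement_mode = movement_mode,
    injection_layer = as.integer(injection_layer),
    bn_layer = as.integer(bn_layer), sizes = sizes
  ), class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat("CNN spec: ", paste(x$input_size, collapse = "x"), " x ", x$in_channels,
      " -> ", paste(x$channels, collapse = "/"), " conv channels -> ",
      x$n_classes, " classes\n", sep = "")
  cat("movement: ", x$movement_mode,
      if (x$movement_mode != "none") paste0(" (layer ", x$injection_layer, ")"),
      "; batch-norm after conv-", x$bn_layer, "\n", sep = "")
  invisible(x)
}

conv_in_channels <- function(spec, k) {
  base <- if (k == 1L) spec$in_channels else spec$channels[k - 1L]
  if (spec$movement_mode == "feature_image" && spec$injection_layer == k) {
    base + 1L
  } else {
    base
  }
}

#' Build a network with randomly initialized weights
#'
#' Convolutional and fully connected layers carry the trainable parameters
#' (He-style variance-scaled initialization); the batch-normalization layer
#' adds a trainable per-channel scale and shift. Initialization is
#' reproducible under `seed`.
#'
#' @param spec a [cnn_spec()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `cnn_net`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  rng <- local_rng(seed)
  params <- list()
  for (k in seq_len(spec$n_conv)) {
    cin <- conv_in_channels(spec, k)
    cout <- spec$channels[k]
    fan_in <- 9L * cin
    params[[paste0("conv", k)]] <- list(
      w = matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                 nrow = cout),
      b = numeric(cout)
    )
  }
  cbn <- spec$channels[spec$bn_layer]
  params$bn <- list(gamma = rep(1, cbn), beta = numeric(cbn),
                    run_mean = numeric(cbn), run_var = rep(1, cbn))
  last <- spec$sizes[[spec$n_conv + 1L]]
  d_fc <- prod(last) * spec$channels[spec$n_conv]
  params$fc <- list(
    w = matrix(stats::rnorm(spec$n_classes * d_fc, sd = sqrt(2 / d_fc)),
               nrow = spec$n_classes),
    b = numeric(spec$n_classes)
  )
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 history = NULL), class = "cnn_net")
}

#' @export
print.cnn_net <- function(x, ...) {
  print(x$spec)
  np <- sum(vapply(x$params, function(p) sum(lengths(lapply(p, c))), 0))
  cat("trainable + running parameters: ", np, "\n", sep = "")
  if (!is.null(x$history)) {
    cat("trained: ", length(x$history$train_acc), " epochs, final val acc ",
        round(utils::tail(x$history$val_acc, 1), 3), "\n", sep = "")
  }
  invisible(x)
}

as_input_array <- function(x, spec) {
  if (is.list(x)) x <- simplify2array(x)
  d <- dim(x)
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) == 3L) {
    # (H, W, N) grayscale stack -> (H, W, 1, N)
    x <- array(x, c(d[1], d[2], 1L, d[3]))
  }
  stopifnot(dim(x)[1] == spec$input_size[1], dim(x)[2] == spec$input_size[2])
  x
}

prep_movement <- function(movement, spec, n, k_size) {
  if (spec$movement_mode == "none") return(NULL)
  if (spec$movement_mode == "global_scalar") {
    stopifnot(length(movement) == n)
    return(as.numeric(movement))
  }
  if (is.list(movement)) movement <- simplify2array(movement)
  d <- dim(movement)
  if (length(d) == 2L) movement <- array(movement, c(d, 1L))
  if (dim(movement)[1] != k_size[1] || dim(movement)[2] != k_size[2]) {
    stop("movement image size ", paste(dim(movement)[1:2], collapse = "x"),
         " does not match injection-layer input size ",
         paste(k_size, collapse = "x"))
  }
  array(movement, c(k_size[1], k_size[2], 1L, n))
}

#' Forward pass of a network
#'
#' Computes class probabilities for a batch, optionally recording per-layer
#' activations or the full cache needed for backpropagation.
#'
#' @param net a `cnn_net`.
#' @param x visual input: (H, W, N) or (H, W, C, N) array, or list of images.
#' @param movement movement input: image stack for `"feature_image"` mode,
#'   numeric vector (one scalar per sample) for `"global_scalar"`, `NULL`
#'   otherwise.
#' @param train logical; use batch statistics in batch normalization (and
#'   update running statistics) rather than running statistics.
#' @param keep `"probs"`, `"acts"` (per-layer post-ReLU activations) or
#'   `"cache"` (everything required by [net_backward()]).
#' @return list with `probs` (K x N), and `acts`/`cache` when requested.
#' @export
net_forward <- function(net, x, movement = NULL, train = FALSE,
                        keep = c("probs", "acts", "cache")) {
  keep <- match.arg(keep)
  spec <- net$spec
  x <- as_input_array(x, spec)
  n <- dim(x)[4]
  if (spec$movement_mode != "none" && is.null(movement)) {
    stop("movement input required for movement_mode = ", spec$movement_mode)
  }
  if (spec$movement_mode == "none" && !is.null(movement)) {
    stop("movement input supplied but movement_mode = none")
  }
  mv <- prep_movement(movement, spec, n,
                      spec$sizes[[spec$injection_layer]])
  cache <- list(n = n)
  acts <- list()
  p <- net$params
  for (k in seq_len(spec$n_conv)) {
    if (spec$movement_mode == "feature_image" && spec$injection_layer == k) {
      d <- dim(x)
      xa <- array(0, c(d[1], d[2], d[3] + 1L, d[4]))
      xa[, , seq_len(d[3]), ] <- x
      xa[, , d[3] + 1L, ] <- mv
      x <- xa
    }
    z <- conv_forward(x, p[[paste0("conv", k)]]$w, p[[paste0("conv", k)]]$b)
    if (spec$movement_mode == "global_scalar" && spec$injection_layer == k) {
      z <- sweep(z, 4L, mv, "+")
    }
    if (spec$bn_layer == k) {
      bf <- bn_forward(z, p$bn$gamma, p$bn$beta, p$bn$run_mean, p$bn$run_var,
                       train = train)
      if (keep == "cache") cache[[paste0("bn", k)]] <- bf
      cache$bn_stats <- bf[c("run_mean", "run_var")]
      zb <- bf$y
    } else {
      zb <- z
    }
    a <- relu_forward(zb)
    pf <- pool_forward(a)
    if (keep == "cache") {
      cache[[paste0("blk", k)]] <- list(x_in = x, zb = zb, pf = pf)
    }
    if (keep == "acts") acts[[paste0("L", k)]] <- a
    x <- pf$y
  }
  d <- dim(x)
  flat <- matrix(x, nrow = prod(d[1:3]))
  logits <- fc_forward(flat, p$fc$w, p$fc$b)
  probs <- softmax(logits)
  out <- list(probs = probs, logits = logits)
  if (keep == "cache") {
    cache$flat <- flat
    cache$flat_dim <- d
    out$cache <- cache
  }
  if (keep == "acts") out$acts <- acts
  out
}

#' Backward pass: gradients of the cross-entropy loss
#'
#' @param net a `cnn_net`.
#' @param cache the cache returned by [net_forward()] with `keep = "cache"`.
#' @param dlogits gradient at the logits (K x N), e.g. from [softmax_ce()],
#'   or an externally injected gradient for probing.
#' @param want_dinput also compute the gradient with respect to the visual
#'   input (needed for activation maximization, skipped during training).
#' @return list with `grads` (named like `net$params`) and `dinput`, the
#'   gradient with respect to the visual input (`NULL` unless requested).
#' @keywords internal
net_backward <- function(net, cache, dlogits, want_dinput = FALSE) {
  spec <- net$spec
  p <- net$params
  grads <- list()
  fb <- fc_backward(dlogits, cache$flat, p$fc$w)
  grads$fc <- list(w = fb$dw, b = fb$db)
  dx <- array(fb$dx, cache$flat_dim)
  for (k in rev(seq_len(spec$n_conv))) {
    blk <- cache[[paste0("blk", k)]]
    da <- pool_backward(dx, blk$pf)
    dzb <- relu_backward(da, blk$zb)
    if (spec$bn_layer == k) {
      bb <- bn_backward(dzb, cache[[paste0("bn", k)]], p$bn$gamma)
      grads$bn <- list(gamma = bb$dgamma, beta = bb$dbeta)
      dz <- bb$dx
    } else {
      dz <- dzb
    }
    in_shape <- dim(blk$x_in)
    cb <- conv_backward(blk$x_in, dz, p[[paste0("conv", k)]]$w,
                        want_dx = k > 1L || want_dinput)
    grads[[paste0("conv", k)]] <- list(w = cb$dw, b = cb$db)
    dx <- cb$dx
    if (!is.null(dx) && spec$movement_mode == "feature_image" &&
        spec$injection_layer == k) {
      dx <- dx[, , seq_len(in_shape[3] - 1L), , drop = FALSE]
    }
  }
  list(grads = grads, dinput = dx)
}

#' Per-layer channel activations
#'
#' Returns the post-ReLU activation tensor of a convolutional layer together
#' with the per-channel spatial means (the population-analysis unit used by
#' the representational analyses: each channel's activity averaged across its
#' entire unit grid).
#'
#' @param net a `cnn_net`.
#' @param x visual input (see [net_forward()]).
#' @param movement movement input, or `NULL`.
#' @param layer conv layer index (1-based).
#' @return list with `tensor` (H, W, C, N) and `channel_mean` (C x N).
#' @export
layer_activations <- function(net, x, movement = NULL, layer = 1L) {
  spec <- net$spec
  if (layer < 1L || layer > spec$n_conv) {
    stop("layer must be in 1..", spec$n_conv)
  }
  fw <- net_forward(net, x, movement, train = FALSE, keep = "acts")
  a <- fw$acts[[paste0("L", layer)]]
  d <- dim(a)
  cm <- matrix(colMeans(matrix(a, nrow = d[1] * d[2])), nrow = d[3])
  structure(list(layer = layer, tensor = a, channel_mean = cm),
            class = "layer_activations")
}

#' Predict class labels
#'
#' @param object a trained `cnn_net`.
#' @param x visual input.
#' @param movement movement input, or `NULL`.
#' @param ... unused.
#' @return integer vector of predicted labels (1..K).
#' @export
predict.cnn_net <- function(object, x, movement = NULL, ...) {
  pr <- net_forward(object, x, movement, train = FALSE)$probs
  apply(pr, 2L, which.max)
}
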