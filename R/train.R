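# Optimization: mini-batch SGD with momentum, categorical cross-entropy,
# early stopping on a held-out validation stream. Optimizer settings are a
# single shared configuration so that compared conditions differ only in the
# manipulated factor.

#' Training configuration
#'
#' @param max_epochs epoch cap (15 for quick runs, 55 to reach plateau).
#' @param batch_size mini-batch size.
#' @param lr learning rate (identical across all compared conditions).
#' @param momentum SGD momentum.
#' @param validation_frequency iterations between validation checks; `Inf`
#'   checks only at epoch boundaries.
#' @param stop_accuracy stop as soon as validation accuracy reaches this
#'   value (0.80 for the fixational task, about 0.20 for saccadic runs), or
#'   `NULL` to train to the epoch cap.
#' @param seed integer seed for batch shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(max_epochs = 15L, batch_size = 64L, lr = 0.01,
                         momentum = 0.9, validation_frequency = 700L,
                         stop_accuracy = NULL, seed = 1L) {
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum,
                 validation_frequency = validation_frequency,
                 stop_accuracy = stop_accuracy, seed = as.integer(seed)),
            class = "train_config")
}

slice_batch <- function(data, ix) {
  x <- data$x[, , ix, drop = FALSE]
  mv <- data$movement
  if (!is.null(mv)) {
    mv <- if (is.matrix(mv) || is.array(mv)) mv[, , ix, drop = FALSE] else mv[ix]
  }
  list(x = x, y = data$y[ix], movement = mv)
}

sgd_step <- function(params, grads, vel, lr, momentum) {
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      key <- paste(nm, f)
      v <- if (is.null(vel[[key]])) 0 else vel[[key]]
      v <- momentum * v - lr * grads[[nm]][[f]]
      vel[[key]] <- v
      params[[nm]][[f]] <- params[[nm]][[f]] + v
    }
  }
  list(params = params, vel = vel)
}

#' Train a network
#'
#' Mini-batch SGD with momentum on the categorical cross-entropy, validating
#' on the held-out set every `validation_frequency` iterations and at each
#' epoch end, with optional early stopping at `stop_accuracy`. A run whose
#' loss becomes non-finite is flagged (`diverged`), not silently dropped.
#'
#' @param net an untrained or pre-trained `cnn_net`.
#' @param dataset list with `train` and `test`, each a list of `x`
#'   (H x W x N array), `y` (labels 1..K), and optionally `movement`.
#' @param config a [train_config()].
#' @return list with `net` (trained), and `summary`: a `run_summary` with
#'   final train/validation/test accuracy, confusion matrix, history,
#'   `above_chance` flag and the seeds used.
#' @export
train_network <- function(net, dataset, config = train_config()) {
  stopifnot(inherits(net, "cnn_net"))
  tr <- dataset$train
  te <- dataset$test
  n <- length(tr$y)
  local_rng(config$seed)
  vel <- list()
  history <- list(iter = integer(), val_acc = numeric(),
                  epoch_loss = numeric())
  it <- 0L
  stopped <- FALSE
  diverged <- FALSE
  val_acc <- NA_real_
  check_val <- function() {
    ev <- evaluate_network(net, te)
    history$iter <<- c(history$iter, it)
    history$val_acc <<- c(history$val_acc, ev$accuracy)
    ev$accuracy
  }
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    losses <- numeric()
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      batch <- slice_batch(tr, b)
      fw <- net_forward(net, batch$x, batch$movement, train = TRUE,
                        keep = "cache")
      ce <- softmax_ce(fw$logits, batch$y)
      if (!is.finite(ce$loss)) {
        diverged <- TRUE
        break
      }
      losses <- c(losses, ce$loss)
      bw <- net_backward(net, fw$cache, ce$dz)
      st <- sgd_step(net$params, bw$grads, vel, config$lr, config$momentum)
      net$params <- st$params
      vel <- st$vel
      net$params$bn$run_mean <- fw$cache$bn_stats$run_mean
      net$params$bn$run_var <- fw$cache$bn_stats$run_var
      it <- it + 1L
      if (is.finite(config$validation_frequency) &&
          it %% config$validation_frequency == 0L) {
        val_acc <- check_val()
        if (!is.null(config$stop_accuracy) &&
            val_acc >= config$stop_accuracy) {
          stopped <- TRUE
          break
        }
      }
    }
    history$epoch_loss <- c(history$epoch_loss, mean(losses))
    if (diverged || stopped) break
    val_acc <- check_val()
    if (!is.null(config$stop_accuracy) && val_acc >= config$stop_accuracy) {
      stopped <- TRUE
      break
    }
  }
  ev <- evaluate_network(net, te)
  chance <- 1 / net$spec$n_classes
  se <- sqrt(chance * (1 - chance) / length(te$y))
  summary <- structure(list(
    test_accuracy = ev$accuracy,
    train_accuracy = evaluate_network(net, tr)$accuracy,
    confusion = ev$confusion,
    epochs_run = epoch,
    early_stopped = stopped,
    diverged = diverged,
    above_chance = !diverged && ev$accuracy > chance + 2 * se,
    chance = chance,
    history = history,
    init_seed = net$seed,
    shuffle_seed = config$seed
  ), class = "run_summary")
  net$history <- history
  list(net = net, summary = summary)
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(
    "run: test acc %.3f (chance %.3f, %s), %d epochs%s%s\n",
    x$test_accuracy, x$chance,
    if (x$above_chance) "above chance" else "at chance",
    x$epochs_run,
    if (x$early_stopped) ", early-stopped" else "",
    if (x$diverged) ", DIVERGED" else ""))
  invisible(x)
}

#' Evaluate a network on labelled data
#'
#' @param net a `cnn_net`.
#' @param data list with `x`, `y`, optionally `movement`.
#' @param batch_size evaluation batch size.
#' @return list with `accuracy` (= trace(confusion) / sum(confusion)),
#'   `confusion` (true x predicted, rows sum to per-class counts), and
#'   `pred`.
#' @export
evaluate_network <- function(net, data, batch_size = 256L) {
  n <- length(data$y)
  if (n == 0L) stop("empty dataset")
  pred <- integer(n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    batch <- slice_batch(data, b)
    pred[b] <- predict(net, batch$x, batch$movement)
  }
  k <- net$spec$n_classes
  confusion <- table(factor(data$y, levels = seq_len(k)),
                     factor(pred, levels = seq_len(k)))
  list(accuracy = mean(pred == data$y),
       confusion = unclass(confusion), pred = pred)
}

#' Replicate training over random weight initializations
#'
#' Re-trains the same architecture under `n_seeds` different weight
#' initializations (and shuffling streams), mirroring the practice of
#' repeated training runs to account for initialization variability.
#' Reports the accuracy distribution over all runs and over the
#' above-chance subset.
#'
#' @param dataset as in [train_network()], or a function of the replicate
#'   index returning such a dataset (a fresh stimulus draw per replicate,
#'   which averages dataset sampling error out of the replicate mean).
#' @param spec a [cnn_spec()].
#' @param config a [train_config()]; its seed field is re-derived per run.
#' @param n_seeds number of replicates (>= 2).
#' @param seed master seed from which per-run seeds are derived.
#' @return list with `summaries`, `accuracy` (vector), `mean`, `sd`,
#'   `frac_above_chance`, `mean_above`, `sd_above`.
#' @export
run_replicates <- function(dataset, spec, config = train_config(),
                           n_seeds = 10L, seed = 1L) {
  stopifnot(n_seeds >= 2L)
  summaries <- vector("list", n_seeds)
  nets <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    ds <- if (is.function(dataset)) dataset(i) else dataset
    net <- build_network(spec, derive_seed(seed, "init", i))
    cfg <- config
    cfg$seed <- derive_seed(seed, "shuffle", i)
    res <- train_network(net, ds, cfg)
    summaries[[i]] <- res$summary
    nets[[i]] <- res$net
  }
  acc <- vapply(summaries, function(s) s$test_accuracy, 0)
  above <- vapply(summaries, function(s) isTRUE(s$above_chance), TRUE)
  list(summaries = summaries, nets = nets, accuracy = acc,
       mean = mean(acc), sd = stats::sd(acc),
       frac_above_chance = mean(above),
       mean_above = if (any(above)) mean(acc[above]) else NA_real_,
       sd_above = if (sum(above) > 1) stats::sd(acc[above]) else NA_real_,
       above_chance = above)
}
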