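# Experiment orchestration: named, reproducible experiment recipes driven
# by a config (R list or YAML file) and a master seed, with results and a
# manifest written to a directory. Every source of randomness derives from
# the master seed via derive_seed(), so a run is reproducible from
# config + seed alone.

#' Default configuration for a named experiment
#'
#' @param experiment one of `"fixational_constant"`, `"fixational_modulated"`,
#'   `"global_scalar"`, `"phosphene"`, `"saccadic"`, `"gratings"`.
#' @param seed master seed.
#' @return config list (serializable to YAML).
#' @export
experiment_config <- function(experiment = c("fixational_constant",
                                             "fixational_modulated",
                                             "global_scalar", "phosphene",
                                             "saccadic", "gratings"),
                              seed = 1L) {
  experiment <- match.arg(experiment)
  base <- list(experiment = experiment, seed = as.integer(seed),
               n_seeds = 10L, lr = 0.01, batch_size = 64L)
  extra <- switch(experiment,
    fixational_constant = list(n = 800L, max_epochs = 20L, edge_mode = "wrap"),
    fixational_modulated = list(n = 800L, max_epochs = 40L,
                                stop_accuracy = 0.80, edge_mode = "wrap"),
    global_scalar = list(n = 800L, max_epochs = 40L, injection_layer = 2L,
                         edge_mode = "wrap", fraction = 0.25),
    phosphene = list(n_per_class = 100L, max_epochs = 30L,
                     stop_accuracy = 0.80),
    saccadic = list(n_train_per_class = 100L, n_test_per_class = 50L,
                    source_size = 15L, frame = 3L, shift_range = 4L,
                    max_epochs = 12L, lr = 0.035, fraction = 0.25,
                    n_seeds = 10L),
    gratings = list(n_train_per_class = 400L, n_test_gratings = 300L,
                    grating_fraction = 5e-4, source_size = 15L, frame = 3L,
                    max_epochs = 10L)
  )
  utils::modifyList(base, extra)
}

read_experiment_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$experiment))
  utils::modifyList(experiment_config(config$experiment,
                                      seed = config$seed %||% 1L), config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a named experiment end to end
#'
#' Generates the stimuli, trains the network replicates, runs the
#' experiment's analysis, and (optionally) writes result CSV/JSON files and
#' a manifest into `out_dir`.
#'
#' @param config config list or path to a YAML file (see
#'   [experiment_config()]).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return result list (also serialized when `out_dir` is given).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cfg <- read_experiment_config(config)
  res <- switch(cfg$experiment,
    fixational_constant = run_fixational(cfg, "constant"),
    fixational_modulated = run_fixational(cfg, "modulated"),
    global_scalar = run_global_scalar(cfg),
    phosphene = run_phosphene(cfg),
    saccadic = run_saccadic(cfg),
    gratings = run_gratings(cfg)
  )
  res$config <- cfg
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(res$summary_stats, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(res$table)) {
      utils::write.csv(res$table, file.path(out_dir, "results.csv"),
                       row.names = FALSE)
    }
    manifest <- list(
      experiment = cfg$experiment, seed = cfg$seed,
      config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
      files = list.files(out_dir))
    manifest$files <- union(manifest$files, "manifest.json")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}

run_fixational <- function(cfg, mode) {
  ds <- generate_fixational_dataset(cfg$n, mode,
                                    seed = derive_seed(cfg$seed, "data"),
                                    edge_mode = cfg$edge_mode)
  spec <- cnn_spec(c(28L, 28L), n_classes = 3L)
  tc <- train_config(max_epochs = cfg$max_epochs, batch_size = cfg$batch_size,
                     lr = cfg$lr, validation_frequency = Inf,
                     stop_accuracy = cfg$stop_accuracy)
  reps <- run_replicates(ds, spec, tc, n_seeds = cfg$n_seeds, seed = cfg$seed)
  tab <- data.frame(seed = seq_len(cfg$n_seeds), accuracy = reps$accuracy,
                    above_chance = reps$above_chance)
  list(replicates = reps, table = tab,
       summary_stats = list(mode = mode,
                            mean_accuracy = reps$mean, sd_accuracy = reps$sd,
                            bayes_ceiling = fixational_bayes_accuracy(
                              if (mode == "none") "constant" else mode,
                              cfg$edge_mode)))
}

run_global_scalar <- function(cfg) {
  ds <- generate_fixational_dataset(cfg$n, "none",
                                    seed = derive_seed(cfg$seed, "data"),
                                    edge_mode = cfg$edge_mode)
  spec <- cnn_spec(c(28L, 28L), n_classes = 3L,
                   movement_mode = "global_scalar",
                   injection_layer = cfg$injection_layer)
  # scalar amplitude: shift times a fraction of the layer's amplitude range
  probe_net <- build_network(cnn_spec(c(28L, 28L), n_classes = 3L),
                             derive_seed(cfg$seed, "probe"))
  rng <- estimate_amplitude_range(probe_net, ds$train,
                                  layer = cfg$injection_layer,
                                  seed = derive_seed(cfg$seed, "amp"))
  scl <- movement_scale(rng, max_shift = 2L, fraction = cfg$fraction)
  for (part in c("train", "test")) {
    ds[[part]]$movement <- scl * ds[[part]]$shifts
  }
  tc <- train_config(max_epochs = cfg$max_epochs, batch_size = cfg$batch_size,
                     lr = cfg$lr, validation_frequency = Inf,
                     stop_accuracy = 0.80)
  reps <- run_replicates(ds, spec, tc, n_seeds = cfg$n_seeds, seed = cfg$seed)
  tab <- data.frame(seed = seq_len(cfg$n_seeds), accuracy = reps$accuracy,
                    above_chance = reps$above_chance)
  list(replicates = reps, table = tab,
       summary_stats = list(injection_layer = cfg$injection_layer,
                            scale = scl, mean_accuracy = reps$mean,
                            sd_accuracy = reps$sd,
                            frac_above_chance = reps$frac_above_chance))
}

run_phosphene <- function(cfg) {
  tr <- make_pattern_set(cfg$n_per_class, seed = derive_seed(cfg$seed, "tr"))
  te <- make_pattern_set(max(20L, cfg$n_per_class %/% 2L),
                         seed = derive_seed(cfg$seed, "te"))
  ds <- list(train = list(x = tr$images, y = tr$labels),
             test = list(x = te$images, y = te$labels))
  spec <- cnn_spec(c(28L, 28L), n_classes = 6L)
  tc <- train_config(max_epochs = cfg$max_epochs, batch_size = cfg$batch_size,
                     lr = cfg$lr, validation_frequency = Inf,
                     stop_accuracy = cfg$stop_accuracy)
  res <- train_network(build_network(spec, derive_seed(cfg$seed, "init")),
                       ds, tc)
  spot <- make_focal_spot()
  p_vis <- visual_report_probability(res$net, spot)
  probs <- net_forward(res$net, array(spot, c(28L, 28L, 1L)))$probs[, 1L]
  list(net = res$net, summary = res$summary,
       table = data.frame(channel = seq_len(6L), probability = probs,
                          is_visual = seq_len(6L) <= 4L),
       summary_stats = list(test_accuracy = res$summary$test_accuracy,
                            visual_report_probability = unname(p_vis),
                            min_channel_probability = min(probs)))
}

saccadic_base_sets <- function(cfg) {
  list(train = surrogate_dataset(cfg$n_train_per_class, 10L,
                                 source_size = cfg$source_size,
                                 frame = cfg$frame,
                                 seed = derive_seed(cfg$seed, "base_tr")),
       test = surrogate_dataset(cfg$n_test_per_class, 10L,
                                source_size = cfg$source_size,
                                frame = cfg$frame,
                                seed = derive_seed(cfg$seed, "base_te")))
}

#' Assemble the saccadic training/test streams for one condition
#'
#' @param cfg saccadic experiment config.
#' @param condition `"congruent"`, `"incongruent"` or `"none"`.
#' @param scale movement amplitude scale.
#' @keywords internal
saccadic_streams <- function(cfg, condition, scale) {
  base <- saccadic_base_sets(cfg)
  list(train = generate_saccadic_trials(base$train, cfg$shift_range, condition,
                                        scale = scale,
                                        seed = derive_seed(cfg$seed, "tr_trials")),
       test = generate_saccadic_trials(base$test, cfg$shift_range, condition,
                                       scale = scale,
                                       seed = derive_seed(cfg$seed, "te_trials")))
}

run_saccadic <- function(cfg) {
  scale <- movement_scale(c(0, 255), max_shift = cfg$shift_range,
                          fraction = cfg$fraction)
  S <- cfg$source_size + 2L * cfg$frame
  spec <- cnn_spec(c(S, S), n_classes = 10L, movement_mode = "feature_image")
  tc <- train_config(max_epochs = cfg$max_epochs, batch_size = cfg$batch_size,
                     lr = cfg$lr, validation_frequency = Inf)
  out <- list()
  for (cond in c("congruent", "incongruent")) {
    ds <- saccadic_streams(cfg, cond, scale)
    # same master seed for both conditions: initializations are paired, so
    # the two pools differ only in the movement images
    reps <- run_replicates(ds, spec, tc, n_seeds = cfg$n_seeds,
                           seed = cfg$seed)
    out[[cond]] <- reps
  }
  tab <- do.call(rbind, lapply(names(out), function(cond) {
    data.frame(condition = cond, seed = seq_along(out[[cond]]$accuracy),
               accuracy = out[[cond]]$accuracy,
               above_chance = out[[cond]]$above_chance)
  }))
  list(replicates = out, table = tab, scale = scale,
       summary_stats = list(
         congruent_mean = out$congruent$mean,
         incongruent_mean = out$incongruent$mean,
         congruent_frac_above = out$congruent$frac_above_chance,
         incongruent_frac_above = out$incongruent$frac_above_chance))
}

run_gratings <- function(cfg) {
  S <- cfg$source_size + 2L * cfg$frame
  base <- surrogate_dataset(cfg$n_train_per_class, 10L,
                            source_size = cfg$source_size, frame = cfg$frame,
                            seed = derive_seed(cfg$seed, "base"))
  n_img <- length(base$labels)
  n_gr <- max(1L, floor(cfg$grating_fraction * n_img))
  local_rng(derive_seed(cfg$seed, "gr_tr"))
  g_ori <- rep_len(1:6, n_gr)
  g_imgs <- array(0, c(S, S, n_gr))
  for (j in seq_len(n_gr)) {
    g_imgs[, , j] <- make_grating(g_ori[j], cfg$source_size, cfg$frame)
  }
  x <- array(0, c(S, S, n_img + n_gr))
  x[, , seq_len(n_img)] <- base$images
  x[, , n_img + seq_len(n_gr)] <- g_imgs
  y <- c(base$labels, 10L + g_ori)          # 16 classes
  te_base <- surrogate_dataset(max(10L, cfg$n_train_per_class %/% 4L), 10L,
                               source_size = cfg$source_size,
                               frame = cfg$frame,
                               seed = derive_seed(cfg$seed, "base_te"))
  local_rng(derive_seed(cfg$seed, "gr_te"))
  nt <- cfg$n_test_gratings
  t_ori <- rep_len(1:6, nt)
  t_imgs <- array(0, c(S, S, nt))
  for (j in seq_len(nt)) {
    t_imgs[, , j] <- make_grating(t_ori[j], cfg$source_size, cfg$frame)
  }
  # test datastore is mostly gratings (90%), plus some images
  n_imgte <- min(length(te_base$labels), ceiling(nt / 9))
  xt <- array(0, c(S, S, nt + n_imgte))
  xt[, , seq_len(nt)] <- t_imgs
  xt[, , nt + seq_len(n_imgte)] <- te_base$images[, , seq_len(n_imgte)]
  yt <- c(10L + t_ori, te_base$labels[seq_len(n_imgte)])
  spec <- cnn_spec(c(S, S), n_classes = 16L)
  tc <- train_config(max_epochs = cfg$max_epochs, batch_size = cfg$batch_size,
                     lr = cfg$lr, validation_frequency = Inf)
  ds <- list(train = list(x = x, y = y), test = list(x = xt, y = yt))
  res <- train_network(build_network(spec, derive_seed(cfg$seed, "init")), ds, tc)
  # whole-network accuracy on gratings alone
  gr_eval <- evaluate_network(res$net, list(x = t_imgs, y = 10L + t_ori))
  oa <- orientation_analysis(res$net,
                             list(images = t_imgs, orientation = t_ori),
                             seed = derive_seed(cfg$seed, "lda"))
  lda_acc <- vapply(oa, function(l) l$lda_accuracy, 0)
  list(net = res$net, summary = res$summary, orientation = oa,
       table = data.frame(layer = seq_along(lda_acc), lda_accuracy = lda_acc),
       summary_stats = list(
         grating_fraction = n_gr / (n_img + n_gr),
         network_grating_accuracy = gr_eval$accuracy,
         lda_accuracy = as.list(stats::setNames(lda_acc,
                                                paste0("L", seq_along(lda_acc)))),
         prop_tuned = vapply(oa, function(l) l$prop_tuned, 0)))
}
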