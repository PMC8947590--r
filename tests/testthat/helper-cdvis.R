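# Shared fixtures. Expensive trained objects are built once per test run
# and memoized here so that unit tests and the acceptance checks can share
# them.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# A small trained fixational network (modulated amplitudes, learns quickly).
trained_fixational <- function() {
  memo("fix_net", {
    ds <- generate_fixational_dataset(400L, "modulated", seed = 303L)
    spec <- cnn_spec(c(28L, 28L), n_classes = 3L)
    cfg <- train_config(max_epochs = 15L, validation_frequency = Inf,
                        stop_accuracy = 0.85, seed = 7L)
    res <- train_network(build_network(spec, 11L), ds, cfg)
    list(net = res$net, summary = res$summary, ds = ds)
  })
}

# Tiny untrained feature-image network for geometry/plumbing tests.
tiny_feature_net <- function() {
  memo("tiny_net", {
    spec <- cnn_spec(c(21L, 21L), n_classes = 10L,
                     movement_mode = "feature_image")
    build_network(spec, 5L)
  })
}

# The saccadic study pool (both conditions + plateau extensions), shared by
# all saccadic property checks. The master seed is the study seed.
study_pool <- function() {
  memo("saccadic_pool", saccadic_pool(seed = 11L))
}

study_properties <- function() {
  memo("saccadic_props", saccadic_properties(study_pool(), seed = 11L))
}

# Balanced synthetic channel-activation clusters: k classes, n per class,
# class centres separated by `sep` in a `p`-dimensional feature space.
synthetic_clusters <- function(k = 4L, n = 30L, p = 12L, sep = 4,
                               seed = 1L) {
  set.seed(seed)
  centres <- matrix(rnorm(k * p), k) * sep
  X <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(rnorm(n * p), n) + centres[rep(i, n), ]
  }))
  list(features = t(X), labels = rep(seq_len(k), each = n))
}
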