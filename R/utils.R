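# Seed plumbing shared by the generators, trainers and analyses.

local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(seed)
}

#' Derive a stage seed from a master seed
#'
#' Experiments draw all randomness from a single master seed; each stage
#' (data generation, weight initialization, batch shuffling, embeddings)
#' uses a distinct derived seed so stages can be varied independently while
#' remaining reproducible. Derived seeds stay below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage tag.
#' @param i optional replicate index.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage, i = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 2654435 + i * 97003) %% 2147483629)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
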