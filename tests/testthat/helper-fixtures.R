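# Shared fixtures: the polyurethane gel layers of the standing-wave
# experiments and a two-layer skin-like sample builder.

gel2mm <- function() AcousticLayer(2, sound_speed = 1389, impedance = 1.6)
gel4mm <- function() AcousticLayer(4, sound_speed = 1389, impedance = 1.6)

# bulk with glucose bands (990/1110 cm^-1) under a collagen-like top layer
# with protein bands (1030/1080 cm^-1)
skin_fixture <- function(glucose = 90, coef = 0.06, top = TRUE) {
  bulk <- LayerOptics(1000, water_fraction = 0.8,
                      bands = absorptionBands(c(990, 1110), width = 8,
                                              amplitude = coef * glucose))
  top_layer <- if (top)
    LayerOptics(15, water_fraction = 0.2,
                bands = absorptionBands(c(1030, 1080), width = 10,
                                        amplitude = 120))
  LayeredSample(bulk, top_layer = top_layer)
}

# fivefold pipeline accuracy on a generated dataset (Q2-selected components),
# memoised so several tests can share the same 20-seed sweep
.acc_cache <- new.env(parent = emptyenv())
pipeline_accuracy <- function(mode, seeds) {
  key <- paste0(mode, "-", paste(seeds, collapse = ","))
  if (is.null(.acc_cache[[key]])) {
    .acc_cache[[key]] <- vapply(seeds, function(s) {
      ds <- generateDataset(80, mode, noise = noiseParams(mode, seed = s))
      f <- preprocessDataset(ds)
      sel <- q2LOO(f$X, f$y)
      kfoldAccuracy(f$X, f$y, n_latent = sel$chosen_lv, seed = s)$mean_accuracy
    }, numeric(1))
  }
  .acc_cache[[key]]
}

# noiseless separable toy classification problem: class shifts one feature
separable_xy <- function(n = 20, p = 5, delta = 1) {
  y <- rep(c(0L, 1L), length.out = n)
  # deterministic full-rank base, small against the class shift
  X <- 0.2 * outer(seq_len(n), seq_len(p), function(i, j) sin(i * j / 3))
  X[, 1] <- X[, 1] + delta * y
  list(X = X, y = y)
}
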