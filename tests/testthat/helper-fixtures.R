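# Shared fixtures: tiny model configurations, small synthetic tasks, and an
# independent scalar softmax used by the hand oracles.

tiny_config <- function(n_classes = 2L, n_channels = 2L, seq_len = 4L,
                        frame_dim = 8L, n_layers = 2L, n_heads = 2L,
                        d_model = 8L, d_ff = 16L, dropout = 0,
                        seed = 3L, ...) {
  model_config(n_classes = n_classes, n_channels = n_channels,
               seq_len = seq_len, frame_dim = frame_dim, n_layers = n_layers,
               n_heads = n_heads, d_model = d_model, d_ff = d_ff,
               dropout = dropout, seed = seed, ...)
}

tiny_frames <- function(B = 3L, cfg = tiny_config(), seed = 42L) {
  set.seed(seed)
  array(rnorm(B * cfg$n_channels * cfg$seq_len * cfg$frame_dim),
        c(B, cfg$n_channels, cfg$seq_len, cfg$frame_dim))
}

# small two-class band-signature task (alpha- vs theta-dominant)
mini_task <- function(epochs_per_class = 20L, n_channels = 2L, seed = 11L) {
  spec <- synth_spec(n_channels = n_channels, fs = 256, seed = seed)
  synthetic_task(spec, epochs_per_class = epochs_per_class)
}

# independent row softmax written out longhand for oracle computations
oracle_softmax_row <- function(v) {
  e <- exp(v)
  e / sum(e)
}

# RMS helper
rms <- function(x) sqrt(mean(x^2))
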