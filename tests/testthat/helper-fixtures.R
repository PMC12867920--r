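# Shared fixtures: tiny configurations and a small cached dataset.

tiny_tcn <- function(channels = 4, out_dim = 6, dilations = c(1, 2)) {
  tcn_config(kernel_size = 2, dilations = dilations, channels = channels,
             out_dim = out_dim)
}

tiny_enc <- function(input_dim = 6, model_dim = 8, heads = 2, ffn = 12,
                     layers = 2, dropout = 0, positional = TRUE) {
  encoder_config(n_layers = layers, heads = heads, model_dim = model_dim,
                 ffn_dim = ffn, input_dim = input_dim, dropout = dropout,
                 positional = positional)
}

tiny_model <- function(seed = 9, feature_idx = 1:6, head_hidden = c(5, 4),
                       dropout = 0) {
  cogload_model(tiny_tcn(), tiny_enc(dropout = dropout),
                feature_idx = feature_idx, head_hidden = head_hidden,
                seed = seed)
}

tiny_seq <- function(frames = 12, difficulty = 3, seed = 11, noise_sd = 0.02) {
  generate_sequence(gen_config(n_sequences = 1, frames_per_seq = frames,
                               noise_sd = noise_sd),
                    difficulty, seed = seed)
}

# A coordinate array where only the listed joints move, with the given total
# path lengths (one straight step each); everything else is static.
path_coords <- function(path_lengths, frames = 2) {
  coords <- array(0, c(frames, 25, 3))
  for (j in seq_along(path_lengths)) {
    coords[frames, j, 1] <- path_lengths[j]
    if (frames > 2) {
      coords[, j, 1] <- seq(0, path_lengths[j], length.out = frames)
    }
  }
  coords
}

local_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(gen_config(n_sequences = 30,
                                            frames_per_seq = 30, seed = 4))
    }
    cache
  }
})
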