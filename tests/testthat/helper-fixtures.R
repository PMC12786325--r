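# Small, fast synthetic fixtures shared across test files.

# Compact recording spec: few electrodes, 2.5 kHz, short duration.
tiny_spec <- function(n_electrodes = 2, duration_s = 20, n_active = 1,
                      fs = 2500, seed = 1L, ...) {
  recording_spec(n_electrodes = n_electrodes, fs = fs,
                 duration_s = duration_s, n_active = n_active,
                 noise_sd = 10, seed = seed, ...)
}

# White-noise recording built directly (no 1/f background).
white_rec <- function(n_electrodes = 1, fs = 2500, duration_s = 20,
                      sd = 1, seed = 1L, condition = NULL) {
  set.seed(seed)
  new_recording(matrix(rnorm(n_electrodes * fs * duration_s, sd = sd),
                       nrow = n_electrodes),
                fs = fs, condition = condition)
}

# Hand-built feature object for classifier unit tests.
toy_features <- function(x, labels, groups = seq_len(nrow(x))) {
  colnames(x) <- sprintf("f%d", seq_len(ncol(x)))
  structure(list(x = x, labels = factor(labels), groups = groups,
                 electrodes = 0L, bin_hz = 1,
                 bin_lo = seq_len(ncol(x)) - 1),
            class = "lfp_features")
}
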