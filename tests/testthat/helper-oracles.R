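# Independent periodogram oracle: mean power of x in [f1, f2] Hz, computed
# directly from the DFT, never through the package's wavelet path.
periodogram_band_power <- function(x, fs, band) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * fs
  keep <- f >= band[1] & f <= band[2] & f <= fs / 2
  mean(Mod(X[keep])^2) / n
}

# Amplitude of a sinusoidal component at frequency f0 (direct projection).
component_amplitude <- function(x, fs, f0) {
  t <- (seq_along(x) - 1) / fs
  2 * Mod(mean(x * exp(-2i * pi * f0 * t)))
}

# Small, fast simulation configuration shared across tests.
tiny_sim <- function(...) {
  sim_config(n_subjects = 2, trials_per_block = 16, blocks_per_depth = 1,
             fs_raw = 2000, ...)
}
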