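# Shared fixtures, built in code at test time.

# A minimal schedule: one trial per cue x CTI cell, all valid.
tiny_schedule <- function(seed = 1) {
  generate_schedule(schedule_config(n_per_cell = 1, n_valid_per_cell = 1),
                    seed = seed)
}

# Noise-free EEG spec (templates only).
silent_eeg_spec <- function(...) {
  eeg_spec(background_power = 0, alpha_power = 0, gamma_power = 0, ...)
}

# Hand-made ERP waveform on an explicit time grid (seconds).
make_erp <- function(values, times) {
  structure(list(values = values, times = times, n_trials = 1,
                 roi = "synthetic"),
            class = "erp_waveform")
}

# Hand-made epochs: data = list of channels x samples matrices.
make_epochs <- function(data, times, sfreq, channels,
                        alignment = "target_onset", info = NULL) {
  info <- info %||% data.frame(trial_index = seq_along(data))
  posnertacs:::new_eeg_epochs(data, times, sfreq, channels, alignment, info)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Balanced long-format mixed-design dataset with optional planted
# group x session shift (applied to active post cells).
make_mixed_data <- function(n_per_group = 9, n_tt = 4, shift = 0,
                            seed = 1) {
  posnertacs:::with_seed(seed, {
    d <- expand.grid(subject = sprintf("s%02d", seq_len(2 * n_per_group)),
                     session = c("pre", "post"),
                     trial_type = paste0("T", seq_len(n_tt)),
                     stringsAsFactors = TRUE)
    d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= n_per_group,
                      "sham", "active")
    d$y <- rnorm(nrow(d)) +
      shift * (d$group == "active") * (d$session == "post")
    d
  })
}

# Fraction of spectral energy of `x` inside [lo, hi] Hz times its variance:
# an FFT-based band-variance oracle independent of the multitaper code.
fft_band_variance <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- Mod(fft(x - mean(x)))^2 / n^2
  f <- seq(0, n - 1) * fs / n
  sum(X[f >= lo & f <= hi | f >= fs - hi & f <= fs - lo])
}
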