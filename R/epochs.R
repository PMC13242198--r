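#' EEG generation parameters
#'
#' Describes the synthetic 32-channel EEG: a scale-free background with a
#' target detrended-fluctuation exponent, band-limited alpha (8-12 Hz) and
#' gamma (30-45 Hz) processes with controllable band variance, and
#' target-locked N1 (negative) and P3 (positive) Gaussian-windowed ERP
#' templates. `effect_spec` describes what changes in the active group's
#' post-stimulation session: alpha power down, gamma power up, background
#' exponent down, template amplitude/latency shifts.
#'
#' @param channels channel labels (default: the 32-label montage).
#' @param sampling_rate Hz; must be at least twice the upper gamma edge
#'   (90 Hz) so the gamma band is representable. Defaults to 256 for
#'   desk-scale work; higher rates (e.g. 1200) are supported.
#' @param background_power background variance, uV^2.
#' @param alpha_power,gamma_power per-channel band variances, uV^2.
#' @param background_alpha target DFA exponent of the background, in (0, 2).
#' @param n1_amp_uv,n1_latency_ms,n1_width_ms N1 template: peak amplitude
#'   (negative), centre latency and Gaussian SD width.
#' @param p3_amp_uv,p3_latency_ms,p3_width_ms P3 template (positive peak).
#' @param effect_spec named list: `alpha_power_ratio`, `gamma_power_ratio`,
#'   `background_alpha_delta`, `n1_amp_delta_uv`, `p3_amp_delta_uv`,
#'   `n1_latency_shift_ms`, `p3_latency_shift_ms`; applied to active-group
#'   post sessions only.
#' @return List of class `eeg_spec`.
#' @export
eeg_spec <- function(channels = default_montage()$label,
                     sampling_rate = 256,
                     background_power = 20,
                     alpha_power = 10,
                     gamma_power = 2,
                     background_alpha = 0.85,
                     n1_amp_uv = -3, n1_latency_ms = 140, n1_width_ms = 18,
                     p3_amp_uv = 4, p3_latency_ms = 320, p3_width_ms = 45,
                     effect_spec = list(alpha_power_ratio = 0.7,
                                        gamma_power_ratio = 1.5,
                                        background_alpha_delta = -0.1,
                                        n1_amp_delta_uv = -1,
                                        p3_amp_delta_uv = 1,
                                        n1_latency_shift_ms = 0,
                                        p3_latency_shift_ms = -15)) {
  if (sampling_rate < 2 * 45)
    stop("sampling_rate must be >= 90 Hz so the gamma band (30-45 Hz) is representable")
  if (background_alpha <= 0 || background_alpha >= 2)
    stop("background_alpha must lie in (0, 2)")
  if (alpha_power < 0 || gamma_power < 0 || background_power < 0)
    stop("band/background powers must be >= 0")
  structure(list(channels = channels, sampling_rate = sampling_rate,
                 background_power = background_power,
                 alpha_power = alpha_power, gamma_power = gamma_power,
                 background_alpha = background_alpha,
                 n1_amp_uv = n1_amp_uv, n1_latency_ms = n1_latency_ms,
                 n1_width_ms = n1_width_ms,
                 p3_amp_uv = p3_amp_uv, p3_latency_ms = p3_latency_ms,
                 p3_width_ms = p3_width_ms,
                 effect_spec = effect_spec),
            class = "eeg_spec")
}

# Internal constructor for the epoch container.
new_eeg_epochs <- function(data, times, sfreq, channels, alignment, info) {
  structure(list(data = data, times = times, sfreq = sfreq,
                 channels = channels, alignment = alignment, info = info),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d channels, %g Hz, aligned to %s\n",
              length(x$data), length(x$channels), x$sfreq, x$alignment))
  invisible(x)
}

#' Subset epochs by trial
#'
#' @param epochs an `eeg_epochs` object.
#' @param which logical or integer index into trials (evaluated against
#'   `epochs$info` rows).
#' @return An `eeg_epochs` with the selected trials.
#' @export
subset_epochs <- function(epochs, which) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  new_eeg_epochs(epochs$data[which], epochs$times, epochs$sfreq,
                 epochs$channels, epochs$alignment,
                 epochs$info[which, , drop = FALSE])
}

#' Stack equal-length epochs into a trials x channels x samples array
#' @param epochs an `eeg_epochs` object whose trials share one length.
#' @return 3-D numeric array.
#' @export
epochs_array <- function(epochs) {
  ns <- unique(vapply(epochs$data, ncol, integer(1)))
  if (length(ns) != 1)
    stop("epochs have unequal lengths; cannot stack")
  arr <- array(NA_real_, c(length(epochs$data), length(epochs$channels), ns))
  for (i in seq_along(epochs$data)) arr[i, , ] <- epochs$data[[i]]
  dimnames(arr) <- list(NULL, epochs$channels, NULL)
  arr
}

gauss_template <- function(times_s, amp, center_ms, width_ms) {
  amp * exp(-0.5 * ((times_s * 1000 - center_ms) / width_ms)^2)
}

#' Simulate multichannel EEG epochs for one session
#'
#' For every trial of `schedule` two segments are produced: a cue-aligned
#' CTI segment of length `cti_s` and a target-locked segment spanning -0.1
#' to 0.5 s. Each channel's scale-free background is drawn as one
#' continuous series per session and sliced across trials, so long-range
#' temporal correlations persist across concatenated CTI segments;
#' band-limited alpha and gamma noise at the specified band variances is
#' added per segment, and polarity-correct N1/P3 Gaussian templates are
#' added to target-locked segments. The template topography is zero-mean
#' across channels — full amplitude over the parieto-occipital ROI with a
#' small compensating counter-polarity elsewhere, as for a dipolar source —
#' so common-average re-referencing leaves ROI-averaged component
#' amplitudes unchanged. For `group = "active"`, `session = "post"` the
#' `effect_spec` modifiers are applied.
#'
#' @param schedule a [generate_schedule()] result.
#' @param spec an [eeg_spec()].
#' @param subject,group,session labels stored in the trial info.
#' @param seed integer RNG seed.
#' @return List with elements `cti` and `target`, each an `eeg_epochs`.
#' @export
simulate_epochs <- function(schedule, spec = eeg_spec(),
                            subject = "s01", group = "sham",
                            session = "pre", seed = 1L) {
  stopifnot(inherits(spec, "eeg_spec"))
  fs <- spec$sampling_rate
  post_active <- identical(group, "active") && identical(session, "post")
  ef <- spec$effect_spec
  a_pow <- spec$alpha_power * if (post_active) ef$alpha_power_ratio %||% 1 else 1
  g_pow <- spec$gamma_power * if (post_active) ef$gamma_power_ratio %||% 1 else 1
  bg_alpha <- spec$background_alpha +
    if (post_active) ef$background_alpha_delta %||% 0 else 0
  n1_amp <- spec$n1_amp_uv + if (post_active) ef$n1_amp_delta_uv %||% 0 else 0
  p3_amp <- spec$p3_amp_uv + if (post_active) ef$p3_amp_delta_uv %||% 0 else 0
  n1_lat <- spec$n1_latency_ms +
    if (post_active) ef$n1_latency_shift_ms %||% 0 else 0
  p3_lat <- spec$p3_latency_ms +
    if (post_active) ef$p3_latency_shift_ms %||% 0 else 0

  n_tgt <- round(0.6 * fs)
  t_tgt <- seq(0, n_tgt - 1) / fs - 0.1
  n_cti <- round(schedule$cti_s * fs)
  n_per_trial <- n_cti + n_tgt
  n_total <- sum(n_per_trial)
  nch <- length(spec$channels)
  erp <- gauss_template(t_tgt, n1_amp, n1_lat, spec$n1_width_ms) +
    gauss_template(t_tgt, p3_amp, p3_lat, spec$p3_width_ms)
  # zero-mean dipolar topography: ROI channels carry the full template
  roi <- intersect(erp_roi(), spec$channels)
  topo <- if (length(roi) > 0 && length(roi) < nch) {
    w <- rep(-length(roi) / (nch - length(roi)), nch)
    w[spec$channels %in% roi] <- 1
    w
  } else rep(1, nch)
  erp_map <- outer(topo, erp)

  with_seed(seed, {
    cti_data <- vector("list", nrow(schedule))
    tgt_data <- vector("list", nrow(schedule))
    # continuous per-channel backgrounds spanning the whole session
    bg <- if (spec$background_power > 0 && n_total > 0) {
      vapply(seq_len(nch), function(ch)
        scalefree_raw(n_total, bg_alpha, spec$background_power),
        numeric(n_total))
    } else matrix(0, max(n_total, 1), nch)
    offset <- 0L
    for (i in seq_len(nrow(schedule))) {
      len <- n_per_trial[i]
      seg <- matrix(0, nch, len)
      for (ch in seq_len(nch)) {
        x <- bg[(offset + 1):(offset + len), ch]
        if (a_pow > 0) x <- x + bandlimited_raw(len, fs, c(8, 12), a_pow)
        if (g_pow > 0) x <- x + bandlimited_raw(len, fs, c(30, 45), g_pow)
        seg[ch, ] <- x
      }
      offset <- offset + len
      cti_data[[i]] <- seg[, seq_len(n_cti[i]), drop = FALSE]
      tgt <- seg[, (n_cti[i] + 1):len, drop = FALSE]
      tgt_data[[i]] <- tgt + erp_map
    }
    info <- data.frame(subject = subject, group = group, session = session,
                       trial_index = schedule$index,
                       cue_type = schedule$cue_type,
                       validity = schedule$validity,
                       trial_type = trial_type_label(schedule$cue_type,
                                                     schedule$validity),
                       cti_s = schedule$cti_s, stringsAsFactors = FALSE)
    list(cti = new_eeg_epochs(cti_data, NULL, fs, spec$channels,
                              "cue_onset", info),
         target = new_eeg_epochs(tgt_data, t_tgt, fs, spec$channels,
                                 "target_onset", info))
  })
}
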