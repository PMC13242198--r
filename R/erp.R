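#' Component analysis windows for N1 and P3
#'
#' N1 is the negative target-evoked deflection quantified over 90-200 ms,
#' P3 the positive deflection over 250-400 ms (closed intervals).
#'
#' @param name "N1" or "P3".
#' @return List of class `component_window` with `name`, `t_lo`, `t_hi`
#'   (seconds) and `polarity`.
#' @export
component_window <- function(name = c("N1", "P3")) {
  name <- match.arg(name)
  if (name == "N1")
    structure(list(name = "N1", t_lo = 0.090, t_hi = 0.200,
                   polarity = "negative"), class = "component_window")
  else
    structure(list(name = "P3", t_lo = 0.250, t_hi = 0.400,
                   polarity = "positive"), class = "component_window")
}

# Zero-phase FIR low-pass: windowed-sinc (Hamming), transition band from
# `cutoff` to 1.25*cutoff, >= 53 dB stopband. Linear-phase kernel applied
# centred (sides = 2) after reflection padding, so no group delay.
fir_lowpass_kernel <- function(fs, cutoff) {
  transition <- 0.25 * cutoff
  order <- ceiling(3.3 * fs / transition)
  if (order %% 2 == 1) order <- order + 1
  wc <- (cutoff + transition / 2) / (fs / 2)   # mid-transition cutoff
  signal::fir1(order, wc, type = "low")
}

filter_zero_phase <- function(x, kernel) {
  half <- (length(kernel) - 1) / 2
  n <- length(x)
  pad_l <- 2 * x[1] - x[pmin(n, seq(half + 1, 2))]
  pad_r <- 2 * x[n] - x[pmax(1, seq(n - 1, n - half))]
  ext <- c(pad_l, x, pad_r)
  y <- stats::filter(ext, kernel, method = "convolution", sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

#' Preprocess target-locked epochs for ERP analysis
#'
#' Fixed processing order: (1) re-reference to the common average
#' (per-sample channel-mean subtraction), (2) zero-phase FIR low-pass at
#' `lp_cutoff`, (3) per-channel linear detrend over the epoch. All three
#' steps are linear; the order is fixed so outputs are bit-stable.
#'
#' @param epochs target-aligned `eeg_epochs`.
#' @param lp_cutoff low-pass cutoff in Hz (default 30); must be below
#'   Nyquist after accounting for the filter transition band.
#' @return Preprocessed `eeg_epochs`.
#' @export
preprocess_epochs <- function(epochs, lp_cutoff = 30) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (1.25 * lp_cutoff >= epochs$sfreq / 2)
    stop("lp_cutoff too close to Nyquist for sampling rate ", epochs$sfreq)
  kernel <- fir_lowpass_kernel(epochs$sfreq, lp_cutoff)
  data <- lapply(epochs$data, function(seg) {
    seg <- sweep(seg, 2, colMeans(seg), "-")           # common average ref
    filt <- t(apply(seg, 1, filter_zero_phase, kernel = kernel))
    t(detrend_linear(t(filt)))                         # per-channel detrend
  })
  new_eeg_epochs(data, epochs$times, epochs$sfreq, epochs$channels,
                 epochs$alignment, epochs$info)
}

#' Extract a ROI-averaged, baseline-corrected ERP waveform
#'
#' Trials are averaged, the average is collapsed across the region-of-
#' interest channels, and the mean over the baseline interval is
#' subtracted.
#'
#' @param epochs target-aligned `eeg_epochs` (equal trial lengths).
#' @param roi channel labels to average (default [erp_roi()]).
#' @param baseline numeric length 2, baseline interval in seconds
#'   (default c(-0.1, 0)).
#' @return List of class `erp_waveform`: `values` (uV), `times` (s),
#'   `n_trials`, `roi`.
#' @export
extract_erp <- function(epochs, roi = erp_roi(), baseline = c(-0.1, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"), !is.null(epochs$times))
  missing_ch <- setdiff(roi, epochs$channels)
  if (length(missing_ch) > 0)
    stop("ROI channel(s) not present in epochs: ",
         paste(missing_ch, collapse = ", "))
  if (length(epochs$data) == 0) stop("no trials to average")
  arr <- epochs_array(epochs)
  avg <- apply(arr, c(2, 3), mean)                 # channels x samples
  wave <- colMeans(avg[match(roi, epochs$channels), , drop = FALSE])
  bl <- epochs$times >= baseline[1] & epochs$times <= baseline[2]
  if (!any(bl)) stop("baseline interval contains no samples")
  wave <- wave - mean(wave[bl])
  structure(list(values = wave, times = epochs$times,
                 n_trials = length(epochs$data), roi = roi),
            class = "erp_waveform")
}

window_samples <- function(times, window) {
  step <- stats::median(diff(times))
  idx <- which(times >= window$t_lo - step / 2 & times <= window$t_hi + step / 2)
  if (length(idx) == 0 || window$t_lo < times[1] - step / 2 ||
      window$t_hi > times[length(times)] + step / 2)
    stop("component window [", window$t_lo, ", ", window$t_hi,
         "] s lies outside the epoch span")
  idx
}

#' Mean amplitude within a component window
#'
#' Arithmetic mean of the waveform over the closed window; chosen over
#' peak measures for stability. Membership uses nearest-sample alignment
#' within half a sample step.
#'
#' @param erp an `erp_waveform`.
#' @param window a [component_window()].
#' @return Mean amplitude in uV.
#' @export
mean_amplitude <- function(erp, window) {
  stopifnot(inherits(erp, "erp_waveform"), inherits(window, "component_window"))
  mean(erp$values[window_samples(erp$times, window)])
}

#' Fractional-area latency of a component
#'
#' The waveform is rectified (absolute value) within the window, its
#' cumulative trapezoidal area computed, and the latency returned as the
#' linearly interpolated time at which the cumulative area reaches
#' `fraction` of the total (FAL50 at the default `fraction = 0.5`;
#' fractions such as 0.25 and 0.75 support sensitivity checks).
#'
#' @param erp an `erp_waveform`.
#' @param window a [component_window()].
#' @param fraction target fraction of total rectified area, in (0, 1).
#' @return Latency in ms.
#' @export
fractional_area_latency <- function(erp, window, fraction = 0.5) {
  stopifnot(inherits(erp, "erp_waveform"), fraction > 0, fraction < 1)
  idx <- window_samples(erp$times, window)
  t <- erp$times[idx]
  r <- abs(erp$values[idx])
  cum <- cumtrapz(t, r)
  total <- cum[length(cum)]
  if (total <= 0)
    stop("total rectified area in the window is zero; latency undefined")
  target <- fraction * total
  i <- which(cum >= target)[1]
  if (i == 1) return(t[1] * 1000)
  # linear interpolation within the bracketing sample interval
  t_lat <- t[i - 1] + (target - cum[i - 1]) / (cum[i] - cum[i - 1]) *
    (t[i] - t[i - 1])
  t_lat * 1000
}

#' Component measures for one ERP waveform
#'
#' @param erp an `erp_waveform`.
#' @param components component names to measure (default N1 and P3).
#' @param fraction fractional-area latency fraction.
#' @return data.frame `component`, `mean_amp_uv`, `fal_ms`, `fraction`.
#' @export
component_measures <- function(erp, components = c("N1", "P3"),
                               fraction = 0.5) {
  out <- lapply(components, function(nm) {
    w <- component_window(nm)
    data.frame(component = nm,
               mean_amp_uv = mean_amplitude(erp, w),
               fal_ms = fractional_area_latency(erp, w, fraction),
               fraction = fraction)
  })
  do.call(rbind, out)
}

#' Time-resolved paired pre/post comparison of ERP waveforms
#'
#' Paired t-tests at every time point across subjects, with
#' Benjamini-Hochberg false-discovery-rate control across time points.
#'
#' @param waveforms_pre,waveforms_post numeric matrices, subjects x time,
#'   rows matched across sessions.
#' @param times optional time axis (s) for the output.
#' @param alpha FDR level for the significance mask (default 0.05).
#' @return data.frame `time`, `t`, `p`, `p_adj`, `sig`.
#' @export
timewise_tests <- function(waveforms_pre, waveforms_post, times = NULL,
                           alpha = 0.05) {
  stopifnot(is.matrix(waveforms_pre), is.matrix(waveforms_post),
            all(dim(waveforms_pre) == dim(waveforms_post)))
  n <- nrow(waveforms_pre)
  if (n < 2) stop("paired inference needs at least 2 subjects")
  d <- waveforms_post - waveforms_pre
  m <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  tval <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, Inf * sign(m)))
  p <- 2 * stats::pt(abs(tval), df = n - 1, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(time = times %||% seq_len(ncol(d)), t = tval, p = p,
             p_adj = p_adj, sig = p_adj < alpha)
}
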