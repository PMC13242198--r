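# Cache DPSS computations per (n, nw, k): the tridiagonal eigenproblem is
# the expensive step and epoch lengths repeat heavily across trials.
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Tapers are computed as eigenvectors of the standard symmetric
#' tridiagonal matrix whose eigenvectors coincide with the DPSS, then
#' polarity-normalized and scaled to unit energy. In-band spectral
#' concentrations (the eigenvalues of the sinc kernel) are computed
#' explicitly so low-concentration tapers can be rejected.
#'
#' @param n taper length in samples.
#' @param nw time-half-bandwidth product.
#' @param k number of tapers to return (default `floor(2 * nw)`).
#' @return List with `tapers` (n x k matrix, columns unit-energy) and
#'   `concentration` (length-k, in (0, 1), decreasing).
#' @export
dpss_tapers <- function(n, nw = 4, k = floor(2 * nw)) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  i <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  A <- diag(diag_main)
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  # unit energy; fix sign so each taper starts non-negative (even orders)
  # or has positive initial slope (odd orders)
  for (j in seq_len(k)) {
    tapers[, j] <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    if (sum(tapers[, j]) < 0 ||
        (abs(sum(tapers[, j])) < 1e-8 && tapers[2, j] - tapers[1, j] < 0))
      tapers[, j] <- -tapers[, j]
  }
  # concentration via the Toeplitz sinc kernel: lambda = v' S v
  d <- outer(i, i, "-")
  S <- sin(2 * pi * w * d) / (pi * d)
  diag(S) <- 2 * w
  conc <- vapply(seq_len(k), function(j)
    drop(crossprod(tapers[, j], S %*% tapers[, j])), numeric(1))
  out <- list(tapers = tapers, concentration = conc)
  .dpss_cache[[key]] <- out
  out
}

#' Spectral configuration for CTI band-power analysis
#'
#' The full smoothing bandwidth is `8 / T` Hz for a segment of length `T`
#' seconds, i.e. a time-half-bandwidth product NW = 4 regardless of the
#' CTI length, and only tapers with spectral concentration above
#' `concentration_min` (90%) are used — with NW = 4 that retains 7 tapers.
#'
#' @param bandwidth_num numerator of the full bandwidth rule (Hz * s).
#' @param concentration_min minimum in-band concentration, in (0, 1).
#' @param bands named list of `c(lo, hi)` band edges in Hz.
#' @return List of class `spectral_config`.
#' @export
spectral_config <- function(bandwidth_num = 8, concentration_min = 0.9,
                            bands = list(alpha = c(8, 12),
                                         gamma = c(30, 45))) {
  stopifnot(bandwidth_num > 0,
            concentration_min > 0, concentration_min < 1)
  structure(list(bandwidth_num = bandwidth_num,
                 concentration_min = concentration_min, bands = bands),
            class = "spectral_config")
}

#' Multitaper power spectral density of one segment
#'
#' The segment mean is subtracted, DPSS tapers with time-half-bandwidth
#' NW = T * bandwidth / 2 are computed, tapers with concentration below the
#' configured threshold are dropped, and the one-sided PSD (uV^2/Hz) is the
#' unweighted average of the tapered eigenspectra. The integral of the
#' density over frequency equals the segment variance (Parseval, up to
#' discretization).
#'
#' @param segment numeric vector (one channel, one CTI segment).
#' @param sampling_rate Hz.
#' @param config a [spectral_config()].
#' @return List of class `psd_result`: `frequencies` (Hz), `density`
#'   (uV^2/Hz, one-sided), `n_tapers_used`, `concentration`,
#'   `segment_length` (s).
#' @export
multitaper_psd <- function(segment, sampling_rate,
                           config = spectral_config()) {
  stopifnot(inherits(config, "spectral_config"), length(segment) >= 8)
  n <- length(segment)
  T_seg <- n / sampling_rate
  bw <- config$bandwidth_num / T_seg              # full bandwidth, Hz
  nw <- T_seg * bw / 2
  dp <- dpss_tapers(n, nw)
  keep <- dp$concentration > config$concentration_min
  if (!any(keep))
    stop("no DPSS taper exceeds the concentration threshold ",
         config$concentration_min)
  tapers <- dp$tapers[, keep, drop = FALSE]
  x <- segment - mean(segment)
  nf <- floor(n / 2) + 1
  spec <- matrix(0, nf, ncol(tapers))
  for (j in seq_len(ncol(tapers))) {
    X <- stats::fft(tapers[, j] * x)[seq_len(nf)]
    spec[, j] <- Mod(X)^2 / sampling_rate
  }
  dens <- rowMeans(spec)
  # one-sided: double all bins except DC and (for even n) Nyquist
  dbl <- rep(2, nf); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  dens <- dens * dbl
  structure(list(frequencies = seq(0, nf - 1) * sampling_rate / n,
                 density = dens, n_tapers_used = ncol(tapers),
                 concentration = dp$concentration[keep],
                 segment_length = T_seg),
            class = "psd_result")
}

#' Integrated band power from a PSD
#'
#' Trapezoidal integral of the one-sided density over the closed band
#' `[f_lo, f_hi]`, in uV^2.
#'
#' @param psd a `psd_result`.
#' @param band numeric length 2, band edges in Hz.
#' @return Band power (uV^2).
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_result"), length(band) == 2, band[1] < band[2])
  f <- psd$frequencies
  if (band[1] < min(f) || band[2] > max(f))
    stop("band [", band[1], ", ", band[2],
         "] Hz outside the resolved frequency axis")
  m <- f >= band[1] & f <= band[2]
  if (sum(m) < 2)
    stop("band contains fewer than two frequency bins at resolution ",
         signif(f[2] - f[1], 3), " Hz")
  trapz(f[m], psd$density[m])
}

#' Band power of CTI epochs, per trial and channel
#'
#' Convenience pipeline step: multitaper PSD and band integration of every
#' (trial, channel) CTI segment, averaged over trials per channel and band.
#'
#' @param epochs cue-aligned `eeg_epochs` (CTI segments).
#' @param config a [spectral_config()].
#' @return data.frame `channel`, `band`, `power_uv2`, `n_trials`.
#' @export
cti_band_power <- function(epochs, config = spectral_config()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  nch <- length(epochs$channels)
  bands <- config$bands
  acc <- matrix(0, nch, length(bands))
  for (seg in epochs$data) {
    for (ch in seq_len(nch)) {
      psd <- multitaper_psd(seg[ch, ], epochs$sfreq, config)
      for (b in seq_along(bands))
        acc[ch, b] <- acc[ch, b] + band_power(psd, bands[[b]])
    }
  }
  n_tr <- length(epochs$data)
  data.frame(channel = rep(epochs$channels, times = length(bands)),
             band = rep(names(bands), each = nch),
             power_uv2 = as.vector(acc) / max(n_tr, 1),
             n_trials = n_tr, stringsAsFactors = FALSE)
}
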