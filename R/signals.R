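# Frequency-domain synthesis shared by the scale-free and band-limited
# generators: build a real series whose spectrum has the requested amplitude
# profile with iid complex-Gaussian coefficients, then rescale to an exact
# sample variance.
synth_from_spectrum <- function(amp, n, variance) {
  nf <- length(amp)                       # rfft bins 0..floor(n/2)
  re <- stats::rnorm(nf) * amp
  im <- stats::rnorm(nf) * amp
  z <- complex(real = re, imaginary = im)
  z[1] <- 0                               # zero-mean series
  if (n %% 2 == 0) z[nf] <- complex(real = re[nf], imaginary = 0)
  full <- c(z, Conj(rev(z[2:(nf - (n %% 2 == 0))])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x * sqrt(variance) / s
}

#' Synthesize a scale-free (1/f-like) time series with a target DFA exponent
#'
#' Spectral-synthesis surrogate: Fourier amplitudes follow a power law
#' `S(f) ~ f^-(2*alpha - 1)` with random phases, which yields an expected
#' detrended-fluctuation scaling exponent equal to `target_alpha` over the
#' fit range (alpha = 0.5 is white noise, 1.5 integrated white noise). The
#' sample variance is scaled exactly to `variance`.
#'
#' @param n_samples series length (>= 512 so the default DFA window range
#'   up to 200 samples is well covered).
#' @param target_alpha desired scaling exponent, in (0, 2).
#' @param variance sample variance of the output.
#' @param seed integer RNG seed.
#' @return Numeric vector of length `n_samples`.
#' @export
#' @examples
#' x <- synthesize_scalefree_series(4096, target_alpha = 1.0, seed = 7)
#' dfa(x)$alpha  # ~1.0
synthesize_scalefree_series <- function(n_samples, target_alpha,
                                        variance = 1, seed = 1L) {
  if (target_alpha <= 0 || target_alpha >= 2)
    stop("target_alpha must lie strictly inside (0, 2)")
  if (n_samples < 512)
    stop("n_samples must be >= 512")
  with_seed(seed,
            scalefree_raw(n_samples, target_alpha, variance))
}

# Unseeded core (callers manage RNG state); no length floor so the epoch
# generator can draw short continuous slices.
scalefree_raw <- function(n, target_alpha, variance) {
  beta <- 2 * target_alpha - 1            # spectral exponent: S(f) ~ f^-beta
  f <- seq(0, floor(n / 2)) / n
  amp <- c(0, f[-1]^(-beta / 2))
  synth_from_spectrum(amp, n, variance)
}

# Band-limited Gaussian noise with exact sample variance, spectrum flat on
# [band[1], band[2]] Hz. Returns zeros if no rfft bin falls inside the band.
bandlimited_raw <- function(n, fs, band, variance) {
  f <- seq(0, floor(n / 2)) * fs / n
  amp <- as.numeric(f >= band[1] & f <= band[2])
  if (sum(amp) == 0 || variance == 0) return(rep(0, n))
  synth_from_spectrum(amp, n, variance)
}
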