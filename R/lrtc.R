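#' Default DFA window-size grid
#'
#' Approximately 15 log-spaced unique integer window sizes spanning 25 to
#' 200 samples.
#'
#' @param n_lo,n_hi range of window sizes in samples.
#' @param n_points number of (approximately) log-spaced sizes.
#' @return Integer vector, sorted ascending.
#' @export
dfa_default_grid <- function(n_lo = 25, n_hi = 200, n_points = 15) {
  unique(round(exp(seq(log(n_lo), log(n_hi), length.out = n_points))))
}

#' Detrended fluctuation analysis
#'
#' Estimates the scaling exponent alpha of long-range temporal
#' correlations. The series is mean-subtracted and cumulatively summed to a
#' profile; for each window size n the profile is partitioned (from the
#' start) into `floor(N/n)` contiguous non-overlapping segments, each
#' segment is detrended by its least-squares line, and the root-mean-square
#' fluctuation F(n) is taken over the covered samples. Alpha is the
#' ordinary-least-squares slope of log F(n) versus log n over the grid;
#' alpha = 0.5 indicates an uncorrelated series, larger values persistent
#' correlations.
#'
#' @param series numeric vector with non-zero variance, length at least
#'   `2 * max(n_grid)`.
#' @param n_grid integer window sizes (default [dfa_default_grid()]).
#' @return List of class `dfa_result`: `n`, `fluctuation`, `alpha`,
#'   `fit_r2`.
#' @export
#' @examples
#' x <- rnorm(4000)
#' dfa(x)$alpha  # ~0.5
dfa <- function(series, n_grid = dfa_default_grid()) {
  n_grid <- sort(unique(as.integer(n_grid)))
  if (any(n_grid < 4)) stop("window sizes must be >= 4 samples")
  N <- length(series)
  if (N < 2 * max(n_grid))
    stop("series length ", N, " is below 2 x max window size (",
         2 * max(n_grid), ")")
  if (stats::sd(series) == 0)
    stop("series is constant; fluctuation undefined")
  y <- cumsum(series - mean(series))
  f <- vapply(n_grid, function(n) {
    m <- N %/% n
    Y <- matrix(y[seq_len(m * n)], nrow = n)        # segments in columns
    res <- detrend_linear(Y)
    sqrt(sum(res^2) / (m * n))
  }, numeric(1))
  lx <- log(n_grid)
  ly <- log(f)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- unname(fit$coefficients[2])
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  structure(list(n = n_grid, fluctuation = f, alpha = alpha, fit_r2 = r2),
            class = "dfa_result")
}

#' DFA of CTI epochs, per channel
#'
#' Individual CTI segments can be shorter than twice the largest DFA
#' window, so segments of the same condition are pooled before analysis:
#' in `"concatenate"` mode (default) all segments of a channel are joined
#' end to end and analysed as one series; `"per_epoch"` mode analyses each
#' segment separately (restricting the grid to windows the segment can
#' hold) and averages the exponents.
#'
#' @param epochs cue-aligned `eeg_epochs`.
#' @param n_grid DFA window sizes.
#' @param mode `"concatenate"` or `"per_epoch"`.
#' @return data.frame `channel`, `alpha`, `fit_r2`, `n_samples`.
#' @export
cti_dfa <- function(epochs, n_grid = dfa_default_grid(),
                    mode = c("concatenate", "per_epoch")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  mode <- match.arg(mode)
  nch <- length(epochs$channels)
  out <- lapply(seq_len(nch), function(ch) {
    if (mode == "concatenate") {
      x <- unlist(lapply(epochs$data, function(seg) seg[ch, ]))
      r <- dfa(x, n_grid)
      data.frame(channel = epochs$channels[ch], alpha = r$alpha,
                 fit_r2 = r$fit_r2, n_samples = length(x))
    } else {
      res <- lapply(epochs$data, function(seg) {
        x <- seg[ch, ]
        grid <- n_grid[n_grid <= length(x) %/% 2]
        if (length(grid) < 4) return(NULL)
        dfa(x, grid)
      })
      res <- res[!vapply(res, is.null, logical(1))]
      if (length(res) == 0)
        stop("no CTI segment is long enough for the requested window grid")
      data.frame(channel = epochs$channels[ch],
                 alpha = mean(vapply(res, `[[`, numeric(1), "alpha")),
                 fit_r2 = mean(vapply(res, `[[`, numeric(1), "fit_r2")),
                 n_samples = sum(vapply(epochs$data, function(s) ncol(s),
                                        integer(1))))
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
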