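#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed from a parent seed and a label, so
# every stage of a pipeline run has its own independent, reproducible stream.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label, ":")) * seq_along(utf8ToInt(paste0(label, ":"))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cumulative trapezoidal integral of y over x (same length as y, starts at 0).
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Remove per-column best-fit line (used for per-channel/segment detrending).
detrend_linear <- function(y) {
  n <- NROW(y)
  t <- seq_len(n) - (n + 1) / 2            # centred time axis
  if (is.matrix(y)) {
    slope <- colSums(t * y) / sum(t * t)
    sweep(y - outer(t, slope), 2, colMeans(y), "-")
  } else {
    slope <- sum(t * y) / sum(t * t)
    y - t * slope - mean(y)
  }
}
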