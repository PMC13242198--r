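test_that("low-pass kernel meets its passband and stopband design", {
  h <- posnertacs:::fir_lowpass_kernel(256, 30)
  gain <- function(f) Mod(sum(h * exp(-2i * pi * f / 256 *
                                        seq_along(h))))
  expect_lt(abs(gain(5) - 1), 0.01)          # 5 Hz preserved within 1%
  expect_lt(20 * log10(gain(45)), -20)       # >= 20 dB down at 45 Hz
  expect_lt(20 * log10(gain(45)), -50)       # windowed-sinc reaches ~53 dB
  expect_lt(abs(gain(0) - 1), 0.005)         # near-unit DC gain
})

test_that("zero-phase filtering introduces no delay", {
  t <- seq(0, 2, by = 1 / 256)
  x <- sin(2 * pi * 5 * t)
  h <- posnertacs:::fir_lowpass_kernel(256, 30)
  y <- posnertacs:::filter_zero_phase(x, h)
  mid <- 100:400
  fit <- lm(y[mid] ~ x[mid])
  expect_lt(abs(coef(fit)[2] - 1), 0.01)     # in phase, unit gain
})

test_that("preprocessing annihilates DC-offset-only epochs", {
  offs <- matrix(c(3, -1, 4), nrow = 3, ncol = 160)
  ep <- make_epochs(list(offs, 2 * offs), times = seq_len(160) / 256 - 0.1,
                    sfreq = 256, channels = c("a", "b", "c"))
  out <- preprocess_epochs(ep)
  expect_lt(max(abs(unlist(out$data))), 1e-9)
})

test_that("preprocess rejects cutoffs at or above Nyquist", {
  ep <- make_epochs(list(matrix(0, 2, 64)), seq_len(64) / 128, 128,
                    c("a", "b"))
  expect_error(preprocess_epochs(ep, lp_cutoff = 60), "Nyquist")
})

test_that("extract_erp reduces correctly in degenerate cases", {
  times <- seq(-0.1, 0.5, by = 1 / 250)
  tmpl <- -3 * exp(-0.5 * ((times - 0.14) / 0.018)^2)
  trial <- rbind(tmpl, tmpl / 2)
  ep <- make_epochs(list(trial, trial, trial), times, 250, c("Pz", "O1"))
  # identical trials: ERP equals any single trial after baseline correction
  erp <- extract_erp(ep, roi = c("Pz", "O1"))
  one <- colMeans(trial)
  expect_equal(erp$values, one - mean(one[times <= 0]), tolerance = 1e-12)
  expect_equal(erp$n_trials, 3)
  # single-channel ROI equals that channel's trial average
  erp1 <- extract_erp(ep, roi = "O1")
  expect_equal(erp1$values, trial[2, ] - mean(trial[2, times <= 0]),
               tolerance = 1e-12)
  expect_error(extract_erp(ep, roi = c("Pz", "Cz")), "Cz")
})

test_that("extracted ERPs have zero baseline mean", {
  sch <- generate_schedule(schedule_config(n_per_cell = 2,
                                           n_valid_per_cell = 2), seed = 1)
  eps <- simulate_epochs(sch, eeg_spec(), seed = 2)
  erp <- extract_erp(preprocess_epochs(eps$target))
  bl <- erp$times >= -0.1 & erp$times <= 0
  expect_lt(abs(mean(erp$values[bl])), 1e-9)
})

test_that("mean amplitude is an arithmetic window mean and is linear", {
  times <- seq(-100, 500, by = 5) / 1000    # window edges on the grid
  const <- make_erp(rep(2, length(times)), times)
  expect_equal(mean_amplitude(const, component_window("N1")), 2)
  expect_equal(mean_amplitude(const, component_window("P3")), 2)

  piece <- make_erp(ifelse(times >= 0.090 & times <= 0.145, -4, 0), times)
  expect_equal(mean_amplitude(piece, component_window("N1")), -2,
               tolerance = 0.15)             # half the window at -4

  set.seed(77)
  v <- rnorm(length(times))
  erp <- make_erp(v, times)
  w <- component_window("N1")
  idx <- which(times >= w$t_lo & times <= w$t_hi)
  expect_equal(mean_amplitude(erp, w), sum(v[idx]) / length(idx),
               tolerance = 1e-12)
  # linearity and shift equivariance
  expect_equal(mean_amplitude(make_erp(3 * v, times), w),
               3 * mean_amplitude(erp, w), tolerance = 1e-12)
  expect_equal(mean_amplitude(make_erp(v + 1.5, times), w),
               mean_amplitude(erp, w) + 1.5, tolerance = 1e-12)
})

test_that("mean amplitude rejects windows outside the epoch", {
  short <- make_erp(rnorm(26), seq(0, 0.1, by = 0.004))
  expect_error(mean_amplitude(short, component_window("P3")), "outside")
})

test_that("fractional-area latency matches closed forms", {
  times <- seq(-100, 500, by = 4) / 1000   # grid hits 150 ms exactly
  wc <- structure(list(name = "box", t_lo = 0.100, t_hi = 0.200,
                       polarity = "negative"), class = "component_window")
  # symmetric pulse centred in a symmetric window -> FAL50 at the centre
  pulse <- make_erp(-exp(-0.5 * ((times - 0.150) / 0.012)^2), times)
  expect_equal(fractional_area_latency(pulse, wc, 0.5), 150,
               tolerance = 1e-9)
  # constant magnitude on [100, 200] ms: cumulative area is linear
  box <- make_erp(rep(-2, length(times)), times)
  expect_equal(fractional_area_latency(box, wc, 0.25), 125, tolerance = 1e-6)
  expect_equal(fractional_area_latency(box, wc, 0.75), 175, tolerance = 1e-6)
})

test_that("fractional-area latency matches a dense-grid oracle", {
  # asymmetric triangle: rises 90->120 ms, falls 120->200 ms
  tri_fun <- function(t) {
    y <- numeric(length(t))
    up <- t >= 0.09 & t <= 0.12
    dn <- t > 0.12 & t <= 0.2
    y[up] <- (t[up] - 0.09) / 0.03
    y[dn] <- (0.2 - t[dn]) / 0.08
    -y
  }
  times <- seq(-0.1, 0.5, by = 1 / 256)
  w <- component_window("N1")
  got <- fractional_area_latency(make_erp(tri_fun(times), times), w, 0.5)
  # brute-force cumulative integration on a 100x denser grid
  dense <- seq(0.09, 0.2, length.out = 30000)
  r <- abs(tri_fun(dense))
  cum <- cumsum((r[-1] + r[-length(r)]) / 2 * diff(dense))
  oracle <- dense[which(cum >= 0.5 * cum[length(cum)])[1]] * 1000
  expect_lt(abs(got - oracle), 1000 / 256 / 2)   # within half a sample
})

test_that("fractional-area latency is monotone with limiting behaviour", {
  times <- seq(-0.1, 0.5, by = 1 / 256)
  set.seed(5)
  erp <- make_erp(rnorm(length(times)), times)
  w <- component_window("P3")
  fr <- c(0.01, 0.25, 0.5, 0.75, 0.99)
  lat <- vapply(fr, function(f) fractional_area_latency(erp, w, f),
                numeric(1))
  expect_true(all(diff(lat) >= 0))
  expect_lt(lat[1] - 250, 5)
  expect_lt(400 - lat[5], 5)
  zero <- make_erp(rep(0, length(times)), times)
  expect_error(fractional_area_latency(zero, w), "zero")
})

test_that("time-resolved paired tests behave at the null and under signal", {
  times <- seq(-0.1, 0.5, by = 1 / 128)
  nt <- length(times)
  pre <- matrix(rnorm(9 * nt), 9, nt)
  # identical sessions: no point survives
  res0 <- timewise_tests(pre, pre, times)
  expect_false(any(res0$sig))
  expect_true(all(res0$p_adj == 1))

  # +5 uV shift on [250, 400] ms, unit noise: detected nearly everywhere
  set.seed(12)
  win <- times >= 0.25 & times <= 0.4
  post <- matrix(rnorm(9 * nt), 9, nt) +
    5 * matrix(win, 9, nt, byrow = TRUE)
  res1 <- timewise_tests(matrix(rnorm(9 * nt), 9, nt), post, times)
  expect_gte(mean(res1$sig[win]), 0.9)
  expect_error(timewise_tests(pre[1, , drop = FALSE],
                              pre[1, , drop = FALSE]), "2 subjects")
})

test_that("FDR keeps the null false-discovery proportion controlled", {
  set.seed(9)
  nt <- 80
  fdp <- replicate(200, {
    a <- matrix(rnorm(9 * nt), 9, nt)
    b <- matrix(rnorm(9 * nt), 9, nt)
    r <- timewise_tests(a, b)
    if (any(r$sig)) 1 else 0       # all discoveries are false under the null
  })
  # BH bounds the expected FDP by 0.05; allow 2.5 binomial SEs of MC noise
  expect_lte(mean(fdp), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 200))
})

test_that("component_measures returns both components in one table", {
  sch <- tiny_schedule()
  erp <- extract_erp(simulate_epochs(sch, silent_eeg_spec(),
                                     seed = 1)$target)
  cm <- component_measures(erp)
  expect_equal(cm$component, c("N1", "P3"))
  expect_lt(cm$mean_amp_uv[1], 0)
  expect_gt(cm$mean_amp_uv[2], 0)
  expect_true(all(cm$fal_ms >= c(90, 250) & cm$fal_ms <= c(200, 400)))
})
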