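test_that("bandpass analytic signal has unit gain, zero phase and sharp skirts", {
  fs <- 1000
  t <- (0:1999) / fs
  mid <- 300:1700  # away from epoch edges

  z <- analytic_signal(sin(2 * pi * 60 * t + 0.4), fs, 60)
  expect_equal(mean(Mod(z)[mid]), 1, tolerance = 0.02)
  # instantaneous frequency = centre (unwrap via circular median of steps)
  step <- diff(Arg(z)[mid])
  expect_equal(median(step), 2 * pi * 60 / fs, tolerance = 1e-3)

  # >= 40 dB attenuation at centre +/- 3 halfwidths
  amp_at <- function(f) {
    zz <- analytic_signal(sin(2 * pi * f * t), fs, 60, halfwidth = 3.5)
    mean(Mod(zz)[mid])
  }
  expect_lt(amp_at(60 + 3 * 3.5) / amp_at(60), 10^(-40 / 20))
  expect_lt(amp_at(60 - 3 * 3.5) / amp_at(60), 10^(-40 / 20))

  # zero group delay: in/out cross-correlation of a passband sine peaks at 0
  x <- sin(2 * pi * 60 * t)
  cc <- ccf(Re(analytic_signal(x, fs, 60))[mid], x[mid], lag.max = 5,
            plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(analytic_signal(x, fs, 499), "Nyquist")
})

test_that("coherence is 1 for scaled reference copies and vanishes for null data", {
  fs <- 1000
  time <- seq(-0.5, 0.999, by = 1 / fs)
  refm <- matrix(sin(2 * pi * 60 * time + 0.3), 20, length(time),
                 byrow = TRUE)
  zr <- analytic_signal(refm, fs, 60)
  mid <- which(time > -0.2 & time < 0.7)

  co <- coherence_timecourse(analytic_signal(4.2 * refm, fs, 60), zr)
  expect_equal(max(abs(co[mid] - 1)), 0, tolerance = 1e-10)

  # amplitude rescaling invariance of the estimator itself
  set.seed(12)
  zm <- analytic_signal(matrix(rnorm(20 * length(time)), 20), fs, 60)
  expect_equal(coherence_timecourse(zm, zr),
               coherence_timecourse(7 * zm, 0.3 * zr), tolerance = 1e-12)

  # bounded by 1 under a constant-amplitude reference
  expect_true(all(coherence_timecourse(zm, zr) <= 1 + 1e-12))

  # uniformly rotated phases with fixed amplitude average toward zero
  ph <- runif(20, -pi, pi)
  zrot <- exp(1i * ph) * matrix(1, 20, 50)
  zone <- matrix(1 + 0i, 20, 50)
  expect_lt(mean(coherence_timecourse(zrot, zone)), 0.35)

  # null level decreases with trial count (Monte-Carlo trend)
  null_level <- function(n) {
    set.seed(n)
    zn <- analytic_signal(matrix(rnorm(n * length(time)), n), fs, 60)
    zrn <- analytic_signal(matrix(refm[1, ], n, length(time), byrow = TRUE),
                           fs, 60)
    mean(coherence_timecourse(zn, zrn)[mid])
  }
  lev <- vapply(c(10, 50, 200), null_level, 0)
  expect_true(all(diff(lev) < 0))

  expect_error(coherence_timecourse(zm[1, , drop = FALSE],
                                    zr[1, , drop = FALSE]), "2 trials")
})

test_that("coherence TFR shows the tag ridge during search and the evoked onset burst", {
  cfg <- small_config(seed = 14, n_blocks = 2, trials_per_block = 10,
                      n_sensors = 1, signal_sensors = 1, snr = 1.2,
                      evoked_amplitude = 0)
  e <- generate_experiment(cfg, layouts = FALSE)
  freqs <- seq(52, 74, by = 2)
  tfr <- coherence_tfr(e$recording, freqs = freqs, sensors = 1)
  tv <- e$recording$time
  search <- tv >= 0.15 & tv <= 0.5
  pre <- tv <= -0.2
  row60 <- which(freqs == 60)
  prof <- rowMeans(tfr$values[1, , search])
  expect_equal(which.max(prof), row60)
  # ridge absent before onset
  expect_lt(mean(tfr$values[1, row60, pre]),
            mean(tfr$values[1, row60, search]) / 2)

  # evoked transient only: broadband elevation near t = 0 across rows
  cfg0 <- small_config(seed = 15, n_blocks = 2, trials_per_block = 10,
                       n_sensors = 1, signal_sensors = 1, snr = 0,
                       evoked_amplitude = 4)
  e0 <- generate_experiment(cfg0, layouts = FALSE)
  tfr0 <- coherence_tfr(e0$recording, freqs = freqs, sensors = 1)
  onset <- tv >= 0 & tv <= 0.15
  late <- tv >= 0.3 & tv <= 0.5
  expect_gt(mean(tfr0$values[1, , onset]), mean(tfr0$values[1, , late]))
})

test_that("condition coherence averages the counterbalanced splits symmetrically", {
  cfg <- small_config(seed = 20, n_blocks = 2, trials_per_block = 16,
                      n_sensors = 1, signal_sensors = 1, snr = 1)
  e <- generate_experiment(cfg, layouts = FALSE)
  a <- condition_coherence(e$recording, e$trials, "target", sensors = 1)
  expect_equal(a$n_trials, c(8, 8))

  # relabelling every trial's colour-frequency map (swap colours and the
  # map together) leaves the role-averaged series unchanged
  tr2 <- e$trials
  tr2$target_colour <- ifelse(e$trials$target_colour == "yellow",
                              "cyan", "yellow")
  tr2$freq_yellow <- e$trials$freq_cyan
  tr2$freq_cyan <- e$trials$freq_yellow
  b <- condition_coherence(e$recording, tr2, "target", sensors = 1)
  expect_equal(a$values, b$values, tolerance = 1e-12)

  expect_error(condition_coherence(e$recording, e$trials[1:2, ], "target"),
               "fewer than 2")
})
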