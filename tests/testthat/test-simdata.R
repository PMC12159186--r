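test_that("trial counts and blocking match the configured design", {
  cfg <- sim_config(n_blocks = 24, trials_per_block = 40)
  expect_equal(cfg$n_blocks * cfg$trials_per_block, 960)

  e <- generate_experiment(small_config(seed = 3), layouts = FALSE)
  tr <- e$trials
  expect_equal(nrow(tr), 32)
  tab <- table(tr$condition, tr$set_size)
  expect_true(all(tab == 8))
  # half present / half absent within every block
  per_block <- tapply(tr$target_present, tr$block, mean)
  expect_true(all(per_block == 0.5))
  # tot spans [0,1] monotonically in trial index
  expect_equal(range(tr$tot), c(0, 1))
  expect_true(all(diff(tr$tot[order(tr$trial_index)]) >= 0))
})

test_that("colour-frequency assignment is a counterbalanced bijection", {
  e <- generate_experiment(small_config(seed = 11), layouts = FALSE)
  tr <- e$trials
  expect_true(all(tr$freq_yellow != tr$freq_cyan))
  expect_true(all(sort(unique(c(tr$freq_yellow, tr$freq_cyan))) == c(60, 67)))
  # exact balance: each colour tagged at each frequency in half the trials
  expect_equal(mean(tr$freq_yellow == 60), 0.5)
  # guided blocks keep a constant target colour, unguided randomise it
  g <- tr[tr$condition == "guided", ]
  expect_true(all(tapply(g$target_colour, g$block,
                         function(x) length(unique(x))) == 1))
})

test_that("seed determinism gives bit-identical experiments", {
  cfg <- small_config(seed = 99)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$recording$data, e2$recording$data)
  expect_identical(e1$trials, e2$trials)
  expect_identical(e1$gaze[[1]]$x, e2$gaze[[1]]$x)
  e3 <- generate_experiment(small_config(seed = 100), layouts = FALSE)
  expect_false(identical(e1$recording$data, e3$recording$data))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(tag_freqs = c(60, 60)), "distinct")
  expect_error(sim_config(tag_freqs = c(60, 600)), "Nyquist")
  expect_error(sim_config(trials_per_block = 7), "even")
  expect_error(sim_config(boost_gain = 0), "positive")
  expect_error(sim_config(seed = NA), "seed")
})

test_that("reference generator matches its contract", {
  r <- make_reference(60, phase = 0, duration = 0.5, fs = 1000)
  expect_equal(r[1], 0)                     # sin(0) at t = 0
  expect_gt(max(abs(r)), 0.995)  # unit amplitude up to sampling phase
  expect_error(make_reference(600, 0, 0.5, fs = 1000), "alias")

  set.seed(5); a <- make_reference(60, 0, 1, 1000, noise_amplitude = 0.05)
  set.seed(5); b <- make_reference(60, 0, 1, 1000, noise_amplitude = 0.05)
  expect_identical(a, b)
  # residual noise has the configured scale
  resid <- a - make_reference(60, 0, 1, 1000)
  expect_equal(sd(resid), 0.05, tolerance = 0.05)
})

test_that("noiseless tag component peaks at the tag frequency bin", {
  cfg <- small_config(seed = 2, snr = 2, white_noise_sd = 0,
                      evoked_amplitude = 0)
  e <- generate_experiment(cfg, layouts = FALSE)
  tr <- e$trials[1, ]
  # reconstruct the noiseless carrier the generator added and check its
  # Welch spectrum peaks at the planted frequency
  time <- e$recording$time
  f1 <- 60
  carrier <- sin(2 * pi * f1 * time) * (time >= 0)
  spec <- spectrum(carrier[time >= 0], plot = FALSE)
  fpk <- spec$freq[which.max(spec$spec)] * cfg$sampling_rate
  expect_lt(abs(fpk - f1), 2)
})

test_that("planted effects order the trial-averaged coherence by gain", {
  cfg <- small_config(seed = 21, n_blocks = 2, trials_per_block = 16,
                      n_sensors = 2, signal_sensors = 1, snr = 0.8)
  e <- generate_experiment(cfg, layouts = FALSE)
  w <- e$recording$time >= 0.1 & e$recording$time <= 0.5
  ct <- condition_coherence(e$recording, e$trials, "target", sensors = 1)
  cd <- condition_coherence(e$recording, e$trials, "distractor", sensors = 1)
  expect_gt(mean(ct$values[, w]), mean(cd$values[, w]))
})

test_that("snr = 0 leaves no reference-locked component", {
  cfg <- small_config(seed = 8, snr = 0, evoked_amplitude = 0,
                      n_blocks = 2, trials_per_block = 20, n_sensors = 1,
                      signal_sensors = 1)
  e <- generate_experiment(cfg, layouts = FALSE)
  zr <- analytic_signal(e$recording$ref[1, , ], 1000, 60)
  zm <- analytic_signal(e$recording$data[1, , ], 1000, 60)
  coh <- coherence_timecourse(zm, zr)
  w <- e$recording$time >= 0.1 & e$recording$time <= 0.5
  # null level for n trials is of order sqrt(pi/4)/sqrt(n); stay well
  # below any planted-signal level
  expect_lt(mean(coh[w]), 3 / sqrt(nrow(e$trials)))
})

test_that("gaze generator honours bias, anisotropy and validity flags", {
  set.seed(31)
  lay <- make_layout(16, TRUE, "yellow")
  expect_equal(sum(lay$colour == "yellow"), 8)
  expect_equal(sum(lay$is_target), 1)
  expect_true(all(abs(lay$x) <= 5 & abs(lay$y) <= 5))

  g <- generate_gaze(lay, 1, 1000, colour_bias = 1, jitter_scale = 0,
                     saccade_rate = 0, blink_rate = 0)
  expect_equal(gaze_bias(g, lay)$fraction, 1)
  expect_error(generate_gaze(lay[0, ], 1, 1000), "empty")
  expect_error(generate_gaze(lay, 1, 1000, colour_bias = 2), "colour_bias")

  # horizontal saccade-amplitude variance exceeds vertical (>= 1000 events)
  set.seed(7)
  dx <- dy <- numeric(0)
  while (length(dx) < 1000) {
    gg <- generate_gaze(lay, 2, 500, saccade_rate = 5)
    dx <- c(dx, gg$saccades$dx); dy <- c(dy, gg$saccades$dy)
  }
  expect_gt(var(dx), var(dy))

  # blink samples are invalidated
  set.seed(8)
  gb <- generate_gaze(lay, 2, 500, blink_rate = 5)
  if (nrow(gb$blinks) > 0) {
    expect_true(any(!gb$valid))
    expect_true(all(is.na(gb$x[!gb$valid])))
  }
})

test_that("reaction times shift with set size and guidance as configured", {
  e <- generate_experiment(sim_config(n_blocks = 16, trials_per_block = 20,
                                      n_sensors = 1, signal_sensors = 1,
                                      baseline_duration = 0.1,
                                      search_duration = 0.1, snr = 0,
                                      seed = 55), layouts = FALSE)
  tr <- e$trials[e$trials$response != "none", ]
  m <- tapply(tr$rt, list(tr$condition, tr$set_size), mean)
  expect_gt(m["unguided", "32"], m["unguided", "16"])
  expect_gt(m["unguided", "32"], m["guided", "32"])
})
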