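test_that("gaze bias handles degenerate layouts and label symmetry", {
  lay <- data.frame(x = c(-2, 2, -2, 2), y = c(-2, -2, 2, 2),
                    colour = c("yellow", "cyan", "cyan", "yellow"),
                    is_target = c(TRUE, FALSE, FALSE, FALSE))
  attr(lay, "target_colour") <- "yellow"
  tr <- list(x = rep(-2, 500) + rnorm(500, 0, 0.01),
             y = rep(-2, 500) + rnorm(500, 0, 0.01),
             valid = rep(TRUE, 500), fs = 1000, target_colour = "yellow")
  class(tr) <- "gaze_trace"
  expect_equal(gaze_bias(tr, lay)$fraction, 1)

  # layout entirely in the target colour: fraction 1 for any gaze
  lay1 <- transform(lay, colour = "yellow")
  attr(lay1, "target_colour") <- "yellow"
  expect_equal(gaze_bias(tr, lay1)$fraction, 1)

  # swapping all stimulus colours maps fraction -> 1 - fraction
  set.seed(50)
  tr2 <- tr; tr2$x <- rnorm(500, 0, 2); tr2$y <- rnorm(500, 0, 2)
  f <- gaze_bias(tr2, lay)$fraction
  lay_sw <- transform(lay, colour = ifelse(colour == "yellow",
                                           "cyan", "yellow"))
  attr(lay_sw, "target_colour") <- "yellow"
  expect_equal(gaze_bias(tr2, lay_sw)$fraction, 1 - f)

  # joint translation of gaze and layout leaves the fraction unchanged
  tr3 <- tr2; tr3$x <- tr3$x + 3; tr3$y <- tr3$y - 1
  lay_t <- transform(lay, x = x + 3, y = y - 1)
  attr(lay_t, "target_colour") <- "yellow"
  expect_equal(gaze_bias(tr3, lay_t)$fraction, f)

  # all samples invalid -> error
  tr4 <- tr; tr4$valid[] <- FALSE; tr4$x[] <- NA; tr4$y[] <- NA
  expect_error(gaze_bias(tr4, lay), "invalid")
})

test_that("event counts by split aggregate correctly", {
  mk <- function(nsac, nblk) {
    structure(list(x = numeric(100), y = numeric(100),
                   valid = rep(TRUE, 100), fs = 1000,
                   saccades = data.frame(onset = seq_len(nsac) * 0.01,
                                         offset = seq_len(nsac) * 0.01 + 0.02,
                                         dx = rep(0, nsac),
                                         dy = rep(0, nsac)),
                   blinks = data.frame(onset = seq_len(nblk) * 0.1,
                                       offset = seq_len(nblk) * 0.1 + 0.1)),
              class = "gaze_trace")
  }
  trials <- data.frame(condition = "guided", set_size = 16,
                       split = rep(c("fast", "slow"), each = 4),
                       trial_index = 0:7)
  # identical event streams in both splits -> zero difference
  traces <- lapply(1:8, function(i) mk(3, 1))
  ec <- event_counts_by_split(traces, trials)
  expect_equal(diff(ec$summary$mean_saccades), 0)
  # planted +2 saccades per slow trial -> detected difference
  traces2 <- lapply(1:8, function(i) mk(if (i > 4) 5 else 3, 0))
  ec2 <- event_counts_by_split(traces2, trials)
  s <- ec2$summary
  expect_equal(s$mean_saccades[s$split == "slow"] -
                 s$mean_saccades[s$split == "fast"], 2)
  # no events anywhere -> zero table
  traces0 <- lapply(1:8, function(i) mk(0, 0))
  ec0 <- event_counts_by_split(traces0, trials)
  expect_true(all(ec0$summary$mean_saccades == 0))
  expect_true(all(ec0$summary$mean_blinks == 0))
})

test_that("fixation heatmap is a normalised density with correct box mass", {
  pin <- structure(list(x = numeric(200), y = numeric(200),
                        valid = rep(TRUE, 200), fs = 1000,
                        saccades = NULL, blinks = NULL),
                   class = "gaze_trace")
  h <- fixation_heatmap(list(pin), extent = 5, resolution = 11)
  expect_equal(sum(h$density), 1)
  expect_equal(max(h$density), 1)  # all mass in the central bin
  expect_equal(h$fraction_in_box, 1)

  # isotropic Gaussian jitter with sd 0.3 deg: >= 99% within the 1-deg box
  set.seed(51)
  g <- structure(list(x = rnorm(20000, 0, 0.3), y = rnorm(20000, 0, 0.3),
                      valid = rep(TRUE, 20000), fs = 1000,
                      saccades = NULL, blinks = NULL),
                 class = "gaze_trace")
  h2 <- fixation_heatmap(list(g))
  expect_gte(h2$fraction_in_box, 0.99)
  # theoretical mass for comparison: (2 Phi(1/0.3) - 1)^2
  expect_equal(h2$fraction_in_box, (2 * pnorm(1 / 0.3) - 1)^2,
               tolerance = 0.005)

  # horizontally anisotropic traces leave a wider x-marginal
  set.seed(52)
  lay <- make_layout(16, TRUE, "yellow")
  traces <- lapply(1:30, function(i)
    generate_gaze(lay, 1, 500, saccade_rate = 4))
  xs <- unlist(lapply(traces, function(t) t$x[t$valid]))
  ys <- unlist(lapply(traces, function(t) t$y[t$valid]))
  expect_gt(var(xs), var(ys))
})
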