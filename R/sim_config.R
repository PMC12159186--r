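#' Configuration for a synthetic frequency-tagging experiment
#'
#' Collects and validates every parameter of the synthetic-data generator.
#' Defaults reproduce the design of the modelled experiment: 24 blocks of 40
#' trials (960 trials), guided/unguided search crossed with set sizes 16 and
#' 32, luminance tagging at 60 and 67 Hz, 1000 Hz sampling, and a 1.5 s
#' pre-search baseline.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param tag_freqs Numeric pair of tagging frequencies in Hz; must be
#'   distinct and below Nyquist.
#' @param n_blocks Number of blocks. Blocks are assigned round-robin to the
#'   four cells of the guided/unguided x set-size design and then shuffled.
#' @param trials_per_block Trials per block; must be even (half target
#'   present, half absent) and is balanced over the two colour-frequency
#'   assignments within each block.
#' @param set_sizes Integer pair of set sizes (items per display).
#' @param baseline_duration,search_duration Epoch segments in seconds; the
#'   time axis runs from `-baseline_duration` to `search_duration` with 0 at
#'   search-display onset.
#' @param boost_gain,suppress_gain,unguided_gain Dimensionless amplitude
#'   multipliers applied to the tag carrier of, respectively, the guided
#'   target colour, the guided distractor colour, and either colour in
#'   unguided search. The effect direction of the modelled experiment
#'   corresponds to `boost_gain >= unguided_gain >= suppress_gain`; any
#'   positive ordering is accepted (e.g. all equal for null simulations).
#' @param evoked_amplitude Amplitude of the broadband evoked transient at
#'   search onset (a.u.; 0 disables it).
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param snr Amplitude of a gain-1 tag carrier relative to the unit-sd
#'   background noise; 0 removes all flicker-locked signal.
#' @param n_sensors Number of synthetic sensors.
#' @param signal_sensors Indices of sensors that carry the tag signal and the
#'   evoked response (the "occipital" subset).
#' @param white_noise_sd Standard deviation of additional white sensor noise.
#' @param ref_phase Phases (radians) of the two reference sinusoids.
#' @param rt_shift,rt_meanlog,rt_sdlog Shifted-lognormal reaction-time model:
#'   `rt = rt_shift + lognormal(meanlog, sdlog)`.
#' @param rt_beta_set,rt_beta_guided Additive effects on `meanlog` for the
#'   larger set size and for guided search (positive/negative respectively
#'   in the modelled effect direction).
#' @param dprime_base Sensitivity d' for unguided search at the smaller set
#'   size; accuracy per cell is derived from an equal-variance
#'   signal-detection model with unbiased criterion.
#' @param dprime_beta_set,dprime_beta_guided Additive d' effects of the
#'   larger set size and of guidance.
#' @param nonresponse_rate Probability of a missing response per trial.
#' @param response_deadline Seconds after which a trial times out
#'   (response "none").
#' @param gaze_colour_bias Colour bias of the gaze generator (0.5 =
#'   colour-independent fixational jitter).
#' @param gaze_jitter_scale Stationary sd of fixational jitter in degrees.
#' @param seed Integer seed; identical configurations give bit-identical
#'   experiments.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_experiment()]
#' @export
#' @examples
#' cfg <- sim_config(n_blocks = 4, trials_per_block = 8, n_sensors = 4)
#' cfg$tag_freqs
sim_config <- function(sampling_rate = 1000,
                       tag_freqs = c(60, 67),
                       n_blocks = 24,
                       trials_per_block = 40,
                       set_sizes = c(16L, 32L),
                       baseline_duration = 1.5,
                       search_duration = 1,
                       boost_gain = 1.6,
                       suppress_gain = 0.5,
                       unguided_gain = 1,
                       evoked_amplitude = 1,
                       noise_exponent = 1,
                       snr = 0.5,
                       n_sensors = 20,
                       signal_sensors = 1:4,
                       white_noise_sd = 0.3,
                       ref_phase = c(0, 0),
                       rt_shift = 0.2,
                       rt_meanlog = log(0.65),
                       rt_sdlog = 0.35,
                       rt_beta_set = 0.180,
                       rt_beta_guided = -0.138,
                       dprime_base = 2.8,
                       dprime_beta_set = -0.74,
                       dprime_beta_guided = 0.56,
                       nonresponse_rate = 0.02,
                       response_deadline = 4,
                       gaze_colour_bias = 0.5,
                       gaze_jitter_scale = 0.3,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$tag_freqs) == 2, length(cfg$set_sizes) == 2)
  if (cfg$tag_freqs[1] == cfg$tag_freqs[2])
    stop("tag_freqs must be distinct", call. = FALSE)
  if (any(cfg$tag_freqs <= 0) || any(cfg$tag_freqs >= cfg$sampling_rate / 2))
    stop("tag_freqs must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  if (cfg$trials_per_block %% 2 != 0)
    stop("trials_per_block must be even (half target present, half absent)",
         call. = FALSE)
  if (any(c(cfg$boost_gain, cfg$suppress_gain, cfg$unguided_gain) <= 0))
    stop("gains must be positive", call. = FALSE)
  if (cfg$snr < 0) stop("snr must be non-negative", call. = FALSE)
  if (length(cfg$seed) != 1 || !is.finite(cfg$seed) ||
      cfg$seed != round(cfg$seed))
    stop("seed must be a single integer", call. = FALSE)
  if (any(cfg$signal_sensors < 1) || any(cfg$signal_sensors > cfg$n_sensors))
    stop("signal_sensors out of range", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  n_trials <- x$n_blocks * x$trials_per_block
  cat("<sim_config>\n",
      sprintf("  %d blocks x %d trials = %d trials\n",
              x$n_blocks, x$trials_per_block, n_trials),
      sprintf("  tagging at %g / %g Hz, fs = %g Hz\n",
              x$tag_freqs[1], x$tag_freqs[2], x$sampling_rate),
      sprintf("  gains (boost/unguided/suppress): %g / %g / %g, snr %g\n",
              x$boost_gain, x$unguided_gain, x$suppress_gain, x$snr),
      sprintf("  %d sensors (%d signal-carrying), seed %d\n",
              x$n_sensors, length(x$signal_sensors), as.integer(x$seed)),
      sep = "")
  invisible(x)
}
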