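#' 1/f^alpha Gaussian background noise
#'
#' Spectral-synthesis generator for power-law ("pink" at alpha = 1)
#' background noise, the standard surrogate for electrophysiological
#' baseline activity. Each series is scaled to unit standard deviation.
#'
#' @param n Samples per series.
#' @param n_series Number of independent series.
#' @param exponent Spectral slope alpha of the power spectrum 1/f^alpha.
#' @return A numeric `n x n_series` matrix.
#' @export
colored_noise <- function(n, n_series = 1, exponent = 1) {
  stopifnot(n >= 2, n_series >= 1)
  w <- matrix(rnorm(n * n_series), n, n_series)
  if (exponent == 0) return(scale_to_unit_sd(w))
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) / n
  amp <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::mvfft(stats::mvfft(w) * amp, inverse = TRUE)) / n
  scale_to_unit_sd(x)
}

scale_to_unit_sd <- function(x) {
  s <- sqrt(colMeans(x^2) - colMeans(x)^2)
  s[s == 0] <- 1
  sweep(x, 2, s, "/")
}

#' Reference ("photodiode") signal
#'
#' Unit-amplitude sinusoid at the tagging frequency with known phase,
#' optionally with additive white noise. The offline analysis replaces the
#' recorded photodiode trace with exactly this phase-matched sine; a small
#' noise amplitude (0.05 in the modelled analysis) is added when the
#' reference is evaluated away from its own frequency, to avoid division by
#' the zero off-peak power of a perfect sine.
#'
#' @param freq Frequency in Hz, strictly below Nyquist.
#' @param phase Phase in radians at t = 0.
#' @param duration Duration in seconds (used when `time` is NULL; the axis
#'   then starts at 0).
#' @param fs Sampling rate in Hz.
#' @param noise_amplitude Standard-deviation multiplier of added white
#'   noise; 0 gives the perfect sine.
#' @param time Optional explicit time axis in seconds (overrides
#'   `duration`).
#' @return Numeric vector `sin(2 pi freq t + phase) + noise`.
#' @export
#' @examples
#' r <- make_reference(60, 0, duration = 0.1, fs = 1000)
#' r[1]  # 0 at t = 0 for phase 0
make_reference <- function(freq, phase = 0, duration = NULL, fs = 1000,
                           noise_amplitude = 0, time = NULL) {
  if (freq >= fs / 2)
    stop("reference frequency at or above Nyquist would alias", call. = FALSE)
  if (freq <= 0) stop("reference frequency must be positive", call. = FALSE)
  if (is.null(time)) {
    stopifnot(!is.null(duration))
    time <- seq(0, by = 1 / fs, length.out = round(duration * fs))
  }
  x <- sin(2 * pi * freq * time + phase)
  if (noise_amplitude > 0) x <- x + noise_amplitude * rnorm(length(time))
  x
}

#' Random search-display layout
#'
#' Places `set_size` items (1 deg bars) on the 10 x 10 deg search grid
#' centred on fixation, half in each colour, with at most one target.
#' Screen-centred coordinates in degrees visual angle, +x right, +y up.
#'
#' @param set_size Number of items (even).
#' @param target_present Logical; place one target?
#' @param target_colour `"yellow"` or `"cyan"`; colour of the target (and,
#'   on target-absent trials, the colour label carried by the design).
#' @return A data frame with columns `x`, `y`, `colour`, `is_target`, and a
#'   `target_colour` attribute.
#' @export
make_layout <- function(set_size, target_present = TRUE,
                        target_colour = c("yellow", "cyan")) {
  target_colour <- match.arg(target_colour)
  stopifnot(set_size >= 2, set_size %% 2 == 0)
  centres <- seq(-4.375, 4.375, length.out = 8)
  cells <- expand.grid(x = centres, y = centres)
  if (set_size > nrow(cells)) stop("set_size exceeds grid capacity")
  idx <- sample(nrow(cells), set_size)
  pos <- cells[idx, ]
  jit <- 0.25
  pos$x <- pos$x + runif(set_size, -jit, jit)
  pos$y <- pos$y + runif(set_size, -jit, jit)
  colours <- sample(rep(c("yellow", "cyan"), set_size / 2))
  is_target <- rep(FALSE, set_size)
  if (target_present) {
    cand <- which(colours == target_colour)
    is_target[cand[sample.int(length(cand), 1)]] <- TRUE
  }
  out <- data.frame(x = pos$x, y = pos$y, colour = colours,
                    is_target = is_target, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "target_colour") <- target_colour
  out
}

#' Synthetic gaze trace for one trial
#'
#' Fixational jitter is an Ornstein-Uhlenbeck walk around fixation;
#' microsaccade-like jumps arrive as a Poisson process with horizontally
#' anisotropic amplitudes and drift back exponentially; blinks invalidate
#' samples. `colour_bias` maps to an attraction weight `w = 2 bias - 1`
#' toward a randomly chosen stimulus of the target colour: at 0.5 the gaze
#' is independent of stimulus colour, at 1 (with `jitter_scale = 0`) it is
#' pinned to a target-colour item; values below 0.5 attract toward the
#' other colour symmetrically.
#'
#' @param layout Layout data frame from [make_layout()] (must carry a
#'   `target_colour` attribute or `target_colour` must be given).
#' @param duration Trace duration in seconds (the search interval).
#' @param fs Sampling rate in Hz.
#' @param colour_bias Bias in `[0, 1]`; 0.5 = colour-independent.
#' @param jitter_scale Stationary sd of the jitter in degrees.
#' @param saccade_rate,blink_rate Event rates per second.
#' @param saccade_sd Vertical saccade-amplitude sd in degrees; horizontal sd
#'   is `anisotropy` times larger.
#' @param anisotropy Horizontal/vertical saccade-amplitude sd ratio (> 1
#'   reproduces the predominantly horizontal microsaccades of fixation).
#' @param target_colour Colour counted as "target"; defaults to the
#'   layout's attribute.
#' @param seed Optional integer seed for a self-contained reproducible
#'   trace.
#' @return A list of class `gaze_trace`: `x`, `y` (degrees), `valid`
#'   (logical, FALSE during blinks), `fs`, `saccades` and `blinks` event
#'   data frames with onset/offset in seconds.
#' @export
generate_gaze <- function(layout, duration, fs = 1000, colour_bias = 0.5,
                          jitter_scale = 0.3, saccade_rate = 2,
                          blink_rate = 0.1, saccade_sd = 0.15,
                          anisotropy = 2,
                          target_colour = attr(layout, "target_colour"),
                          seed = NULL) {
  if (is.null(layout) || nrow(layout) == 0)
    stop("empty stimulus layout", call. = FALSE)
  if (colour_bias < 0 || colour_bias > 1)
    stop("colour_bias must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  theta <- 0.01
  sig <- jitter_scale * sqrt(2 * theta)
  jx <- ou_path(n, theta, sig)
  jy <- ou_path(n, theta, sig)

  t_axis <- (seq_len(n) - 1) / fs
  n_sac <- rpois(1, saccade_rate * duration)
  sac <- data.frame(onset = numeric(0), offset = numeric(0),
                    dx = numeric(0), dy = numeric(0))
  sx <- numeric(n); sy <- numeric(n)
  if (n_sac > 0) {
    onset <- sort(runif(n_sac, 0, duration))
    dx <- rnorm(n_sac, 0, anisotropy * saccade_sd)
    dy <- rnorm(n_sac, 0, saccade_sd)
    sac <- data.frame(onset = onset, offset = pmin(onset + 0.02, duration),
                      dx = dx, dy = dy)
    for (i in seq_len(n_sac)) {
      after <- t_axis >= onset[i]
      decay <- exp(-(t_axis[after] - onset[i]) / 0.2)
      sx[after] <- sx[after] + dx[i] * decay
      sy[after] <- sy[after] + dy[i] * decay
    }
  }
  x <- jx + sx
  y <- jy + sy

  w <- 2 * colour_bias - 1
  if (w != 0) {
    attract_colour <- if (w > 0) target_colour else
      setdiff(c("yellow", "cyan"), target_colour)
    cand <- which(layout$colour == attract_colour)
    if (length(cand) == 0)
      stop("no stimulus of the attraction colour in layout", call. = FALSE)
    g <- cand[sample.int(length(cand), 1)]
    aw <- abs(w)
    x <- (1 - aw) * x + aw * layout$x[g]
    y <- (1 - aw) * y + aw * layout$y[g]
  }

  valid <- rep(TRUE, n)
  n_blink <- rpois(1, blink_rate * duration)
  blinks <- data.frame(onset = numeric(0), offset = numeric(0))
  if (n_blink > 0) {
    onset <- runif(n_blink, 0, duration)
    offset <- pmin(onset + runif(n_blink, 0.1, 0.3), duration)
    blinks <- data.frame(onset = onset, offset = offset)
    for (i in seq_len(n_blink))
      valid[t_axis >= onset[i] & t_axis < offset[i]] <- FALSE
  }
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  structure(list(x = x, y = y, valid = valid, fs = fs,
                 saccades = sac, blinks = blinks,
                 target_colour = target_colour),
            class = "gaze_trace")
}

ou_path <- function(n, theta, sig) {
  x <- numeric(n)
  eps <- rnorm(n, 0, sig)
  for (i in 2:n) x[i] <- x[i - 1] * (1 - theta) + eps[i]
  x
}

#' Construct a tagged recording container
#'
#' Bundles multichannel per-trial sensor data with the reference signals
#' and a sample-aligned time axis (0 = search-display onset). Used both by
#' the generator and to assemble recordings from externally produced
#' arrays.
#'
#' @param data Numeric array `sensors x trials x samples`.
#' @param ref Numeric array `refs x trials x samples`, one reference per
#'   tagging frequency.
#' @param time Time axis in seconds, length `samples`.
#' @param fs Sampling rate in Hz.
#' @param tag_freqs Frequencies (Hz) of the reference rows.
#' @param sensor_labels Optional sensor names.
#' @param sensor_positions Optional `sensors x 2` layout coordinates (used
#'   for sensor adjacency in cluster tests).
#' @param candidate_sensors Indices eligible for sensor selection.
#' @return An object of class `tagged_recording`.
#' @export
tagged_recording <- function(data, ref, time, fs, tag_freqs,
                             sensor_labels = NULL, sensor_positions = NULL,
                             candidate_sensors = NULL) {
  stopifnot(length(dim(data)) == 3, length(dim(ref)) == 3,
            dim(data)[3] == length(time), dim(ref)[3] == length(time),
            dim(ref)[2] == dim(data)[2], dim(ref)[1] == length(tag_freqs))
  ns <- dim(data)[1]
  if (is.null(sensor_labels)) sensor_labels <- sprintf("S%02d", seq_len(ns))
  if (is.null(sensor_positions)) {
    side <- ceiling(sqrt(ns))
    g <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(ns), ]
    sensor_positions <- as.matrix(g)
  }
  if (is.null(candidate_sensors)) candidate_sensors <- seq_len(ns)
  structure(list(data = data, ref = ref, time = time, fs = fs,
                 tag_freqs = tag_freqs, sensor_labels = sensor_labels,
                 sensor_positions = sensor_positions,
                 candidate_sensors = candidate_sensors),
            class = "tagged_recording")
}

#' @export
print.tagged_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<tagged_recording> %d sensors x %d trials x %d samples (fs %g Hz)\n",
    d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %.3f .. %.3f s, tags at %s Hz\n", min(x$time),
              max(x$time), paste(x$tag_freqs, collapse = "/")))
  invisible(x)
}

#' Generate a full synthetic experiment
#'
#' Produces a blocked guided/unguided visual-search experiment with the
#' statistical structure the analysis pipeline assumes. Each trial's sensor
#' data are the sum of unit-sd 1/f background noise, white sensor noise, a
#' phase-locked broadband evoked transient at search onset, and -- on the
#' signal-carrying sensors, during the search interval -- one tag carrier
#' per stimulus colour whose amplitude is `snr` times the role-appropriate
#' gain: the guided target colour gets `boost_gain`, the guided distractor
#' colour `suppress_gain`, and both colours `unguided_gain` in unguided
#' blocks. Colour-to-frequency assignment is counterbalanced within block
#' and crossed with target presence; reaction times follow a shifted
#' lognormal whose location increases with set size and decreases under
#' guidance; responses follow an equal-variance signal-detection model.
#'
#' Identical configurations (including the seed) give bit-identical output.
#'
#' @param config A [sim_config()] object.
#' @param layouts,gaze Logical; generate stimulus layouts / gaze traces
#'   (skipping them saves time when only sensor analyses are needed).
#' @return A list of class `rift_experiment` with elements `recording`
#'   (a [tagged_recording()]), `trials` (the trial table data frame),
#'   `layouts` (list of layout data frames), `gaze` (list of `gaze_trace`),
#'   and `config`.
#' @export
#' @examples
#' exp <- generate_experiment(sim_config(n_blocks = 2, trials_per_block = 4,
#'                                       n_sensors = 2, signal_sensors = 1,
#'                                       search_duration = 0.3,
#'                                       baseline_duration = 0.3))
#' nrow(exp$trials)
generate_experiment <- function(config, layouts = TRUE, gaze = TRUE) {
  validate_sim_config(config)
  set.seed(as.integer(config$seed))
  fs <- config$sampling_rate
  n_trials <- config$n_blocks * config$trials_per_block
  n_samples <- round((config$baseline_duration + config$search_duration) * fs)
  time <- (seq_len(n_samples) - 1) / fs - config$baseline_duration
  search <- time >= 0

  trials <- build_trial_table(config)

  ## references: phase-matched sinusoids extending into the baseline
  ref <- array(0, dim = c(2, n_trials, n_samples))
  for (j in 1:2) {
    r <- make_reference(config$tag_freqs[j], config$ref_phase[j],
                        fs = fs, time = time)
    ref[j, , ] <- matrix(r, n_trials, n_samples, byrow = TRUE)
  }

  ## deterministic (phase-locked) evoked waveform per signal sensor
  evoked <- matrix(0, config$n_sensors, n_samples)
  if (config$evoked_amplitude > 0) {
    env_dur <- 0.15
    env <- ifelse(time >= 0 & time <= env_dur,
                  0.5 * (1 - cos(2 * pi * time / env_dur)), 0)
    for (s in config$signal_sensors) {
      burst <- bandlimited_noise(n_samples, fs, c(30, 80))
      evoked[s, ] <- config$evoked_amplitude * env * burst
    }
  }

  data <- array(0, dim = c(config$n_sensors, n_trials, n_samples))
  carriers <- rbind(sin(2 * pi * config$tag_freqs[1] * time +
                          config$ref_phase[1]) * search,
                    sin(2 * pi * config$tag_freqs[2] * time +
                          config$ref_phase[2]) * search)
  for (s in seq_len(config$n_sensors)) {
    noise <- t(colored_noise(n_samples, n_trials, config$noise_exponent))
    if (config$white_noise_sd > 0)
      noise <- noise + config$white_noise_sd *
        matrix(rnorm(n_trials * n_samples), n_trials, n_samples)
    noise <- noise + matrix(evoked[s, ], n_trials, n_samples, byrow = TRUE)
    if (config$snr > 0 && s %in% config$signal_sensors) {
      amp <- carrier_amplitudes(trials, config)  # trials x 2 (per freq)
      noise <- noise + config$snr *
        (outer(amp[, 1], carriers[1, ]) + outer(amp[, 2], carriers[2, ]))
    }
    data[s, , ] <- noise
  }

  rec <- tagged_recording(data, ref, time, fs, config$tag_freqs,
                          candidate_sensors = seq_len(config$n_sensors))

  layout_list <- NULL
  gaze_list <- NULL
  if (layouts) {
    layout_list <- lapply(seq_len(n_trials), function(i)
      make_layout(trials$set_size[i], trials$target_present[i],
                  trials$target_colour[i]))
    if (gaze) {
      gaze_list <- lapply(seq_len(n_trials), function(i)
        generate_gaze(layout_list[[i]], duration = config$search_duration,
                      fs = fs, colour_bias = config$gaze_colour_bias,
                      jitter_scale = config$gaze_jitter_scale))
    }
  }

  structure(list(recording = rec, trials = trials, layouts = layout_list,
                 gaze = gaze_list, config = config),
            class = "rift_experiment")
}

## per-trial carrier amplitude (gain) at each tag frequency
carrier_amplitudes <- function(trials, config) {
  freq_of <- function(colour)
    ifelse(colour == "yellow", trials$freq_yellow, trials$freq_cyan)
  tf <- freq_of(trials$target_colour)
  amp <- matrix(0, nrow(trials), 2)
  for (j in 1:2) {
    f <- config$tag_freqs[j]
    is_target_freq <- tf == f
    amp[, j] <- ifelse(trials$condition == "unguided", config$unguided_gain,
                       ifelse(is_target_freq, config$boost_gain,
                              config$suppress_gain))
  }
  amp
}

bandlimited_noise <- function(n, fs, band) {
  x <- rnorm(n)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  keep <- f >= band[1] & f <= band[2]
  y <- Re(fft(fft(x) * keep, inverse = TRUE)) / n
  s <- sd(y)
  if (s > 0) y <- y / s
  y
}

build_trial_table <- function(config) {
  cells <- expand.grid(condition = c("guided", "unguided"),
                       set_size = config$set_sizes,
                       stringsAsFactors = FALSE)
  block_cell <- cells[rep_len(seq_len(nrow(cells)), config$n_blocks), ]
  ord <- sample(config$n_blocks)
  block_cell <- block_cell[ord, ]
  ## balanced target colours over guided blocks
  guided_blocks <- which(block_cell$condition == "guided")
  guided_cols <- sample(rep_len(c("yellow", "cyan"), length(guided_blocks)))

  tpb <- config$trials_per_block
  rows <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    cond <- block_cell$condition[b]
    ss <- block_cell$set_size[b]
    ## balanced present x colour-frequency assignment within block
    present <- rep(c(TRUE, FALSE), each = tpb / 2)
    yellow60 <- rep_len(c(TRUE, FALSE, FALSE, TRUE), tpb)
    perm <- sample(tpb)
    present <- present[perm]
    yellow60 <- yellow60[perm]
    tcol <- if (cond == "guided")
      rep(guided_cols[match(b, guided_blocks)], tpb)
    else sample(c("yellow", "cyan"), tpb, replace = TRUE)
    rows[[b]] <- data.frame(
      block = b, condition = cond, set_size = ss,
      target_present = present, target_colour = tcol,
      freq_yellow = ifelse(yellow60, config$tag_freqs[1],
                           config$tag_freqs[2]),
      freq_cyan = ifelse(yellow60, config$tag_freqs[2],
                         config$tag_freqs[1]),
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, rows)
  n <- nrow(trials)
  trials$trial_index <- seq_len(n) - 1L
  trials$tot <- if (n > 1) trials$trial_index / (n - 1) else 0

  ## behaviour: equal-variance signal detection with unbiased criterion
  is32 <- trials$set_size == max(config$set_sizes)
  guided <- trials$condition == "guided"
  dp <- config$dprime_base + config$dprime_beta_set * is32 +
    config$dprime_beta_guided * guided
  p_yes <- ifelse(trials$target_present, pnorm(dp / 2), pnorm(-dp / 2))
  said_yes <- runif(n) < p_yes
  trials$response <- ifelse(said_yes, "present", "absent")

  mu <- config$rt_meanlog + config$rt_beta_set * is32 +
    config$rt_beta_guided * guided
  rt <- config$rt_shift + rlnorm(n, mu, config$rt_sdlog)
  none <- runif(n) < config$nonresponse_rate | rt > config$response_deadline
  trials$response[none] <- "none"
  rt[none] <- NA_real_
  trials$rt <- rt
  trials$correct <- !none & ((trials$response == "present") ==
                               trials$target_present)
  rownames(trials) <- NULL
  trials
}
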