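# Shared fixtures: scaled-down experiment configurations used across the
# suite. Sizes are chosen so one experiment generates in well under a
# second while keeping every structural property of the full design.

small_config <- function(seed = 1L, ...) {
  defaults <- list(n_blocks = 4, trials_per_block = 8, n_sensors = 4,
                   signal_sensors = 1:2, baseline_duration = 0.8,
                   search_duration = 0.6, snr = 1, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# single-sensor recording of pure 1/f noise plus a 60 Hz reference sine:
# the null case for sensor selection (no component phase-locked to the
# reference)
null_recording <- function(n_trials = 50, fs = 1000,
                           t_range = c(-0.9, 0.6), freq = 60) {
  time <- seq(t_range[1], t_range[2], by = 1 / fs)
  n <- length(time)
  dat <- array(t(colored_noise(n, n_trials, 1)), dim = c(1, n_trials, n))
  ref <- aperm(array(sin(2 * pi * freq * time), dim = c(n, n_trials, 1)),
               c(3, 2, 1))
  tagged_recording(dat, ref, time, fs, freq)
}

# recording whose signal sensors carry a reference-locked 60 Hz component
# during the search interval only
planted_recording <- function(n_trials = 30, fs = 1000, amp = 0.8,
                              n_sensors = 5, signal_sensors = 1:3,
                              t_range = c(-0.9, 0.6), freq = 60) {
  time <- seq(t_range[1], t_range[2], by = 1 / fs)
  n <- length(time)
  carrier <- sin(2 * pi * freq * time) * (time >= 0)
  dat <- array(0, dim = c(n_sensors, n_trials, n))
  for (s in seq_len(n_sensors)) {
    x <- t(colored_noise(n, n_trials, 1))
    if (s %in% signal_sensors)
      x <- x + matrix(amp * carrier, n_trials, n, byrow = TRUE)
    dat[s, , ] <- x
  }
  ref <- aperm(array(sin(2 * pi * freq * time), dim = c(n, n_trials, 1)),
               c(3, 2, 1))
  tagged_recording(dat, ref, time, fs, freq)
}
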