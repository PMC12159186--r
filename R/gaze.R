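#' Per-trial gaze bias toward the target colour
#'
#' Bins the gaze trace into fixed intervals (0.1 s by default), summarises
#' each bin by the mean of its valid samples, finds the Euclidean-nearest
#' stimulus, and reports the fraction of valid bins whose nearest stimulus
#' has the target colour. Bins contaminated by blinks (no valid samples)
#' and bins whose nearest distance is tied between the two colours are
#' excluded from both numerator and denominator.
#'
#' @param trace A `gaze_trace` from [generate_gaze()].
#' @param layout Stimulus layout data frame.
#' @param bin Bin width in seconds (default 0.1).
#' @param target_colour Colour counted as target; defaults to the trace's
#'   (or layout's) label.
#' @return List with `fraction` (unit interval), `n_bins` (valid bins),
#'   `n_target_bins`.
#' @export
gaze_bias <- function(trace, layout, bin = 0.1,
                      target_colour = trace$target_colour) {
  if (is.null(layout) || nrow(layout) == 0)
    stop("empty stimulus layout", call. = FALSE)
  if (is.null(target_colour)) target_colour <- attr(layout, "target_colour")
  n <- length(trace$x)
  nb <- floor(n / (bin * trace$fs))
  if (nb < 1) stop("trace shorter than one bin", call. = FALSE)
  bw <- round(bin * trace$fs)
  n_target <- 0L; n_valid <- 0L
  for (b in seq_len(nb)) {
    idx <- ((b - 1) * bw + 1):(b * bw)
    ok <- trace$valid[idx]
    if (!any(ok)) next
    gx <- mean(trace$x[idx][ok]); gy <- mean(trace$y[idx][ok])
    d <- sqrt((layout$x - gx)^2 + (layout$y - gy)^2)
    dmin <- min(d)
    nearest <- which(d - dmin < 1e-12)
    cols <- unique(layout$colour[nearest])
    if (length(cols) > 1) next  # equidistant colour tie: bin excluded
    n_valid <- n_valid + 1L
    if (cols == target_colour) n_target <- n_target + 1L
  }
  if (n_valid == 0) stop("all bins invalid", call. = FALSE)
  list(fraction = n_target / n_valid, n_bins = n_valid,
       n_target_bins = n_target)
}

#' Saccade and blink counts by reaction-time split
#'
#' Mean per-trial saccade and blink counts per condition cell and
#' fast/slow median-split label, as produced by the online event parser of
#' the simulated eye tracker.
#'
#' @param traces List of `gaze_trace` objects, one per recording trial.
#' @param trials Trial table carrying a `split` column (see
#'   [median_split()]); `trial_index` selects each trial's trace.
#' @param by Grouping columns defining condition cells.
#' @return List with `summary` (data frame: cell columns, `split`,
#'   `n_trials`, `mean_saccades`, `mean_blinks`) and `per_trial` (counts
#'   per trial).
#' @export
event_counts_by_split <- function(traces, trials,
                                  by = c("condition", "set_size")) {
  sac <- vapply(trials$trial_index + 1L,
                function(i) nrow(traces[[i]]$saccades), 0L)
  blk <- vapply(trials$trial_index + 1L,
                function(i) nrow(traces[[i]]$blinks), 0L)
  per_trial <- cbind(trials[, c(by, "split"), drop = FALSE],
                     saccades = sac, blinks = blk)
  key <- interaction(per_trial[, c(by, "split"), drop = FALSE], drop = TRUE)
  agg <- lapply(levels(key), function(k) {
    sub <- per_trial[key == k, , drop = FALSE]
    out <- sub[1, c(by, "split"), drop = FALSE]
    out$n_trials <- nrow(sub)
    out$mean_saccades <- mean(sub$saccades)
    out$mean_blinks <- mean(sub$blinks)
    out
  })
  list(summary = do.call(rbind, agg), per_trial = per_trial)
}

#' Fixation heatmap
#'
#' 2-D histogram of all valid gaze samples over the display extent,
#' normalised to sum to one, together with the fraction of samples inside
#' the central 1-degree box (the fixation-compliance criterion).
#'
#' @param traces List of `gaze_trace` objects.
#' @param extent Half-extent of the display in degrees (bins span
#'   `[-extent, extent]` in both axes).
#' @param resolution Number of bins per axis.
#' @param box Half-width in degrees of the central compliance box.
#' @return List with `density` (`resolution x resolution` matrix, sums to
#'   1), `xbreaks`, `ybreaks`, `fraction_in_box`, `n_samples`.
#' @export
fixation_heatmap <- function(traces, extent = 5, resolution = 50, box = 1) {
  xs <- unlist(lapply(traces, function(tr) tr$x[tr$valid]))
  ys <- unlist(lapply(traces, function(tr) tr$y[tr$valid]))
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) == 0) stop("no valid gaze samples", call. = FALSE)
  breaks <- seq(-extent, extent, length.out = resolution + 1)
  cx <- cut(pmin(pmax(xs, -extent), extent), breaks, include.lowest = TRUE)
  cy <- cut(pmin(pmax(ys, -extent), extent), breaks, include.lowest = TRUE)
  h <- table(cx, cy)
  dens <- unclass(h) / length(xs)
  frac <- mean(abs(xs) <= box & abs(ys) <= box)
  list(density = dens, xbreaks = breaks, ybreaks = breaks,
       fraction_in_box = frac, n_samples = length(xs))
}
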