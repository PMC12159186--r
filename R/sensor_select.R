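#' Bias-corrected z-transform of a coherence difference
#'
#' Fisher z-transforms the search- and baseline-interval coherence
#' magnitudes, subtracts the small-sample bias `1/(2n - 2)` from each, and
#' scales the difference:
#' `Z = ((atanh|coh_search| - bias) - (atanh|coh_bsl| - bias)) / sqrt(2 bias)`.
#' The bias terms cancel in the numerator, so the value equals
#' `(atanh(coh_search) - atanh(coh_bsl)) * sqrt(n - 1)`; the expression is
#' nevertheless evaluated as printed.
#'
#' @param coh_search,coh_bsl Coherence magnitudes in `[0, 1)`.
#' @param n Number of trials (>= 2).
#' @return Dimensionless z value(s); vectorised over the coherences.
#' @export
#' @examples
#' z_coherence_diff(0.5, 0.3, 101)  # ~ 2.398
z_coherence_diff <- function(coh_search, coh_bsl, n) {
  if (any(n < 2)) stop("n must be at least 2", call. = FALSE)
  ac <- abs(coh_search); ab <- abs(coh_bsl)
  if (any(ac >= 1) || any(ab >= 1))
    stop("coherence magnitude must be below 1 (atanh diverges)",
         call. = FALSE)
  bias <- 1 / (2 * n - 2)
  ((atanh(ac) - bias) - (atanh(ab) - bias)) / sqrt(2 * bias)
}

#' Permutation-based selection of tagging-responsive sensors
#'
#' For each sensor, coherence with the first-frequency reference is
#' computed per sample (trial-averaged, via the analytic signal) and
#' averaged within a pre-search baseline window and a search window of
#' equal length. The windowed difference is z-transformed with
#' [z_coherence_diff()]. A Monte-Carlo null is built by randomly swapping
#' the baseline and search segments within trials (`n_perm` permutations of
#' the interval labels) and recomputing the z value; a sensor is selected
#' when its empirical z strictly exceeds the `1 - alpha` quantile of its
#' own null distribution.
#'
#' The permutation loop is algebraic: per-trial per-sample cross-products
#' and amplitudes are precomputed for both windows, and every permutation's
#' trial means are obtained from one 0/1 swap-matrix multiplication.
#'
#' @param rec A [tagged_recording()].
#' @param trials Optional trial table; if given, only its `trial_index`
#'   rows enter (e.g. after [exclude_trials()]).
#' @param search_window,baseline_window Two-element windows in seconds
#'   (equal length; defaults 0 to 0.5 and -0.7 to -0.2).
#' @param ref_index Reference channel used (default 1, i.e. the first
#'   tagging frequency).
#' @param halfwidth Filter half bandwidth in Hz.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Significance level (default 0.01: empirical z must exceed
#'   99% of the null).
#' @param sensors Candidate sensor indices (default the recording's
#'   candidate set).
#' @param seed Optional integer seed for the permutation draws.
#' @return Data frame with one row per candidate sensor: `sensor`, `label`,
#'   `z` (empirical), `null_quantile` (the `1 - alpha` null quantile),
#'   `frac_null_below`, `selected`; attributes `n_perm`, `alpha`,
#'   `n_trials`.
#' @export
select_sensors <- function(rec, trials = NULL,
                           search_window = c(0, 0.5),
                           baseline_window = c(-0.7, -0.2),
                           ref_index = 1, halfwidth = 3.5,
                           n_perm = 1000, alpha = 0.01,
                           sensors = NULL, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  freq <- rec$tag_freqs[ref_index]
  for (w in list(search_window, baseline_window)) {
    if (diff(w) < 1 / freq)
      stop("window shorter than one cycle of the reference frequency",
           call. = FALSE)
    if (w[1] < min(rec$time) - 1e-9 || w[2] > max(rec$time) + 1 / rec$fs)
      stop("window outside the epoch", call. = FALSE)
  }
  idx_trials <- if (is.null(trials)) seq_len(dim(rec$data)[2]) else
    trials$trial_index + 1L
  n <- length(idx_trials)
  if (n < 2) stop("need at least 2 trials", call. = FALSE)
  if (is.null(sensors)) sensors <- rec$candidate_sensors

  ws <- which(rec$time >= search_window[1] & rec$time < search_window[2])
  wb <- which(rec$time >= baseline_window[1] & rec$time < baseline_window[2])
  k <- min(length(ws), length(wb))
  ws <- ws[seq_len(k)]; wb <- wb[seq_len(k)]

  zr <- analytic_signal(rec$ref[ref_index, idx_trials, , drop = TRUE],
                        rec$fs, freq, halfwidth)
  if (is.null(dim(zr))) zr <- matrix(zr, nrow = 1)

  if (!is.null(seed)) set.seed(seed)
  S <- matrix(rbinom(n_perm * n, 1, 0.5), n_perm, n)

  out <- data.frame(sensor = sensors,
                    label = rec$sensor_labels[sensors],
                    z = NA_real_, null_quantile = NA_real_,
                    frac_null_below = NA_real_, selected = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sensors)) {
    zm <- analytic_signal(rec$data[sensors[i], idx_trials, , drop = TRUE],
                          rec$fs, freq, halfwidth)
    if (is.null(dim(zm))) zm <- matrix(zm, nrow = 1)
    r <- swap_permutation_z(zm, zr, ws, wb, S)
    out$z[i] <- r$empirical
    out$null_quantile[i] <- quantile(r$null, 1 - alpha, type = 1,
                                     names = FALSE)
    out$frac_null_below[i] <- mean(r$null < r$empirical)
    out$selected[i] <- r$empirical > out$null_quantile[i]
  }
  attr(out, "n_perm") <- n_perm
  attr(out, "alpha") <- alpha
  attr(out, "n_trials") <- n
  out
}

## Empirical and permutation-null z for one sensor, by algebraic swap of
## the baseline/search windows. zm, zr: trials x samples analytic signals.
swap_permutation_z <- function(zm, zr, ws, wb, S) {
  n <- nrow(zm)
  Xs <- zm[, ws, drop = FALSE] * Conj(zr[, ws, drop = FALSE])
  Xb <- zm[, wb, drop = FALSE] * Conj(zr[, wb, drop = FALSE])
  As <- Mod(zm[, ws, drop = FALSE]); Ab <- Mod(zm[, wb, drop = FALSE])
  Bs <- Mod(zr[, ws, drop = FALSE]); Bb <- Mod(zr[, wb, drop = FALSE])

  sum_coh <- function(SX, SA, SB)  # window-mean coherence from trial sums
    rowMeans(Mod(SX) * n / (SA * SB))

  csum <- function(M) matrix(colSums(M), nrow(S), ncol(M), byrow = TRUE)
  Dx <- Xs - Xb; Da <- As - Ab; Db <- Bs - Bb
  MxS <- csum(Xs) - S %*% Dx; MxB <- csum(Xb) + S %*% Dx
  MaS <- csum(As) - S %*% Da; MaB <- csum(Ab) + S %*% Da
  MbS <- csum(Bs) - S %*% Db; MbB <- csum(Bb) + S %*% Db

  null_cs <- sum_coh(MxS, MaS, MbS)
  null_cb <- sum_coh(MxB, MaB, MbB)
  emp_cs <- mean(Mod(colSums(Xs)) * n / (colSums(As) * colSums(Bs)))
  emp_cb <- mean(Mod(colSums(Xb)) * n / (colSums(Ab) * colSums(Bb)))

  clamp <- function(x) pmin(x, 1 - 1e-12)
  z <- function(cs, cb) (atanh(clamp(cs)) - atanh(clamp(cb))) * sqrt(n - 1)
  list(empirical = z(emp_cs, emp_cb), null = z(null_cs, null_cb))
}
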