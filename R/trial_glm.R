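#' Single-trial Welch coherence at a tagging frequency
#'
#' Quantifies the flicker-locked response of one trial as the
#' magnitude-squared coherence between a sensor and the reference,
#' estimated by Welch's method: the epoch is bandpass filtered (two-pass
#' Butterworth, 30-80 Hz by default, applied to the generously padded full
#' epoch to keep filter edges away from the window of interest), the
#' analysis interval (0.2-0.5 s after search onset by default) is cut into
#' Hanning-tapered windows of 0.1 s stepped by 0.025 s (75% overlap), each
#' window is zero-padded to `nfft` samples and Fourier transformed, and
#' coherence is formed from the averaged cross- and auto-spectra
#' `|<Sxy>|^2 / (<Sxx> <Syy>)` at the FFT bin nearest the tagging
#' frequency.
#'
#' @param x Numeric vector, one trial of one sensor.
#' @param ref Numeric vector, the matching reference samples.
#' @param fs Sampling rate in Hz.
#' @param time Time axis in seconds aligned with `x` (0 = search onset).
#' @param freq Tagging frequency in Hz whose bin is returned.
#' @param interval Analysis interval in seconds.
#' @param window,step Window length and step in seconds.
#' @param nfft FFT length after zero padding (default 512).
#' @param band Bandpass edges in Hz; `NULL` skips filtering.
#' @param filter_order Butterworth order per pass.
#' @return Coherence magnitude in `[0, 1]` with attributes `n_windows` and
#'   `bin_freq` (the actual FFT bin frequency).
#' @export
single_trial_coherence <- function(x, ref, fs, time, freq,
                                   interval = c(0.2, 0.5), window = 0.1,
                                   step = 0.025, nfft = 512,
                                   band = c(30, 80), filter_order = 4) {
  stopifnot(length(x) == length(time), length(ref) == length(x))
  if (!is.null(band)) {
    bf <- signal::butter(filter_order, band / (fs / 2), type = "pass")
    x <- signal::filtfilt(bf, x)
    ref <- signal::filtfilt(bf, ref)
  }
  nw <- round(window * fs)
  if (interval[2] - interval[1] < window + step - 1e-9)
    stop("interval too short: coherence needs at least 2 windows",
         call. = FALSE)
  starts <- seq(interval[1], interval[2] - window + 1e-9, by = step)
  i0 <- round((starts - time[1]) * fs) + 1L
  if (any(i0 < 1) || any(i0 + nw - 1 > length(x)))
    stop("analysis interval outside the epoch", call. = FALSE)
  taper <- as.numeric(signal::hanning(nw))
  seg <- vapply(i0, function(i) c(x[i:(i + nw - 1)] * taper,
                                  rep(0, nfft - nw)), numeric(nfft))
  segr <- vapply(i0, function(i) c(ref[i:(i + nw - 1)] * taper,
                                   rep(0, nfft - nw)), numeric(nfft))
  X <- stats::mvfft(seg)
  Y <- stats::mvfft(segr)
  Sxy <- rowMeans(X * Conj(Y))
  Sxx <- rowMeans(Mod(X)^2)
  Syy <- rowMeans(Mod(Y)^2)
  fgrid <- (seq_len(nfft) - 1) * fs / nfft
  half <- seq_len(floor(nfft / 2) + 1)
  b <- half[which.min(abs(fgrid[half] - freq))]
  coh <- Mod(Sxy[b])^2 / (Sxx[b] * Syy[b])
  structure(coh, n_windows = length(starts), bin_freq = fgrid[b])
}

#' Single-trial RIFT responses for target and distractor colours
#'
#' Runs [single_trial_coherence()] for every trial and sensor, once at the
#' frequency tagging the trial's target colour and once at the distractor
#' colour's frequency (for unguided trials the design's randomised colour
#' label plays the target role).
#'
#' @param rec A [tagged_recording()].
#' @param trials Trial table (rows define the trials analysed).
#' @param sensors Sensor indices (default all).
#' @param ... Passed to [single_trial_coherence()].
#' @return List with `target` and `distractor`, each a matrix
#'   `trials x sensors` of coherence values, plus `trials` (the table).
#' @export
single_trial_rift <- function(rec, trials, sensors = NULL, ...) {
  if (is.null(sensors)) sensors <- seq_len(dim(rec$data)[1])
  target_freq <- ifelse(trials$target_colour == "yellow",
                        trials$freq_yellow, trials$freq_cyan)
  distractor_freq <- ifelse(target_freq == rec$tag_freqs[1],
                            rec$tag_freqs[2], rec$tag_freqs[1])
  n <- nrow(trials)
  tg <- matrix(NA_real_, n, length(sensors))
  ds <- matrix(NA_real_, n, length(sensors))
  for (i in seq_len(n)) {
    tr <- trials$trial_index[i] + 1L
    for (j in 1:2) {
      f <- rec$tag_freqs[j]
      rf <- rec$ref[j, tr, ]
      for (s in seq_along(sensors)) {
        v <- single_trial_coherence(rec$data[sensors[s], tr, ], rf,
                                    rec$fs, rec$time, freq = f, ...)
        if (target_freq[i] == f) tg[i, s] <- v
        if (distractor_freq[i] == f) ds[i, s] <- v
      }
    }
  }
  list(target = tg, distractor = ds, trials = trials, sensors = sensors)
}

#' Design matrix for the stimulus-role GLM
#'
#' Each trial contributes two observations -- its target-colour and its
#' distractor-colour RIFT response -- concatenated as one long vector (all
#' target-colour rows first, then all distractor-colour rows). Guided
#' trials load on the target (T) or distractor (D) indicator; both
#' observations of an unguided trial load on the unguided (U) indicator.
#' The fourth column is time-on-task (tot), shared by the two observations
#' of a trial and spanning `[0, 1]` over the experiment. The three
#' indicators sum to the all-ones vector, which is why the design carries
#' no separate intercept.
#'
#' @param trials Trial table with `condition` and `tot` columns.
#' @return List with `X` (matrix `2n x 4`, columns `T`, `U`, `D`, `tot`)
#'   and `row_map` (data frame mapping rows to `(trial_index, role)`).
#' @export
build_design <- function(trials) {
  n <- nrow(trials)
  guided <- trials$condition == "guided"
  Tcol <- c(as.numeric(guided), rep(0, n))
  Ucol <- c(as.numeric(!guided), as.numeric(!guided))
  Dcol <- c(rep(0, n), as.numeric(guided))
  tot <- c(trials$tot, trials$tot)
  X <- cbind(T = Tcol, U = Ucol, D = Dcol, tot = tot)
  row_map <- data.frame(trial_index = rep(trials$trial_index, 2),
                        role = rep(c("target", "distractor"), each = n),
                        stringsAsFactors = FALSE)
  ## full column rank is only attainable (and required) for mixed designs
  if (any(guided) && any(!guided) && qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient for this trial subset",
         call. = FALSE)
  list(X = X, row_map = row_map)
}

#' Assemble the concatenated response vector for [build_design()]
#'
#' @param rift Output of [single_trial_rift()].
#' @return Matrix `2n x sensors`: target-colour rows stacked over
#'   distractor-colour rows, aligned with `build_design()$X`.
#' @export
rift_response_vector <- function(rift) {
  rbind(rift$target, rift$distractor)
}

#' Fit a GLM by pseudoinverse and compute contrast statistics
#'
#' Ordinary least squares via the Moore-Penrose pseudoinverse,
#' `B = pinv(X) y`, fitted independently per sensor (column of `y`).
#' Residual variance uses the unbiased denominator
#' `observations - rank(X)`. For each contrast vector `c`:
#' `cope = c B`, `varcope = c (X'X)^- c' sigma^2`, `t = cope/sqrt(varcope)`.
#' Zero residual variance flags the t value as undefined (NA) rather than
#' returning an infinity.
#'
#' @param y Numeric vector or matrix `observations x sensors`.
#' @param X Design matrix (or the list from [build_design()]).
#' @param contrasts Named list of contrast vectors; defaults to the target
#'   boosting contrast `T - U = [1, -1, 0, 0]` and the distractor
#'   suppression contrast `D - U = [0, -1, 1, 0]`.
#' @return List of class `glm_result`: `betas` (`p x sensors`), `sigma2`,
#'   `dof`, and per-contrast `cope`, `varcope`, `t` matrices
#'   (`contrasts x sensors`), plus `undefined` (logical matrix).
#' @export
fit_glm <- function(y, X,
                    contrasts = list(target = c(1, -1, 0, 0),
                                     distractor = c(0, -1, 1, 0))) {
  if (is.list(X) && !is.null(X$X)) X <- X$X
  y <- as.matrix(y)
  stopifnot(nrow(y) == nrow(X))
  nobs <- nrow(X)
  r <- qr(X)$rank
  B <- MASS::ginv(X) %*% y
  res <- y - X %*% B
  dof <- nobs - r
  if (dof <= 0) stop("no residual degrees of freedom", call. = FALSE)
  sigma2 <- colSums(res^2) / dof
  XtXinv <- MASS::ginv(crossprod(X))
  nc <- length(contrasts)
  cope <- varcope <- tval <- matrix(NA_real_, nc, ncol(y),
                                    dimnames = list(names(contrasts),
                                                    colnames(y)))
  for (i in seq_len(nc)) {
    cv <- contrasts[[i]]
    stopifnot(length(cv) == ncol(X))
    cope[i, ] <- drop(cv %*% B)
    q <- drop(t(cv) %*% XtXinv %*% cv)
    varcope[i, ] <- q * sigma2
  }
  undefined <- varcope <= .Machine$double.eps * max(1, max(abs(cope)))^2
  tval <- ifelse(undefined, NA_real_, cope / sqrt(varcope))
  structure(list(betas = B, sigma2 = sigma2, dof = dof, rank = r,
                 cope = cope, varcope = varcope, t = tval,
                 undefined = undefined, contrasts = contrasts),
            class = "glm_result")
}

#' GLM linking the RIFT response to behaviour
#'
#' Fits per-sensor responses from guided trials to a design with a
#' constant, time-on-task, and reaction time; the contrast on the rt
#' column tests whether the single-trial RIFT response covaries with
#' response speed.
#'
#' @param y Vector or matrix `trials x sensors` of RIFT responses for one
#'   stimulus role, guided trials only.
#' @param trials Matching guided-trial table with `tot` and `rt` (no NAs).
#' @return A `glm_result` with contrasts `rt = c(0, 0, 1)` and
#'   `tot = c(0, 1, 0)`.
#' @export
behaviour_glm <- function(y, trials) {
  if (any(trials$condition != "guided"))
    stop("behaviour GLM is defined for guided trials only", call. = FALSE)
  if (anyNA(trials$rt))
    stop("rt must be present for all trials", call. = FALSE)
  X <- cbind(const = 1, tot = trials$tot, rt = trials$rt)
  fit_glm(y, X, contrasts = list(rt = c(0, 0, 1), tot = c(0, 1, 0)))
}
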