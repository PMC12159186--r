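#' Exclude invalid trials
#'
#' Removes trials with implausibly short reaction times (at or below
#' `min_rt`, default 200 ms) and trials without a response, returning the
#' filtered table together with an exclusion log. Idempotent.
#'
#' @param trials Trial table with `rt` (NA allowed) and `response` columns.
#' @param min_rt Exclusion threshold in seconds; trials with `rt <= min_rt`
#'   are dropped.
#' @return A list with `trials` (filtered copy) and `log` (data frame with
#'   one row per excluded trial and a `reason` column).
#' @export
exclude_trials <- function(trials, min_rt = 0.2) {
  stopifnot("rt" %in% names(trials))
  no_resp <- if ("response" %in% names(trials))
    trials$response == "none" | is.na(trials$rt) else is.na(trials$rt)
  fast <- !no_resp & trials$rt <= min_rt
  drop <- no_resp | fast
  log <- trials[drop, , drop = FALSE]
  log$reason <- ifelse(no_resp[drop], "no_response", "rt_too_short")
  list(trials = trials[!drop, , drop = FALSE], log = log)
}

#' Signal-detection sensitivity d'
#'
#' `d' = z(H) - z(FA)`, the difference of standard-normal quantiles of the
#' hit rate (target-present trials) and the false-alarm rate (target-absent
#' trials). Rates of exactly 0 or 1 are first adjusted by the half-count
#' rule (`0 -> 1/(2N)`, `1 -> 1 - 1/(2N)`) so the quantiles stay finite.
#'
#' @param hits,misses Counts on target-present trials.
#' @param false_alarms,correct_rejections Counts on target-absent trials.
#' @param correction `"half-count"` (default) or `"none"`.
#' @return Sensitivity d' (dimensionless).
#' @export
#' @examples
#' dprime(16, 4, 4, 16)  # H = 0.8, FA = 0.2
dprime <- function(hits, misses, false_alarms, correct_rejections,
                   correction = c("half-count", "none")) {
  correction <- match.arg(correction)
  stopifnot(all(c(hits, misses, false_alarms, correct_rejections) >= 0))
  n_p <- hits + misses
  n_a <- false_alarms + correct_rejections
  if (n_p == 0 || n_a == 0)
    stop("need at least one target-present and one target-absent trial",
         call. = FALSE)
  H <- hits / n_p
  FA <- false_alarms / n_a
  if (correction == "half-count") {
    H <- edge_correct(H, n_p)
    FA <- edge_correct(FA, n_a)
  }
  qnorm(H) - qnorm(FA)
}

edge_correct <- function(p, n) {
  if (p == 0) return(1 / (2 * n))
  if (p == 1) return(1 - 1 / (2 * n))
  p
}

#' Behavioural counts from a trial table
#'
#' @param trials Trial table with `target_present` and `response` columns
#'   (no-response trials should have been excluded).
#' @return A list with `hits`, `misses`, `false_alarms`,
#'   `correct_rejections`.
#' @export
behaviour_counts <- function(trials) {
  yes <- trials$response == "present"
  list(hits = sum(trials$target_present & yes),
       misses = sum(trials$target_present & !yes),
       false_alarms = sum(!trials$target_present & yes),
       correct_rejections = sum(!trials$target_present & !yes))
}

#' Per-cell behavioural summary
#'
#' Mean reaction time (responded trials) and d' per condition x set-size
#' cell.
#'
#' @param trials Trial table (after [exclude_trials()]).
#' @return Data frame with one row per cell: `condition`, `set_size`,
#'   `n_trials`, `mean_rt`, `dprime`.
#' @export
condition_summary <- function(trials) {
  cells <- unique(trials[, c("condition", "set_size")])
  cells <- cells[order(cells$condition, cells$set_size), ]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$condition == cells$condition[i] &
                    trials$set_size == cells$set_size[i], ]
    cnt <- behaviour_counts(sub)
    data.frame(condition = cells$condition[i],
               set_size = cells$set_size[i],
               n_trials = nrow(sub),
               mean_rt = mean(sub$rt, na.rm = TRUE),
               dprime = dprime(cnt$hits, cnt$misses, cnt$false_alarms,
                               cnt$correct_rejections),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Median split on reaction time
#'
#' Labels trials within each condition x set-size cell as `fast` or `slow`
#' relative to the cell's median reaction time. Implemented rank-based:
#' trials are ordered by rt and the first `ceiling(n/2)` labelled fast, so
#' label counts never differ by more than one and a trial sitting exactly
#' at an odd-n median goes to the fast half.
#'
#' @param trials Trial table with an `rt` column (no NAs).
#' @param by Character vector of grouping columns defining the cells.
#' @return `trials` with an added `split` factor (`"fast"`/`"slow"`).
#' @export
median_split <- function(trials, by = c("condition", "set_size")) {
  key <- interaction(trials[, by, drop = FALSE], drop = TRUE)
  split_lab <- rep(NA_character_, nrow(trials))
  for (cell in levels(key)) {
    idx <- which(key == cell)
    if (length(idx) < 2)
      stop("median split needs at least 2 trials per cell", call. = FALSE)
    ord <- idx[order(trials$rt[idx])]
    n_fast <- ceiling(length(ord) / 2)
    split_lab[ord[seq_len(n_fast)]] <- "fast"
    split_lab[ord[-seq_len(n_fast)]] <- "slow"
  }
  trials$split <- factor(split_lab, levels = c("fast", "slow"))
  trials
}
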