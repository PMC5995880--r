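#' Instantaneous running speed from a position trace
#'
#' Central finite difference on the tracked positions (forward/backward
#' differences at the endpoints), optionally followed by a boxcar average.
#' The default 0.4-s window suppresses video-tracker jitter without biasing
#' the 3 cm/s activity cut used downstream.
#'
#' @param trace Tibble with columns `t`, `x`, `y`.
#' @param smooth_window Boxcar width in seconds; 0 disables smoothing.
#' @return Tibble with columns `t` and `speed` (cm/s), one row per sample.
#' @examples
#' tr <- tibble::tibble(t = 0:10, x = 3 * (0:10), y = 0)
#' compute_speed(tr, smooth_window = 0)
#' @export
compute_speed <- function(trace, smooth_window = 0.4) {
  check_that(nrow(trace) >= 2, "need at least 2 samples to compute speed")
  t <- trace$t; x <- trace$x; y <- trace$y
  n <- length(t)
  ip <- c(2:n, n)   # forward neighbour (backward difference at the end)
  im <- c(1, 1:(n - 1))
  v <- sqrt((x[ip] - x[im])^2 + (y[ip] - y[im])^2) / (t[ip] - t[im])
  if (smooth_window > 0) {
    dt <- median(diff(t))
    k <- max(1L, round(smooth_window / dt))
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1) v <- running_mean(v, k)
  }
  tibble::tibble(t = t, speed = v)
}

# centred running mean with shrinking window at the edges
running_mean <- function(v, k) {
  n <- length(v)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Active-movement intervals
#'
#' Periods of inactivity (speed below `threshold`) are excluded from all
#' spatial analyses; this returns the complementary active intervals. Samples
#' exactly at the threshold count as active (the exclusion rule is a strict
#' `<`). Each active sample contributes one sample period, so the summed
#' interval length equals (active samples) x (sample period).
#'
#' @param trace Tibble with `t`, `x`, `y`.
#' @param speed Tibble from [compute_speed()], aligned to `trace`.
#' @param threshold Speed cut in cm/s (default 3).
#' @return Tibble with columns `start`, `end`: disjoint, sorted, half-open
#'   `[start, end)` intervals in seconds.
#' @export
filter_inactive <- function(trace, speed, threshold = 3) {
  check_that(nrow(speed) == nrow(trace), "`speed` is not aligned to `trace`")
  if (nrow(trace) == 0) return(tibble::tibble(start = numeric(), end = numeric()))
  period <- if (nrow(trace) > 1) median(diff(trace$t)) else 0
  active <- speed$speed >= threshold
  if (!any(active)) return(tibble::tibble(start = numeric(), end = numeric()))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(
    start = trace$t[starts[keep]],
    end = trace$t[ends[keep]] + period
  )
}

# TRUE for each time that falls inside any half-open [start, end) interval
in_intervals <- function(t, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(t)))
  edges <- as.vector(rbind(intervals$start, intervals$end))
  findInterval(t, edges) %% 2L == 1L
}

#' Restrict a spike train to active intervals
#'
#' @param spikes Numeric vector of spike times (s), sorted.
#' @param intervals Tibble from [filter_inactive()].
#' @return Numeric vector of the spikes falling inside any interval, order
#'   preserved. Never increases the spike count; idempotent.
#' @export
restrict_spikes <- function(spikes, intervals) {
  spikes[in_intervals(spikes, intervals)]
}

#' Cluster-drift quality control
#'
#' Flags units whose spike-sorting cluster drifted over a day of recording.
#' Drift is measured on the first-principal-component amplitude of the spike
#' waveforms: the absolute difference between the mean feature in the last
#' and first deciles of the day's spikes, in units of the pooled
#' within-decile standard deviation. Units with drift above `sd_threshold`
#' (default 3 SD) are excluded. The statistic is invariant to affine
#' rescaling of the feature.
#'
#' @param features Tibble with per-spike `t` and `feature`.
#' @param session_labels Vector (length `nrow(features)`) tagging each spike
#'   with its session; QC requires spikes from at least two sessions of the
#'   day, otherwise it is skipped with a warning and the unit retained.
#' @param sd_threshold Exclusion threshold in pooled-SD units (default 3).
#' @return One-row tibble: `decision` ("retain"/"exclude"), `drift_sd`
#'   (the statistic), `n_spikes`.
#' @export
qc_cluster_drift <- function(features, session_labels, sd_threshold = 3) {
  check_that(nrow(features) >= 2, "need at least 2 spikes for drift QC")
  check_that(length(session_labels) == nrow(features),
             "`session_labels` must tag every spike")
  if (dplyr::n_distinct(session_labels) < 2) {
    warn("drift QC skipped: spikes from a single session only; unit retained")
    return(tibble::tibble(decision = "retain", drift_sd = NA_real_,
                          n_spikes = nrow(features)))
  }
  ord <- order(features$t)
  f <- features$feature[ord]
  n <- length(f)
  k <- max(1L, floor(n / 10))
  first <- f[seq_len(k)]
  last <- f[seq.int(n - k + 1L, n)]
  pooled_sd <- sqrt((var_or_zero(first) + var_or_zero(last)) / 2)
  diff_means <- abs(mean(last) - mean(first))
  drift <- if (diff_means == 0) 0 else diff_means / pooled_sd  # 0/0 -> no drift
  tibble::tibble(
    decision = if (is.finite(drift) && drift <= sd_threshold || diff_means == 0)
      "retain" else "exclude",
    drift_sd = drift, n_spikes = n)
}

var_or_zero <- function(x) if (length(x) < 2) 0 else var(x)

#' Putative pyramidal-cell classification
#'
#' Surrogate criteria for separating pyramidal cells from fast-spiking
#' interneurons, based on mean firing rate and the mean lag of the spike-time
#' autocorrelogram: pyramidal cells fire slowly and in bursts, so their mean
#' rate is low and their short-lag autocorrelogram is not dominated by very
#' short intervals. A unit is "pyramidal" iff mean rate <= `rate_ceiling` and
#' the mean pairwise lag within `acg_window` is >= `acg_mean_min`. Note the
#' ACG criterion is deliberately simple: a strongly bursty unit whose
#' autocorrelogram mass sits entirely at 2-5 ms lags can fall below
#' `acg_mean_min` and be classed "other"; the thresholds are configurable.
#'
#' @param spikes Numeric vector of spike times (s).
#' @param session_duration Session length in seconds.
#' @param rate_ceiling Maximum mean rate in Hz (default 8).
#' @param acg_window Autocorrelogram window in ms (default 50).
#' @param acg_mean_min Minimum mean ACG lag in ms (default 8).
#' @param min_spikes Below this spike count classification is not attempted
#'   and the unit is "other" with `low_count = TRUE` (default 50).
#' @return One-row tibble: `class` ("pyramidal"/"other"), `mean_rate`,
#'   `acg_mean_ms`, `low_count`.
#' @export
classify_pyramidal <- function(spikes, session_duration, rate_ceiling = 8,
                               acg_window = 50, acg_mean_min = 8,
                               min_spikes = 50) {
  check_that(session_duration > 0, "`session_duration` must be positive")
  n <- length(spikes)
  rate <- n / session_duration
  if (n < min_spikes) {
    return(tibble::tibble(class = "other", mean_rate = rate,
                          acg_mean_ms = NA_real_, low_count = TRUE))
  }
  acg_mean <- acg_mean_lag(sort(spikes), acg_window / 1000) * 1000
  cls <- if (rate <= rate_ceiling && !is.na(acg_mean) && acg_mean >= acg_mean_min)
    "pyramidal" else "other"
  tibble::tibble(class = cls, mean_rate = rate, acg_mean_ms = acg_mean,
                 low_count = FALSE)
}

# mean of all pairwise spike-time lags in (0, window] seconds, O(n log n)
acg_mean_lag <- function(t, window) {
  n <- length(t)
  if (n < 2) return(NA_real_)
  hi <- findInterval(t + window, t)
  cnt <- hi - seq_len(n)
  cs <- cumsum(c(0, t))
  lag_sum <- (cs[hi + 1L] - cs[seq_len(n) + 1L]) - t * cnt
  if (sum(cnt) == 0) return(NA_real_)
  sum(lag_sum) / sum(cnt)
}

#' Behavioural summary of a session
#'
#' Median running speed and thigmotaxis (mean distance from the arena
#' centre), both over active samples only.
#'
#' @param trace Tibble with `t`, `x`, `y`.
#' @param intervals Active intervals from [filter_inactive()].
#' @param arena An [arena_geometry()].
#' @param smooth_window Speed smoothing window passed to [compute_speed()].
#' @return One-row tibble: `median_speed` (cm/s), `thigmotaxis` (cm),
#'   `active_time` (s). All `NA` if no active samples.
#' @export
behavior_summary <- function(trace, intervals, arena = arena_geometry(),
                             smooth_window = 0.4) {
  if (nrow(intervals) == 0 || nrow(trace) < 2) {
    return(tibble::tibble(median_speed = NA_real_, thigmotaxis = NA_real_,
                          active_time = 0))
  }
  sp <- compute_speed(trace, smooth_window = smooth_window)
  act <- in_intervals(trace$t, intervals)
  r <- sqrt((trace$x - arena$center_x)^2 + (trace$y - arena$center_y)^2)
  tibble::tibble(
    median_speed = median(sp$speed[act]),
    thigmotaxis = mean(r[act]),
    active_time = sum(intervals$end - intervals$start)
  )
}
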