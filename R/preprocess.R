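# Head-saccade detection and quality control. Head-orientation traces are
# sampled at 6 kHz; saccade onset and offset are threshold crossings of
# the smoothed vectorial head speed (default threshold 10 deg/s), and
# responses with reaction times shorter than 150 ms, null responses, or
# multi-peaked velocity profiles are discarded.

trace_fs <- function(trace) {
  fs <- attr(trace, "fs_hz")
  if (is.null(fs)) fs <- 1 / stats::median(diff(trace$t))
  fs
}

#' Smoothed head speed from an orientation trace
#'
#' Low-pass filters azimuth and elevation with a zero-phase 4th-order
#' Butterworth filter (default cutoff 40 Hz, balancing the 6 kHz sensor
#' noise floor against saccade dynamics), differentiates by central
#' differences, and returns the vectorial speed over both channels.
#'
#' @param trace A `head_trace` (columns `t`, `azimuth`, `elevation`;
#'   uniform sampling).
#' @param smooth_cutoff_hz Low-pass cutoff in Hz before differentiation.
#' @return A tibble with `t`, `v_az`, `v_el`, `speed` (deg/s).
#' @export
compute_velocity <- function(trace, smooth_cutoff_hz = 40) {
  fs <- trace_fs(trace)
  n <- nrow(trace)
  if (n < 30) stop("trace too short for velocity filtering")
  bf <- signal::butter(4, smooth_cutoff_hz / (fs / 2), type = "low")
  # edge-replicate padding suppresses filtfilt end transients
  np <- min(n - 1, ceiling(3 * fs / smooth_cutoff_hz))
  smooth <- function(x) {
    xp <- c(rep(x[1], np), x, rep(x[n], np))
    signal::filtfilt(bf, xp)[(np + 1):(np + n)]
  }
  az <- smooth(trace$azimuth)
  el <- smooth(trace$elevation)
  d <- function(x) {
    v <- numeric(n)
    v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2 * fs
    v[1] <- (x[2] - x[1]) * fs
    v[n] <- (x[n] - x[n - 1]) * fs
    v
  }
  v_az <- d(az)
  v_el <- d(el)
  tibble::tibble(t = trace$t, v_az = v_az, v_el = v_el,
                 speed = sqrt(v_az^2 + v_el^2))
}

# Runs of speed >= threshold lasting at least min_ms.
speed_episodes <- function(speed, t, threshold, min_ms) {
  above <- speed >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (t[ends] - t[starts]) * 1000 >= min_ms
  cbind(start = starts[keep], end = ends[keep])
}

# Count distinct velocity peaks above threshold within one episode;
# successive local maxima only count as separate peaks if the valley
# between them dips below half the lower of the two (prominence rule, so
# sensor-noise ripples on a smooth profile are not split into peaks).
count_peaks <- function(speed, idx, threshold) {
  s <- speed[idx]
  n <- length(s)
  if (n < 3) return(1L)
  loc <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n] &
               s[2:(n - 1)] >= threshold) + 1
  if (length(loc) <= 1) return(1L)
  count <- 1L
  for (k in 2:length(loc)) {
    valley <- min(s[loc[k - 1]:loc[k]])
    if (valley < 0.5 * min(s[loc[k - 1]], s[loc[k]])) count <- count + 1L
  }
  count
}

#' Detect the head saccade in one orientation trace
#'
#' Onset is the first upward crossing of the speed threshold after
#' stimulus onset (sustained for at least `min_peak_ms`); offset is the
#' next downward crossing. The endpoint is the mean orientation over a
#' 100 ms hold window starting 50 ms after offset. Profiles with more
#' than one velocity peak above threshold (counting distinct
#' above-threshold episodes and within-episode local maxima) are flagged
#' `anomalous_profile`; traces that never cross threshold are
#' `null_response`.
#'
#' @param trace A `head_trace`.
#' @param threshold Speed threshold in deg/s (default 10).
#' @param stim_onset_ms Stimulus onset time within the trace, ms.
#' @param smooth_cutoff_hz Velocity smoothing cutoff, see
#'   [compute_velocity()].
#' @param min_peak_ms Minimum above-threshold duration for a crossing to
#'   count as movement rather than noise.
#' @param hold_offset_ms,hold_window_ms Endpoint estimation window:
#'   `hold_window_ms` of trace starting `hold_offset_ms` after offset.
#' @return A one-row tibble (class `saccade_event`): `onset_ms`,
#'   `offset_ms`, `endpoint_az`, `endpoint_el`, `peak_velocity`, `rt_ms`,
#'   `n_peaks`, `qc` (`"ok"`, `"null_response"`, `"anomalous_profile"`).
#' @export
detect_saccade <- function(trace, threshold = 10, stim_onset_ms = 0,
                           smooth_cutoff_hz = 40, min_peak_ms = 10,
                           hold_offset_ms = 50, hold_window_ms = 100) {
  vel <- compute_velocity(trace, smooth_cutoff_hz)
  after <- which(trace$t * 1000 >= stim_onset_ms)
  ep <- speed_episodes(vel$speed[after], vel$t[after], threshold, min_peak_ms)
  null_event <- function() {
    ev <- tibble::tibble(onset_ms = NA_real_, offset_ms = NA_real_,
                         endpoint_az = NA_real_, endpoint_el = NA_real_,
                         peak_velocity = max(vel$speed[after]),
                         rt_ms = NA_real_, n_peaks = 0L, qc = "null_response")
    class(ev) <- c("saccade_event", class(ev))
    ev
  }
  if (nrow(ep) == 0) return(null_event())
  onset_i <- after[ep[1, "start"]]
  offset_i <- after[ep[1, "end"]]
  onset_ms <- trace$t[onset_i] * 1000
  offset_ms <- trace$t[offset_i] * 1000
  n_peaks <- sum(vapply(seq_len(nrow(ep)), function(k) {
    count_peaks(vel$speed[after], ep[k, "start"]:ep[k, "end"], threshold)
  }, integer(1)))
  fs <- trace_fs(trace)
  h0 <- offset_i + round(hold_offset_ms / 1000 * fs)
  h1 <- h0 + round(hold_window_ms / 1000 * fs)
  h0 <- min(h0, nrow(trace)); h1 <- min(h1, nrow(trace))
  ev <- tibble::tibble(
    onset_ms = onset_ms, offset_ms = offset_ms,
    endpoint_az = mean(trace$azimuth[h0:h1]),
    endpoint_el = mean(trace$elevation[h0:h1]),
    peak_velocity = max(vel$speed[onset_i:offset_i]),
    rt_ms = onset_ms - stim_onset_ms,
    n_peaks = as.integer(n_peaks),
    qc = if (n_peaks > 1 || nrow(ep) > 1) "anomalous_profile" else "ok")
  class(ev) <- c("saccade_event", class(ev))
  ev
}

#' Quality-control filter for detected saccades
#'
#' Discards null responses, anomalous (multi-peaked) velocity profiles,
#' and saccades with reaction times shorter than `min_rt_ms` (those start
#' well before the elevation percept can be formed). Kept events have
#' `qc == "ok"` and `rt_ms >= min_rt_ms`; early responses are relabelled
#' `"early_rt"` in the discarded set.
#'
#' @param events A tibble of saccade events (rows from [detect_saccade()]).
#' @param min_rt_ms Minimum admissible reaction time in ms (default 150).
#' @return A list with tibbles `kept` and `discarded`.
#' @export
qc_filter <- function(events, min_rt_ms = 150) {
  early <- events$qc == "ok" & !is.na(events$rt_ms) &
    events$rt_ms < min_rt_ms
  events$qc[early] <- "early_rt"
  keep <- events$qc == "ok"
  list(kept = events[keep, ], discarded = events[!keep, ])
}

#' Check that the head stayed still during a discrimination trial
#'
#' `TRUE` iff the maximum deviation of head orientation (vector magnitude
#' over azimuth and elevation) from its initial position stays within
#' `max_excursion_deg` (inclusive) during the stimulus window. The
#' initial position is the mean over the first 10 ms of the trace.
#'
#' @param trace A `head_trace`.
#' @param max_excursion_deg Excursion limit in degrees (default 5).
#' @param stim_onset_ms,stim_duration_ms Stimulus window in ms; by
#'   default the whole trace is checked.
#' @return Logical.
#' @export
head_still_check <- function(trace, max_excursion_deg = 5,
                             stim_onset_ms = 0, stim_duration_ms = NULL) {
  t_ms <- trace$t * 1000
  base_idx <- which(t_ms <= t_ms[1] + 10)
  az0 <- mean(trace$azimuth[base_idx])
  el0 <- mean(trace$elevation[base_idx])
  in_win <- t_ms >= stim_onset_ms
  if (!is.null(stim_duration_ms))
    in_win <- in_win & t_ms <= stim_onset_ms + stim_duration_ms
  exc <- sqrt((trace$azimuth[in_win] - az0)^2 +
              (trace$elevation[in_win] - el0)^2)
  max(exc) <= max_excursion_deg
}
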