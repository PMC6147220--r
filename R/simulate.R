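# Synthetic behavioral data: localization endpoints under the
# level-weighted-average (WA) model and a rival bistable model, binomial
# 2AFC choices, and raw head-orientation traces with a single saccade.
#
# WA model for a double trial:  R ~ Normal(g*(w*T + (1-w)*D) + b, sigma_d)
# Single trial:                 R ~ Normal(g*T + b, sigma_s)
# where T/D are target/distractor elevations (deg), g the localization
# gain, b the bias (deg), and w in [0,1] the target-location weight.

#' Weighted-average prediction of the response elevation
#'
#' `g * (w * target + (1 - w) * distractor) + b`. With `w = 1` this reduces
#' exactly to the single-sound prediction [single_predict()], whatever the
#' distractor.
#'
#' @param target_el,distractor_el Elevations in degrees (vectorized).
#' @param w Target weight in `[0, 1]`.
#' @param g Localization gain.
#' @param b Localization bias in degrees.
#' @return Predicted response elevation(s) in degrees.
#' @export
wa_predict <- function(target_el, distractor_el, w, g = 1, b = 0) {
  g * (w * target_el + (1 - w) * distractor_el) + b
}

#' Single-sound prediction of the response elevation
#'
#' @inheritParams wa_predict
#' @return `g * target_el + b`.
#' @export
single_predict <- function(target_el, g = 1, b = 0) {
  g * target_el + b
}

#' Default behavioral parameter set
#'
#' A parameter set qualitatively matching normal-hearing double-sound
#' localization: target weights rise monotonically (logistically) with the
#' AM-vs-GWN level difference, from ~0 at -10 dB to ~1 at +10 dB, with the
#' 5 Hz weight curve shifted ~3 dB toward positive level differences (the
#' 5 Hz AM sound at phase 0 is initially softer, so equal weighting needs
#' a louder target); gain 0.86, bias 0, single-sound SD 9 deg; double-sound
#' SD elevated overall and peaking at the equal-weight point; 2AFC
#' identification near ceiling for singles, at or below chance for equal-
#' level doubles, with a distractor bias at 5 Hz that co-varies with
#' modulation phase.
#'
#' @param w_scale_db Logistic slope (dB) of the weight-vs-level-difference
#'   curve.
#' @param shift_5hz_db Rightward shift (dB) of the 5 Hz curve.
#' @return A list of class `behavior_params` with elements `g`, `b`,
#'   `sigma_s`, `w_table` (per-condition `w` and `sigma_d`), `theta_table`
#'   (per-condition identification rates), `model`, `p_target`.
#' @export
default_behavior_params <- function(w_scale_db = 2.2, shift_5hz_db = 3) {
  grid <- expand.grid(fm_hz = FM_LEVELS, delta_l_db = DELTA_L_LEVELS)
  shift <- ifelse(grid$fm_hz == 5, shift_5hz_db, 0)
  w <- stats::plogis((grid$delta_l_db - shift) / w_scale_db)
  sigma_d <- 11 + 3 * exp(-((grid$delta_l_db - shift) / 4)^2)
  w_table <- tibble::tibble(fm_hz = grid$fm_hz, delta_l_db = grid$delta_l_db,
                            w = w, sigma_d = sigma_d)
  theta_table <- tibble::tibble(
    trial_type = rep(c("single", "double"), each = 3),
    fm_hz = rep(c(5, 120, 2000), 2),
    theta = c(0.98, 0.98, 0.98, 0.32, 0.5, 0.5))
  phases <- (0:7) * pi / 4
  theta_phase <- tibble::tibble(
    trial_type = rep(c("single", "double"), each = 8),
    phase_rad = rep(phases, 2),
    theta = c(rep(0.98, 8), 0.38 - 0.10 * cos(phases)))
  structure(list(g = 0.86, b = 0, sigma_s = 9, w_table = w_table,
                 theta_table = theta_table, theta_phase = theta_phase,
                 model = "weighted_average", p_target = 0.5),
            class = "behavior_params")
}

lookup_condition <- function(trials, w_table) {
  key_t <- paste(trials$fm_hz, trials$delta_l_db)
  key_w <- paste(w_table$fm_hz, w_table$delta_l_db)
  idx <- match(key_t, key_w)
  if (anyNA(idx)) {
    miss <- unique(key_t[is.na(idx)])
    stop("no behavioral parameters for condition(s) (fm delta_l): ",
         paste(miss, collapse = ", "))
  }
  idx
}

rt_truncnorm <- function(n, mean_ms = 250, sd_ms = 50, lower_ms = 160) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    out[todo] <- stats::rnorm(length(todo), mean_ms, sd_ms)
    todo <- todo[out[todo] < lower_ms]
  }
  out
}

#' Simulate localization endpoints under the weighted-average model
#'
#' Single trials draw `Normal(g*T + b, sigma_s)`; double trials draw
#' `Normal(g*(w*T + (1-w)*D) + b, sigma_d)` with `w` and `sigma_d` looked
#' up per (modulation frequency, level difference) condition. Reaction
#' times are truncated-normal (mean 250, sd 50, floor 160 ms) so default
#' data pass the 150 ms quality cut.
#'
#' @param trials A `trial_table` from the design builders.
#' @param params A `behavior_params` list (see [default_behavior_params()]).
#' @param seed Integer seed; the full response set is reproducible from it.
#' @param rt_mean_ms,rt_sd_ms,rt_floor_ms Reaction-time distribution
#'   (truncated normal), configurable to produce quality-control failures.
#' @return A tibble with `index`, `trial_type`, `response_el`, `rt_ms`.
#' @export
simulate_localization <- function(trials, params, seed = 1L,
                                  rt_mean_ms = 250, rt_sd_ms = 50,
                                  rt_floor_ms = 160) {
  is_d <- trials$trial_type == "double"
  mu <- sd <- numeric(nrow(trials))
  mu[!is_d] <- single_predict(trials$target_el[!is_d], params$g, params$b)
  sd[!is_d] <- params$sigma_s
  if (any(is_d)) {
    idx <- lookup_condition(trials[is_d, ], params$w_table)
    mu[is_d] <- wa_predict(trials$target_el[is_d], trials$distractor_el[is_d],
                           params$w_table$w[idx], params$g, params$b)
    sd[is_d] <- params$w_table$sigma_d[idx]
  }
  withr::with_seed(as.integer(seed), {
    tibble::tibble(index = trials$index, trial_type = trials$trial_type,
                   response_el = stats::rnorm(nrow(trials), mu, sd),
                   rt_ms = rt_truncnorm(nrow(trials), rt_mean_ms, rt_sd_ms,
                                        rt_floor_ms))
  })
}

#' Simulate localization endpoints under the bistable model
#'
#' The rival model: on each double trial the response targets either the
#' target (probability `p_target`) or the distractor, with single-sound
#' accuracy `sigma_s` around the chosen source, rather than their weighted
#' average. Produces bimodal endpoint distributions for well-separated
#' sources; fitting the weighted-average model to such data inflates the
#' double-sound SD.
#'
#' @inheritParams simulate_localization
#' @return A tibble with `index`, `trial_type`, `response_el`, `rt_ms`.
#' @export
simulate_bistable <- function(trials, params, seed = 1L) {
  p <- params$p_target %||% 0.5
  if (p < 0 || p > 1) stop("p_target must lie in [0, 1]")
  is_d <- trials$trial_type == "double"
  withr::with_seed(as.integer(seed), {
    pick_target <- stats::runif(nrow(trials)) < p
    center <- ifelse(!is_d | pick_target, trials$target_el,
                     trials$distractor_el)
    tibble::tibble(index = trials$index, trial_type = trials$trial_type,
                   response_el = stats::rnorm(nrow(trials),
                                              single_predict(center, params$g,
                                                             params$b),
                                              params$sigma_s),
                   rt_ms = rt_truncnorm(nrow(trials)))
  })
}

#' Simulate two-alternative forced-choice responses
#'
#' Each trial's up/down choice is correct (pointing at the AM target's
#' direction) with its condition's identification rate `theta`,
#' independently across trials.
#'
#' @param trials A discrimination `trial_table`.
#' @param theta Either a single rate in `[0, 1]`, or a tibble with a
#'   `theta` column plus key columns (any of `trial_type`, `fm_hz`,
#'   `phase_rad`) matched against the trials.
#' @param seed Integer seed.
#' @return A tibble with `index`, `trial_type`, `correct` (logical) and
#'   `choice` (`"up"`/`"down"`).
#' @export
simulate_discrimination <- function(trials, theta, seed = 1L) {
  if (is.numeric(theta) && length(theta) == 1) {
    th <- rep(theta, nrow(trials))
  } else {
    keys <- intersect(setdiff(names(theta), "theta"), names(trials))
    if (!length(keys)) stop("theta table shares no key columns with trials")
    key_t <- do.call(paste, trials[keys])
    key_p <- do.call(paste, theta[keys])
    idx <- match(key_t, key_p)
    if (anyNA(idx))
      stop("no theta for condition(s): ",
           paste(unique(key_t[is.na(idx)]), collapse = ", "))
    th <- theta$theta[idx]
  }
  if (any(th < 0 | th > 1)) stop("theta must lie in [0, 1]")
  withr::with_seed(as.integer(seed), {
    correct <- stats::runif(nrow(trials)) < th
    target_up <- trials$target_el > 0
    tibble::tibble(index = trials$index, trial_type = trials$trial_type,
                   correct = correct,
                   choice = ifelse(xor(correct, target_up), "down", "up"))
  })
}

#' Simulate a raw head-orientation trace containing one saccade
#'
#' The head holds (0, 0) until the reaction time, then executes a single
#' minimum-jerk movement (single-peaked, symmetric velocity profile) to
#' the endpoint and holds it for the rest of the 1500 ms recording.
#' Low-pass-filtered sensor noise is added to both channels. Movement
#' duration scales with amplitude (80 ms + 4 ms/deg).
#'
#' @param endpoint_el Saccade endpoint elevation in degrees, within
#'   `[-90, 90]`.
#' @param rt_ms Saccade onset time re stimulus onset (trace start), ms.
#' @param seed Integer noise seed.
#' @param endpoint_az Endpoint azimuth in degrees (default 0).
#' @param fs_hz Sample rate (6 kHz as acquired).
#' @param duration_ms Trace duration (1500 ms as acquired).
#' @param noise_sd Sensor noise SD in degrees (0 disables noise); the default
#'   0.02 deg reflects the resolution of a coil system after its 120 Hz
#'   acquisition filter.
#' @param noise_cutoff_hz Low-pass cutoff of the sensor noise.
#' @return A tibble of class `head_trace` with columns `t` (s),
#'   `azimuth`, `elevation`, and attribute `fs_hz`.
#' @export
simulate_head_trace <- function(endpoint_el, rt_ms = 250, seed = 1L,
                                endpoint_az = 0, fs_hz = 6000,
                                duration_ms = 1500, noise_sd = 0.02,
                                noise_cutoff_hz = 20) {
  if (abs(endpoint_el) > 90 || abs(endpoint_az) > 90)
    stop("endpoint must lie within +/-90 degrees")
  n <- n_samples_for(duration_ms, fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  amp <- sqrt(endpoint_az^2 + endpoint_el^2)
  dur_s <- (80 + 4 * amp) / 1000
  tau <- pmin(pmax((t - rt_ms / 1000) / dur_s, 0), 1)
  profile <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  az <- endpoint_az * profile
  el <- endpoint_el * profile
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed), {
      matrix(stats::rnorm(2 * n), ncol = 2)
    })
    noise <- apply(noise, 2, function(x) {
      y <- fft_lowpass(x, fs_hz, noise_cutoff_hz)
      y / stats::sd(y) * noise_sd
    })
    az <- az + noise[, 1]
    el <- el + noise[, 2]
  }
  out <- tibble::tibble(t = t, azimuth = az, elevation = el)
  attr(out, "fs_hz") <- fs_hz
  class(out) <- c("head_trace", class(out))
  out
}

fft_lowpass <- function(x, fs_hz, cutoff_hz) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs_hz / n
  absf <- pmin(f, fs_hz - f)
  X <- stats::fft(x)
  X[absf > cutoff_hz] <- 0 + 0i
  Re(stats::fft(X, inverse = TRUE)) / n
}
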