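#' @name detector_core
#' @title Adaptive-threshold R-wave detector with TTL trigger output
#'
#' @description
#' The conversion from ECG to trigger pulses runs on a fixed loop tick
#' (default 5 ms).  Each tick the detector:
#'
#' 1. estimates the ECG derivative as an un-normalized two-sample finite
#'    difference `ecg(t + tick) - ecg(t)`;
#' 2. compares it to an adaptive threshold `thr`: if the difference
#'    exceeds `thr` and the last detection is more than the refractory
#'    period ago, an R-wave is registered, the heart-rate period
#'    `Tj = ti - ti-1` (HR = 60/Tj) is updated and `thr` is re-set to the
#'    current difference; otherwise `thr` decays quasi-exponentially,
#'    `thr <- thr * (1 - x)`;
#' 3. schedules the next trigger: the TTL line goes high at the first
#'    tick strictly later than `ti + (Tj - dtMP)`, i.e. `dtMP` seconds
#'    before the next predicted derivative maximum;
#' 4. lowers the TTL line at the first tick at which it has been high for
#'    at least the pulse width (default 25 ms).
#'
#' Trigger output is suppressed until two detections have established a
#' period estimate.  The threshold re-set from the signal itself makes
#' detection times invariant under positive amplitude scaling.
NULL

# Pre-computed per-run constants derived from a detector_config.
tick_constants <- function(cfg) {
  list(
    tick = cfg$tick,
    x = cfg$decay_rate,
    one_minus_x = 1 - cfg$decay_rate,
    exp_law = identical(cfg$decay_law, "true_exponential"),
    refr_ticks = ticks_strictly_over(cfg$refractory, cfg$tick),
    pw_ticks = ticks_at_least(cfg$pulse_width, cfg$tick),
    dtmp = cfg$dt_mp,
    min_period = if (is.null(cfg$max_hr)) NULL else 60 / cfg$max_hr,
    max_period = if (is.null(cfg$min_hr)) NULL else 60 / cfg$min_hr
  )
}

#' Fresh detector state
#'
#' The live algorithm state: threshold, last detection, period estimate,
#' TTL level, pulse timer and the queue of pending trigger times.  The
#' threshold is unset (`NA`) until the first processed tick initializes
#' it from the first difference magnitude.
#'
#' @return an object of class `detector_state`.
#' @export
detector_state <- function() {
  structure(
    list(thr = NA_real_, last_index = NA_integer_, period = NA_real_,
         hr = NA_real_, ttl_level = 0L, pulse_raised_index = NA_integer_,
         detections_seen = 0L, pending = numeric(0), clamp_warned = FALSE,
         ev = 0L),
    class = "detector_state"
  )
}

#' @export
print.detector_state <- function(x, ...) {
  cat(sprintf(
    "<detector_state: thr=%s, detections=%d, Tj=%s s, HR=%s bpm, TTL=%s>\n",
    if (is.na(x$thr)) "unset" else format(x$thr, digits = 4),
    x$detections_seen,
    if (is.na(x$period)) "unset" else format(x$period, digits = 4),
    if (is.na(x$hr)) "unset" else format(x$hr, digits = 4),
    if (x$ttl_level == 1L) "high" else "low"))
  invisible(x)
}

# One tick of the state machine, index-based.  `d` is the finite
# difference at tick k (NA when no difference is defined, i.e. the last
# sample).  Events are flagged in st$ev as a bitmask:
# 1 = ttl_rising, 2 = ttl_falling, 4 = detection.
advance_tick <- function(st, d, k, cc) {
  ev <- 0L
  raised <- FALSE

  # -- TTL pulse logic, independent of detection --------------------
  if (length(st$pending)) {
    due <- st$pending <= k
    if (any(due)) {
      st$pending <- st$pending[!due]
      if (st$ttl_level == 0L) {
        st$ttl_level <- 1L
        st$pulse_raised_index <- k
        raised <- TRUE
        ev <- ev + 1L
      }
      # a schedule coming due while the line is already high is
      # swallowed: the pulse is not extended and no edge is emitted
    }
  }
  if (!raised && st$ttl_level == 1L &&
      (k - st$pulse_raised_index) >= cc$pw_ticks) {
    st$ttl_level <- 0L
    st$pulse_raised_index <- NA_integer_
    ev <- ev + 2L
  }

  # -- threshold / detection logic ----------------------------------
  if (!is.na(d)) {
    if (is.na(st$thr)) {
      # first processed tick: seed the threshold from the signal
      st$thr <- max(abs(d), 1e-9)
    } else if (d > st$thr &&
               (is.na(st$last_index) ||
                (k - st$last_index) >= cc$refr_ticks)) {
      if (!is.na(st$last_index)) {
        period <- (k - st$last_index) * cc$tick
        if (!is.null(cc$min_period)) period <- max(period, cc$min_period)
        if (!is.null(cc$max_period)) period <- min(period, cc$max_period)
        st$period <- period
        st$hr <- 60 / period
      }
      st$last_index <- k
      st$thr <- d
      st$detections_seen <- st$detections_seen + 1L
      ev <- ev + 4L
      if (st$detections_seen >= 2L) {
        if (cc$dtmp >= st$period - 1e-12) {
          st$pending <- c(st$pending, k + 1)
          if (!st$clamp_warned) {
            st$clamp_warned <- TRUE
            warning("dt_mp >= period estimate Tj; trigger clamped to the next tick",
                    call. = FALSE)
          }
        } else {
          st$pending <- c(st$pending,
                          floor(k + (st$period - cc$dtmp) / cc$tick + 1e-9) + 1)
        }
      }
    } else {
      # decay, also while a crossing is suppressed by the refractory
      st$thr <- if (cc$exp_law) st$thr * exp(-st$thr * cc$x)
                else st$thr * cc$one_minus_x
    }
  }

  st$ev <- ev
  st
}

#' Finite-difference derivative estimate
#'
#' The un-normalized two-sample difference `ecg(t + tick) - ecg(t)` used
#' as the derivative estimate (deliberately not divided by the tick: the
#' threshold lives in the same difference units).
#'
#' @param ecg a [uniform_signal]; resampled onto the tick grid if needed.
#' @param t evaluation time in seconds, on the tick grid.
#' @param cfg a [detector_config].
#' @return the amplitude difference at `t`.
#' @export
finite_difference <- function(ecg, t, cfg = detector_config()) {
  g <- resample_to_grid(ecg, cfg$tick)
  k <- round((t - g$start_time) / cfg$tick)
  if (abs(g$start_time + k * cfg$tick - t) > cfg$tick * 1e-6)
    stop_input("t = ", t, " is not on the tick grid")
  if (k < 0 || k > length(g$samples) - 2L)
    stop_input("t = ", t, " (or t + tick) is outside the signal span")
  g$samples[k + 2L] - g$samples[k + 1L]
}

#' One threshold decay step
#'
#' `first_order`: `thr * (1 - x)`.  `true_exponential`:
#' `thr * exp(-thr * x)`, with the exponent depending on the threshold
#' itself, implemented exactly as stated in its source.
#'
#' @param thr current threshold, > 0.
#' @param cfg a [detector_config] supplying `decay_rate` and `decay_law`.
#' @return the decayed threshold (still > 0).
#' @export
decay_threshold <- function(thr, cfg = detector_config()) {
  if (!is.finite(thr) || thr <= 0)
    stop_input("threshold state corrupted: thr must be > 0")
  if (identical(cfg$decay_law, "true_exponential"))
    thr * exp(-thr * cfg$decay_rate)
  else
    thr * (1 - cfg$decay_rate)
}

#' Heart-rate update from two consecutive detections
#'
#' @param ti time of the current detection, seconds.
#' @param ti_prev time of the previous detection, seconds (`< ti`).
#' @return list with `period` (Tj = ti - ti_prev, seconds) and `hr`
#'   (60 / Tj, beats/min).
#' @export
update_heart_rate <- function(ti, ti_prev) {
  if (!(ti > ti_prev))
    stop_input("detection times must be strictly increasing")
  period <- ti - ti_prev
  list(period = period, hr = 60 / period)
}

#' Trigger scheduling
#'
#' The earliest tick-grid time strictly later than `ti + (Tj - dt_mp)`:
#' the rising edge aimed `dt_mp` seconds ahead of the next predicted
#' derivative maximum.  If `dt_mp >= Tj` the request cannot be honored
#' and the trigger is clamped to the next tick after `ti` (with a
#' warning).
#'
#' @param ti time of the current detection, seconds.
#' @param tj current period estimate Tj, seconds.
#' @param cfg a [detector_config].
#' @param origin grid origin in seconds (the trace start time).
#' @return the scheduled rising-edge time in seconds.
#' @export
schedule_trigger <- function(ti, tj, cfg = detector_config(), origin = 0) {
  if (!is.finite(tj) || tj <= 0)
    stop_input("a period estimate Tj is required (two detections)")
  if (cfg$dt_mp >= tj - 1e-12) {
    warning("dt_mp >= period estimate Tj; trigger clamped to the next tick",
            call. = FALSE)
    k <- grid_index_after(ti, origin, cfg$tick)
  } else {
    k <- grid_index_after(ti + (tj - cfg$dt_mp), origin, cfg$tick)
  }
  origin + k * cfg$tick
}

#' Advance the detector by one tick
#'
#' Executes exactly one tick of the streaming state machine at time `t`:
#' TTL raise/lower handling followed by the threshold compare /
#' detect-or-decay step.  Intended for callers driving the detector
#' sample by sample; [run_streaming()] folds this over a whole trace.
#'
#' @param state a [detector_state].
#' @param ecg a [uniform_signal] already on the tick grid
#'   (`sample_interval == cfg$tick`).
#' @param t current time in seconds; must lie on the tick grid.
#' @param cfg a [detector_config].
#' @return list with `state` (updated), `ttl_level` (0/1 after the tick)
#'   and `events` (character vector among `"detection"`, `"ttl_rising"`,
#'   `"ttl_falling"`).
#' @export
detector_step <- function(state, ecg, t, cfg = detector_config()) {
  if (abs(ecg$sample_interval - cfg$tick) > 1e-12)
    stop_input("ecg must be on the tick grid; use resample_to_grid()")
  k <- round((t - ecg$start_time) / cfg$tick)
  if (abs(ecg$start_time + k * cfg$tick - t) > cfg$tick * 1e-6)
    stop_input("t = ", t, " is not aligned to the tick grid")
  if (k < 0 || k > length(ecg$samples) - 1L)
    stop_input("t = ", t, " is outside the signal span")
  d <- if (k <= length(ecg$samples) - 2L)
    ecg$samples[k + 2L] - ecg$samples[k + 1L] else NA_real_
  st <- advance_tick(state, d, k, tick_constants(cfg))
  ev <- st$ev
  events <- c(if (bitwAnd(ev, 4L)) "detection",
              if (bitwAnd(ev, 1L)) "ttl_rising",
              if (bitwAnd(ev, 2L)) "ttl_falling")
  list(state = st, ttl_level = st$ttl_level, events = events %||% character(0))
}

new_detector_run <- function(ttl, det_t, rise_t, fall_t, hr, cfg, engine,
                             clamped) {
  structure(
    list(ttl = ttl,
         detections = event_series(det_t, "r_detection"),
         rising = event_series(rise_t, "ttl_rising"),
         falling = event_series(fall_t, "ttl_falling"),
         hr = hr, config = cfg, engine = engine, clamped = clamped),
    class = "detector_run"
  )
}

#' @export
print.detector_run <- function(x, ...) {
  cat(sprintf(
    "<detector_run [%s]: %d detections, %d rising edges over %.4g s%s>\n",
    x$engine, length(x$detections), length(x$rising),
    signal_end(x$ttl) - x$ttl$start_time,
    if (x$clamped) ", dt_mp clamped" else ""))
  if (nrow(x$hr))
    cat(sprintf("  last HR estimate: %.2f bpm\n",
                x$hr$hr[nrow(x$hr)]))
  invisible(x)
}

#' Run the streaming detector over a whole trace
#'
#' Resamples the ECG onto the tick grid and folds the one-tick state
#' machine over it.  The threshold is initialized from the first tick's
#' difference magnitude; trigger output is suppressed until two
#' detections establish a period estimate.
#'
#' @param ecg a [uniform_signal] at any sample rate.
#' @param cfg a [detector_config].
#' @return an object of class `detector_run`: the dense TTL signal on
#'   the tick grid (`ttl`), `detections`, `rising` and `falling` edge
#'   [event_series], and `hr`, a data.frame of (time, hr) updates.
#' @seealso [run_batch()] for the whole-array reference implementation.
#' @export
run_streaming <- function(ecg, cfg = detector_config()) {
  g <- resample_to_grid(ecg, cfg$tick)
  n <- length(g$samples)
  if (n < 3L) stop_input("signal shorter than 2 ticks")
  d <- diff(g$samples)
  cc <- tick_constants(cfg)
  st <- detector_state()

  ttl <- integer(n)
  det_k <- integer(0); rise_k <- integer(0); fall_k <- integer(0)
  hr_k <- integer(0); hr_v <- numeric(0)
  clamped <- FALSE

  withCallingHandlers(
    for (k in 0:(n - 1L)) {
      st <- advance_tick(st, if (k <= n - 2L) d[k + 1L] else NA_real_, k, cc)
      ttl[k + 1L] <- st$ttl_level
      ev <- st$ev
      if (ev) {
        if (bitwAnd(ev, 1L)) rise_k <- c(rise_k, k)
        if (bitwAnd(ev, 2L)) fall_k <- c(fall_k, k)
        if (bitwAnd(ev, 4L)) {
          det_k <- c(det_k, k)
          if (st$detections_seen >= 2L) {
            hr_k <- c(hr_k, k)
            hr_v <- c(hr_v, st$hr)
          }
        }
      }
    },
    warning = function(w) {
      if (grepl("clamped", conditionMessage(w))) clamped <<- TRUE
    })

  to_t <- function(k) g$start_time + k * cfg$tick
  new_detector_run(
    ttl = uniform_signal(ttl, cfg$tick, g$start_time, ttl = TRUE),
    det_t = to_t(det_k), rise_t = to_t(rise_k), fall_t = to_t(fall_k),
    hr = data.frame(time = to_t(hr_k), hr = hr_v),
    cfg = cfg, engine = "streaming", clamped = clamped)
}
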