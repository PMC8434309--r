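#' Whole-array batch reference detector
#'
#' Non-streaming reference implementation of the same conversion: the
#' difference array is computed up front, detections are found by
#' jumping from one threshold crossing to the next with the inter-beat
#' decay expressed in closed form (`thr * (1 - x)^j` under the
#' first-order law), trigger times are scheduled from the detection
#' list, and the TTL trace is painted as intervals.  It must agree
#' sample-for-sample with [run_streaming()]; the pair serves as a
#' mutual cross-check.
#'
#' @inheritParams run_streaming
#' @return an object of class `detector_run` (see [run_streaming()]).
#' @export
run_batch <- function(ecg, cfg = detector_config()) {
  g <- resample_to_grid(ecg, cfg$tick)
  n <- length(g$samples)
  if (n < 3L) stop_input("signal shorter than 2 ticks")
  d <- diff(g$samples)              # d[k + 1] belongs to 0-based tick k
  cc <- tick_constants(cfg)
  n_diff <- n - 1L                  # ticks 0 .. n-2 carry a difference

  # ---- detection scan -------------------------------------------------
  # Threshold at comparison tick k, with base value thr_b taken at tick
  # k_b (a detection or the initialization tick), is
  # thr_b * (1 - x)^(k - k_b - 1): one decay per elapsed non-detection
  # tick.  Refractory suppression never interrupts the decay.
  det <- integer(0)
  thr_b <- max(abs(d[1L]), 1e-9)    # initialization at tick 0
  k_b <- 0L
  last <- NA_integer_
  if (!cc$exp_law) {
    pow <- (1 - cc$x)^(0:(n_diff))  # pow[j + 1] = (1 - x)^j
    repeat {
      ks <- (k_b + 1L):(n_diff - 1L)
      if (ks[1L] > n_diff - 1L) break
      ok <- d[ks + 1L] > thr_b * pow[ks - k_b]
      if (!is.na(last)) ok <- ok & (ks - last >= cc$refr_ticks)
      hit <- which(ok)
      if (!length(hit)) break
      k <- ks[hit[1L]]
      det <- c(det, k)
      last <- k
      thr_b <- d[k + 1L]
      k_b <- k
      if (k_b + 1L > n_diff - 1L) break
    }
  } else {
    # no closed form for the state-dependent exponential decay: jump
    # per detection with an explicit decay loop in between
    thr <- thr_b
    k <- 1L
    while (k <= n_diff - 1L) {
      dk <- d[k + 1L]
      if (dk > thr &&
          (is.na(last) || (k - last) >= cc$refr_ticks)) {
        det <- c(det, k)
        last <- k
        thr <- dk
      } else {
        thr <- thr * exp(-thr * cc$x)
      }
      k <- k + 1L
    }
  }

  # ---- period estimates and trigger schedule --------------------------
  clamped <- FALSE
  sched <- numeric(0)
  periods <- numeric(0)
  if (length(det) >= 2L) {
    gaps <- diff(det) * cc$tick
    if (!is.null(cc$min_period)) gaps <- pmax(gaps, cc$min_period)
    if (!is.null(cc$max_period)) gaps <- pmin(gaps, cc$max_period)
    periods <- gaps                  # Tj at detection j+1 (1-based)
    kj <- det[-1L]
    clamp <- cc$dtmp >= periods - 1e-12
    s <- numeric(length(kj))
    s[clamp] <- kj[clamp] + 1
    s[!clamp] <- floor(kj[!clamp] +
                       (periods[!clamp] - cc$dtmp) / cc$tick + 1e-9) + 1
    if (any(clamp)) {
      clamped <- TRUE
      warning("dt_mp >= period estimate Tj; trigger clamped to the next tick",
              call. = FALSE)
    }
    sched <- sort(s)
  }

  # ---- TTL painting ----------------------------------------------------
  # A schedule due at tick s raises the line if it is low; while high
  # (ticks r .. r + pw_ticks, the last being the lowering tick) any due
  # schedule is swallowed.
  rises <- integer(0)
  for (s in sched) {
    if (s > n - 1L) next                      # beyond the trace
    if (length(rises) && s <= rises[length(rises)] + cc$pw_ticks) next
    rises <- c(rises, as.integer(s))
  }
  falls <- rises + cc$pw_ticks
  falls <- falls[falls <= n - 1L]

  ttl <- integer(n)
  for (i in seq_along(rises)) {
    hi_end <- min(rises[i] + cc$pw_ticks - 1L, n - 1L)
    ttl[(rises[i]:hi_end) + 1L] <- 1L
  }

  to_t <- function(k) g$start_time + k * cfg$tick
  hr_det <- if (length(det) >= 2L) det[-1L] else integer(0)
  new_detector_run(
    ttl = uniform_signal(ttl, cfg$tick, g$start_time, ttl = TRUE),
    det_t = to_t(det), rise_t = to_t(rises), fall_t = to_t(falls),
    hr = data.frame(time = to_t(hr_det),
                    hr = if (length(periods)) 60 / periods else numeric(0)),
    cfg = cfg, engine = "batch", clamped = clamped)
}
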