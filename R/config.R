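#' Detector configuration
#'
#' All constants of the ECG-to-TTL conversion algorithm.  Defaults are the
#' device settings: 5-ms loop tick, threshold decay rate x = 0.14% per
#' tick, 20-ms refractory period, 25-ms TTL pulse, and no trigger phase
#' offset (dtMP = 0).
#'
#' @param tick detector loop interval in seconds (the finite-difference
#'   spacing and the grid on which everything is evaluated).
#' @param decay_rate per-tick threshold decay rate x, 0 < x < 1.
#' @param refractory minimum time after a detection before a new one is
#'   accepted, seconds; a candidate exactly at the boundary is rejected.
#' @param pulse_width minimum TTL high time in seconds; the pulse is
#'   lowered at the first tick at which it has been high at least this
#'   long.
#' @param dt_mp trigger phase offset dtMP in seconds: the trigger is
#'   emitted this long before the next predicted R-derivative maximum
#'   (instrument-delay compensation / phase selection).
#' @param decay_law `"first_order"` applies `thr * (1 - x)` per tick;
#'   `"true_exponential"` applies `thr * exp(-thr * x)` (an alternative
#'   decay discussed as a possible refinement; implemented exactly as
#'   stated, with the exponent depending on thr).
#' @param warmup_policy only `"suppress_until_two_detections"`: no TTL
#'   pulse is emitted before two detections have established a beat
#'   period.
#' @param min_hr,max_hr optional plausibility clamp on the heart-rate
#'   estimate in beats/min; `NULL` (default) disables the clamp, matching
#'   the device, which applies none.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(tick = 0.005, decay_rate = 0.0014,
                            refractory = 0.020, pulse_width = 0.025,
                            dt_mp = 0,
                            decay_law = c("first_order", "true_exponential"),
                            warmup_policy = "suppress_until_two_detections",
                            min_hr = NULL, max_hr = NULL) {
  decay_law <- match.arg(decay_law)
  warmup_policy <- match.arg(warmup_policy)
  if (!is.finite(tick) || tick <= 0) stop_input("tick must be > 0")
  if (!is.finite(decay_rate) || decay_rate <= 0 || decay_rate >= 1)
    stop_input("decay_rate must satisfy 0 < x < 1")
  for (nm in c("refractory", "pulse_width", "dt_mp")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0) stop_input(nm, " must be >= 0")
  }
  if (!is.null(min_hr) && !is.null(max_hr) && min_hr >= max_hr)
    stop_input("min_hr must be < max_hr")
  structure(
    list(tick = tick, decay_rate = decay_rate, refractory = refractory,
         pulse_width = pulse_width, dt_mp = dt_mp, decay_law = decay_law,
         warmup_policy = warmup_policy, min_hr = min_hr, max_hr = max_hr),
    class = "detector_config"
  )
}

#' @export
print.detector_config <- function(x, ...) {
  cat("<detector_config>\n")
  cat(sprintf("  tick        %.4g s\n", x$tick))
  cat(sprintf("  decay_rate  %.4g per tick (%s)\n", x$decay_rate,
              x$decay_law))
  cat(sprintf("  refractory  %.4g s\n", x$refractory))
  cat(sprintf("  pulse_width %.4g s\n", x$pulse_width))
  cat(sprintf("  dt_mp       %.4g s\n", x$dt_mp))
  if (!is.null(x$min_hr) || !is.null(x$max_hr))
    cat(sprintf("  hr clamp    [%s, %s] bpm\n",
                x$min_hr %||% "-", x$max_hr %||% "-"))
  invisible(x)
}
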