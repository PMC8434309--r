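#' Evaluate a detector run against ground truth
#'
#' Produces one performance row per trace: number of evaluated cycles,
#' FP/FN/total error percentages, and the mean and sample standard
#' deviation of the trigger timing offset against the ex-post ideal
#' trigger train (matched beats only; FP and FN excluded).  The first
#' two beats are excluded from the cycle count and from FN counting:
#' they fall inside the detector warm-up, during which no trigger can
#' exist.
#'
#' @param run a `detector_run` (from [run_streaming()] or [run_batch()]).
#' @param r_truth ground-truth R-peak times (numeric or [event_series]).
#' @param ecg the ECG trace the run was computed from; used to derive
#'   the derivative-maximum reference for the ideal train.  If `NULL`,
#'   the ground-truth times serve as reference (flagged in the report).
#' @param window matching half-window in seconds; default
#'   `min(0.150, 0.4 * median RR)`, wider than the expected trigger
#'   advance but too narrow to absorb a mid-cycle false positive.
#' @param trace_id label for the report row.
#' @return an object of class `evaluation_report`.
#' @export
evaluate_run <- function(run, r_truth, ecg = NULL, window = NULL,
                         trace_id = "trace") {
  truth <- event_times(r_truth)
  if (length(truth) < 3L)
    stop_input("at least 3 annotated beats are required (2 are warm-up)")
  if (is.null(window))
    window <- min(0.150, 0.4 * stats::median(diff(truth)))

  cfg <- run$config
  reference_kind <- if (is.null(ecg)) "truth" else "derivative_max"
  refs <- if (is.null(ecg)) truth
          else derivative_max_times(ecg, truth, cfg)
  ideal <- ideal_ttl(refs, cfg)

  # Warm-up cycles carry no valid trigger by construction; both the
  # beats and any edges falling inside them are outside the evaluated
  # error surface.
  eval_truth <- truth[-(1:2)]
  n_cycles <- length(eval_truth)
  # The evaluated span is bounded on both sides: a trailing trigger
  # aimed at the first beat after the annotation span belongs to an
  # unobserved cycle and cannot be classified either way.
  eval_start <- eval_truth[1L] - window
  eval_end <- eval_truth[n_cycles] + window
  edges <- event_times(run$rising)
  m <- match_edges(edges[edges >= eval_start & edges <= eval_end],
                   eval_truth, ttl = run$ttl, window = window)
  rates <- error_rates(m, n_cycles)

  dt_mean <- NA_real_; dt_std <- NA_real_; n_dt <- 0L
  if (nrow(m$matched) >= 2L && length(ideal) >= 2L) {
    ts <- timing_stats(m, ideal, window = window)
    dt_mean <- ts$dt_mean_ms; dt_std <- ts$dt_std_ms; n_dt <- ts$n
  }

  structure(
    list(trace_id = trace_id, n_cycles = n_cycles,
         fp_pct = rates$fp_pct, fn_pct = rates$fn_pct,
         error_pct = rates$error_pct,
         dt_mean_ms = dt_mean, dt_std_ms = dt_std, n_dt = n_dt,
         reference = reference_kind, window = window,
         match = m, ideal = ideal),
    class = "evaluation_report"
  )
}

#' @rdname evaluate_run
#' @param cfg a [detector_config] used to run the detector.
#' @param engine `"streaming"` or `"batch"`.
#' @export
evaluate_trace <- function(ecg, r_truth, cfg = detector_config(),
                           window = NULL, trace_id = "trace",
                           engine = c("streaming", "batch")) {
  engine <- match.arg(engine)
  run <- if (engine == "batch") run_batch(ecg, cfg) else run_streaming(ecg, cfg)
  evaluate_run(run, r_truth, ecg = ecg, window = window,
               trace_id = trace_id)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Trace %s: %d cycles\n", x$trace_id, x$n_cycles))
  cat(sprintf("  FP %.2f%%  FN %.2f%%  error %.2f%%\n",
              x$fp_pct, x$fn_pct, x$error_pct))
  if (!is.na(x$dt_mean_ms))
    cat(sprintf("  dt (ideal - actual): %.2f +/- %.2f ms over %d beats\n",
                x$dt_mean_ms, x$dt_std_ms, x$n_dt))
  else
    cat("  dt: not enough matched beats\n")
  cat(sprintf("  reference: %s, matching window %.0f ms\n",
              x$reference, 1000 * x$window))
  invisible(x)
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(trace_id = x$trace_id, n_cycles = x$n_cycles,
             fp_pct = x$fp_pct, fn_pct = x$fn_pct,
             error_pct = x$error_pct, dt_mean_ms = x$dt_mean_ms,
             dt_std_ms = x$dt_std_ms, reference = x$reference,
             stringsAsFactors = FALSE)
}

#' Overlay plot of ECG, actual TTL and ideal TTL
#'
#' @param ecg a [uniform_signal].
#' @param run a `detector_run`.
#' @param ideal optional ideal rising-edge [event_series]; drawn as a
#'   dashed pulse train when given.
#' @param file optional path; when given the plot is written as a PNG.
#' @param xlim optional time range in seconds.
#' @return invisibly `NULL`.
#' @export
plot_overlay <- function(ecg, run, ideal = NULL, file = NULL, xlim = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 500)
    on.exit(grDevices::dev.off())
  }
  t <- signal_times(ecg)
  if (is.null(xlim)) xlim <- range(t)
  amp <- max(abs(ecg$samples))
  plot(t, ecg$samples, type = "l", col = "blue", xlab = "time (s)",
       ylab = "amplitude (arb.)", xlim = xlim,
       ylim = c(-1.6 * amp, 1.2 * amp))
  tt <- signal_times(run$ttl)
  graphics::lines(tt, run$ttl$samples * 0.4 * amp - 1.5 * amp, col = "red")
  if (!is.null(ideal)) {
    pw <- run$config$pulse_width
    for (e in event_times(ideal)) {
      graphics::lines(c(e, e, e + pw, e + pw),
                      c(-1.5, -1.1, -1.1, -1.5) * amp,
                      col = "black", lty = 2)
    }
  }
  graphics::legend("topright",
                   legend = c("ECG", "TTL", if (!is.null(ideal)) "ideal TTL"),
                   col = c("blue", "red", if (!is.null(ideal)) "black"),
                   lty = c(1, 1, if (!is.null(ideal)) 2), bty = "n")
  invisible(NULL)
}
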