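#' Uniformly sampled scalar time series
#'
#' The basic container for both the analog ECG trace and the binary TTL
#' output: a start time, a fixed sample interval and a vector of samples.
#' Sample `k` (0-based) is taken at `start_time + k * sample_interval`.
#'
#' @param samples numeric vector of amplitudes (arbitrary units) or, for a
#'   TTL signal, logic levels 0/1.
#' @param sample_interval sampling interval in seconds (> 0).
#' @param start_time time of the first sample in seconds.
#' @param ttl logical; if `TRUE` the samples are validated as logic levels.
#' @return an object of class `uniform_signal`.
#' @export
uniform_signal <- function(samples, sample_interval, start_time = 0,
                           ttl = FALSE) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop_input("a uniform_signal needs at least 2 samples")
  if (!is.finite(sample_interval) || sample_interval <= 0)
    stop_input("sample_interval must be > 0")
  if (anyNA(samples))
    stop_input("samples contain NA")
  if (ttl && !all(samples %in% c(0, 1)))
    stop_input("a TTL signal may contain only levels 0 and 1")
  structure(
    list(samples = samples, sample_interval = sample_interval,
         start_time = start_time, ttl = isTRUE(ttl)),
    class = "uniform_signal"
  )
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf(
    "<uniform_signal%s: %d samples @ %.6g s (%.4g Hz), span [%.6g, %.6g] s>\n",
    if (x$ttl) " (TTL)" else "", length(x$samples), x$sample_interval,
    1 / x$sample_interval, x$start_time, signal_end(x)))
  invisible(x)
}

#' Sample times of a uniform signal
#' @param sig a [uniform_signal].
#' @return numeric vector of sample times in seconds.
#' @export
signal_times <- function(sig) {
  sig$start_time + (seq_along(sig$samples) - 1) * sig$sample_interval
}

#' @rdname signal_times
#' @export
signal_end <- function(sig) {
  sig$start_time + (length(sig$samples) - 1) * sig$sample_interval
}

#' Linear interpolation of a signal onto a fixed tick grid
#'
#' Input traces may arrive at an arbitrary monitor sample rate; the
#' detector runs on its own loop interval (the tick), so traces are
#' linearly interpolated onto the tick grid anchored at the trace start.
#' A signal already on the requested grid is returned unchanged.
#'
#' @param sig a [uniform_signal].
#' @param tick target sample interval in seconds.
#' @return a [uniform_signal] with `sample_interval == tick`.
#' @export
resample_to_grid <- function(sig, tick) {
  if (!is.finite(tick) || tick <= 0) stop_input("tick must be > 0")
  if (abs(sig$sample_interval - tick) < 1e-12) return(sig)
  n_out <- floor((signal_end(sig) - sig$start_time) / tick + 1e-9) + 1
  if (n_out < 2L)
    stop_input("signal too short for the requested tick grid")
  grid <- sig$start_time + (0:(n_out - 1)) * tick
  y <- stats::approx(signal_times(sig), sig$samples, xout = grid,
                     rule = 2)$y
  uniform_signal(y, tick, sig$start_time, ttl = sig$ttl)
}

# Logic level of a TTL signal at an arbitrary time (nearest sample,
# sample-and-hold semantics on the grid).
ttl_level_at <- function(ttl, t) {
  k <- round((t - ttl$start_time) / ttl$sample_interval)
  k <- pmin(pmax(k, 0), length(ttl$samples) - 1)
  ttl$samples[k + 1]
}

# Rising / falling edge times of a dense TTL signal: time of the first
# sample at the new level.
ttl_edges <- function(ttl) {
  lv <- ttl$samples
  d <- diff(lv)
  t <- signal_times(ttl)
  list(rising = t[which(d == 1) + 1], falling = t[which(d == -1) + 1])
}
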