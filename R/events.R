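#' Annotated time points of one kind
#'
#' Carries strictly increasing event times of a single kind: ground-truth
#' R-peaks, detector detections, or TTL edge times.
#'
#' @param times numeric vector of event times in seconds, strictly
#'   increasing.
#' @param kind one of `"r_wave_truth"`, `"r_detection"`, `"ttl_rising"`,
#'   `"ttl_falling"`.
#' @return an object of class `event_series`.
#' @export
event_series <- function(times, kind = c("r_wave_truth", "r_detection",
                                         "ttl_rising", "ttl_falling")) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  if (anyNA(times)) stop_input("event times contain NA")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_input("event times must be strictly increasing")
  structure(list(times = times, kind = kind), class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series '%s': %d events", x$kind, length(x$times)))
  if (length(x$times))
    cat(sprintf(" in [%.4g, %.4g] s", min(x$times), max(x$times)))
  cat(">\n")
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$times)

# Accept either an event_series or a bare numeric vector of times.
event_times <- function(x) {
  if (inherits(x, "event_series")) x$times else as.numeric(x)
}
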