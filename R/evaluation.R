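#' Ex-post ideal trigger train
#'
#' The trigger train the algorithm aims for, computable only with full
#' knowledge of the trace: one rising edge `dt_mp` seconds before each
#' reference time.  The first two references are skipped, mirroring the
#' detector warm-up (the first real trigger is scheduled by the second
#' detection and targets the third derivative maximum).
#'
#' @param reference reference times (numeric or [event_series]):
#'   R-derivative-maximum times computed offline (see
#'   [derivative_max_times()]) or, alternatively, ground-truth R-peak
#'   times.
#' @param cfg a [detector_config] (supplies `dt_mp`).
#' @return an [event_series] of kind `"ttl_rising"` with the ideal edge
#'   times.
#' @export
ideal_ttl <- function(reference, cfg = detector_config()) {
  r <- event_times(reference)
  if (length(r) < 2L) stop_input("at least 2 reference times are required")
  event_series(r[-(1:2)] - cfg$dt_mp, "ttl_rising")
}

#' Offline R-derivative-maximum times
#'
#' For each annotated beat, the tick-grid time at which the finite
#' difference of the trace is largest, searched within `search` seconds
#' of the R annotation (clipped at the midpoints to neighboring beats).
#' These are the natural reference times for [ideal_ttl()]: the
#' detector's threshold crossings chase exactly this maximum.
#'
#' @param ecg a [uniform_signal].
#' @param r_truth R annotations (numeric or [event_series]).
#' @param cfg a [detector_config] (supplies the tick).
#' @param search half-width of the search window, seconds.
#' @return numeric vector of derivative-maximum times, one per beat.
#' @export
derivative_max_times <- function(ecg, r_truth, cfg = detector_config(),
                                 search = 0.08) {
  r <- event_times(r_truth)
  if (!length(r)) return(numeric(0))
  g <- resample_to_grid(ecg, cfg$tick)
  d <- diff(g$samples)
  td <- g$start_time + (seq_along(d) - 1L) * cfg$tick
  lo_bound <- c(-Inf, r[-length(r)] + diff(r) / 2)
  hi_bound <- c(r[-1L] - diff(r) / 2, Inf)
  vapply(seq_along(r), function(j) {
    sel <- which(td >= max(r[j] - search, lo_bound[j]) &
                 td <= min(r[j] + search, hi_bound[j]))
    if (!length(sel))
      stop_input("no tick in the search window around beat at ", r[j], " s")
    td[sel[which.max(d[sel])]]
  }, numeric(1))
}

#' Match trigger edges to annotated beats
#'
#' Greedy nearest-neighbor matching of rising edges to reference beat
#' times within `+/- window`.  Unmatched edges are false positives (a
#' trigger not produced by an R-wave); unmatched beats are false
#' negatives, typed `stuck_high` when the TTL line is high at the beat
#' time (a pulse that failed to return low before the next R-wave) and
#' `missed` otherwise.
#'
#' @param edges rising-edge times (numeric or [event_series]).
#' @param r_truth beat times (numeric or [event_series]).
#' @param ttl optional dense TTL [uniform_signal], used to type false
#'   negatives; without it every false negative is typed `missed`.
#' @param window matching half-window in seconds (> 0).
#' @return an object of class `match_result`: `matched`
#'   (data.frame `truth_time`, `edge_time`), `false_positives` (times),
#'   `false_negatives` (data.frame `time`, `type`), `window`.
#' @export
match_edges <- function(edges, r_truth, ttl = NULL, window = 0.150) {
  if (!is.finite(window) || window <= 0) stop_input("window must be > 0")
  e <- event_times(edges)
  r <- event_times(r_truth)

  m_truth <- integer(0); m_edge <- integer(0)
  if (length(e) && length(r)) {
    dm <- abs(outer(r, e, "-"))
    cand <- which(dm <= window, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dm[cand], cand[, 1L], cand[, 2L])
      cand <- cand[ord, , drop = FALSE]
      used_r <- logical(length(r)); used_e <- logical(length(e))
      for (i in seq_len(nrow(cand))) {
        ri <- cand[i, 1L]; ei <- cand[i, 2L]
        if (!used_r[ri] && !used_e[ei]) {
          used_r[ri] <- TRUE; used_e[ei] <- TRUE
          m_truth <- c(m_truth, ri); m_edge <- c(m_edge, ei)
        }
      }
    }
  }

  ord <- order(m_truth)
  matched <- data.frame(truth_time = r[m_truth][ord],
                        edge_time = e[m_edge][ord])
  fp <- if (length(e)) e[!seq_along(e) %in% m_edge] else numeric(0)
  fn_t <- if (length(r)) r[!seq_along(r) %in% m_truth] else numeric(0)
  fn_type <- if (!length(fn_t)) character(0)
             else if (is.null(ttl)) rep("missed", length(fn_t))
             else ifelse(ttl_level_at(ttl, fn_t) == 1, "stuck_high", "missed")

  structure(
    list(matched = matched, false_positives = fp,
         false_negatives = data.frame(time = fn_t, type = fn_type,
                                      stringsAsFactors = FALSE),
         window = window),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d matched, %d FP, %d FN (%d stuck_high)>\n",
              nrow(x$matched), length(x$false_positives),
              nrow(x$false_negatives),
              sum(x$false_negatives$type == "stuck_high")))
  invisible(x)
}

#' Error rates as percentages of R-waves
#'
#' @param m a `match_result` (see [match_edges()]).
#' @param n_r number of evaluated R-waves (> 0), the denominator of all
#'   three percentages.
#' @return list with `fp_pct`, `fn_pct` and `error_pct`
#'   (`= fp_pct + fn_pct`).
#' @export
error_rates <- function(m, n_r) {
  if (!is.finite(n_r) || n_r <= 0) stop_input("n_r must be > 0")
  fp_pct <- 100 * length(m$false_positives) / n_r
  fn_pct <- 100 * nrow(m$false_negatives) / n_r
  list(fp_pct = fp_pct, fn_pct = fn_pct, error_pct = fp_pct + fn_pct)
}

#' Timing offsets against the ideal trigger train
#'
#' Pairs each actual rising edge with the nearest ideal edge (greedy,
#' within `window`) and reports the offset `dt = ideal - actual` in
#' milliseconds: positive means the actual trigger fired early
#' (advanced).  Error beats must be excluded upstream — pass the
#' matched edges, not the raw edge list, when false positives exist.
#'
#' @param actual actual rising-edge times (numeric, [event_series], or a
#'   `match_result`, whose matched edge times are used).
#' @param ideal ideal rising-edge times (numeric or [event_series]),
#'   e.g. from [ideal_ttl()].
#' @param window pairing half-window in seconds.
#' @return list with `dt_mean_ms`, `dt_std_ms` (sample standard
#'   deviation) and `n` (number of pairs, >= 2 required).
#' @export
timing_stats <- function(actual, ideal, window = 0.5) {
  a <- if (inherits(actual, "match_result")) actual$matched$edge_time
       else event_times(actual)
  i <- event_times(ideal)
  m <- match_edges(a, i, window = window)
  # matched pairs: truth slot holds the ideal time, edge slot the actual
  dt <- (m$matched$truth_time - m$matched$edge_time) * 1000
  if (length(dt) < 2L)
    stop_input("at least 2 matched pairs are required for timing statistics")
  list(dt_mean_ms = mean(dt), dt_std_ms = stats::sd(dt), n = length(dt))
}
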