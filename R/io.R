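#' Read and write delimited-text signal files
#'
#' The exchange format is a two-column CSV with header `time,amplitude`
#' (or `time,level` for TTL), time in seconds.  Lines beginning with `#`
#' carry metadata and are ignored by generic readers.  The time column
#' must be strictly increasing and uniform to within 1e-6 s; violations
#' are reported with the offending line number.
#'
#' @param path file path.
#' @param format `"delimited"` or `"physionet"` (WFDB; see
#'   [read_wfdb()]).
#' @param channel channel index for PhysioNet records.
#' @return a [uniform_signal].
#' @export
read_signal <- function(path, format = c("delimited", "physionet"),
                        channel = 1) {
  format <- match.arg(format)
  if (format == "physionet") return(read_wfdb(path, channel = channel))
  if (!file.exists(path)) stop_input("input file not found: ", path)

  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 3L)
    stop_input(path, ": need a header and at least 2 samples")
  header <- tolower(trimws(strsplit(lines[1L], ",")[[1L]]))
  if (length(header) != 2L || header[1L] != "time" ||
      !header[2L] %in% c("amplitude", "level"))
    stop_input(path, ": line ", lineno[1L],
               ": expected header 'time,amplitude' or 'time,level'")
  is_ttl <- header[2L] == "level"

  body <- lines[-1L]
  body_ln <- lineno[-1L]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop_input(path, ": line ", body_ln[bad[1L]],
               ": expected two comma-separated fields")
  tv <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  av <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(tv))
    stop_input(path, ": line ", body_ln[which(is.na(tv))[1L]],
               ": unparseable time field")
  if (anyNA(av))
    stop_input(path, ": line ", body_ln[which(is.na(av))[1L]],
               ": unparseable amplitude field")

  dt <- diff(tv)
  if (any(dt <= 0))
    stop_input(path, ": line ", body_ln[which(dt <= 0)[1L] + 1L],
               ": time column is not strictly increasing")
  interval <- stats::median(dt)
  off <- which(abs(dt - interval) > 1e-6)
  if (length(off))
    stop_input(path, ": line ", body_ln[off[1L] + 1L],
               ": non-uniform sampling (interval ",
               format(dt[off[1L]], digits = 8), " vs ",
               format(interval, digits = 8), " s); resample first")
  uniform_signal(av, interval, tv[1L], ttl = is_ttl)
}

#' @rdname read_signal
#' @param sig a [uniform_signal] to write.
#' @export
write_signal <- function(sig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  label <- if (sig$ttl) "level" else "amplitude"
  writeLines(paste0("time,", label), con)
  writeLines(sprintf("%.10g,%.10g", signal_times(sig), sig$samples), con)
  invisible(path)
}

#' Read and write TTL traces
#'
#' TTL traces are stored sparsely by default: only the first sample,
#' every level change and the last sample are written, plus a
#' `# sample_interval:` metadata line that makes the encoding lossless
#' on the known tick grid.  `dense = TRUE` writes every tick instead.
#'
#' @param ttl a TTL-valued [uniform_signal].
#' @param path file path.
#' @param dense write one row per tick instead of the sparse encoding.
#' @return `write_ttl`: the path, invisibly.  `read_ttl`: the dense
#'   [uniform_signal], reconstructed from either encoding.
#' @export
write_ttl <- function(ttl, path, dense = FALSE) {
  stopifnot(all(ttl$samples %in% c(0, 1)))
  if (dense) return(write_signal(ttl, path))
  t <- signal_times(ttl)
  n <- length(t)
  keep <- sort(unique(c(1L, which(diff(ttl$samples) != 0) + 1L, n)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_interval: %.10g", ttl$sample_interval), con)
  writeLines("time,level", con)
  writeLines(sprintf("%.10g,%d", t[keep], as.integer(ttl$samples[keep])), con)
  invisible(path)
}

#' @rdname write_ttl
#' @export
read_ttl <- function(path) {
  if (!file.exists(path)) stop_input("input file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#\\s*sample_interval:", lines, value = TRUE)
  if (!length(meta)) {
    sig <- read_signal(path)
    if (!all(sig$samples %in% c(0, 1)))
      stop_input(path, ": levels other than 0/1 in a TTL file")
    sig$ttl <- TRUE
    return(sig)
  }
  interval <- as.numeric(sub("^#\\s*sample_interval:\\s*", "", meta[1L]))
  if (!is.finite(interval) || interval <= 0)
    stop_input(path, ": bad sample_interval metadata")
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  body <- lines[keep][-1L]                      # drop header
  parts <- strsplit(body, ",", fixed = TRUE)
  tv <- as.numeric(vapply(parts, `[[`, "", 1L))
  lv <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(tv) || anyNA(lv) || !all(lv %in% c(0, 1)))
    stop_input(path, ": malformed sparse TTL body")
  n <- round((tv[length(tv)] - tv[1L]) / interval) + 1L
  grid <- tv[1L] + (0:(n - 1L)) * interval
  lev <- lv[findInterval(grid + interval * 1e-6, tv)]
  uniform_signal(lev, interval, tv[1L], ttl = TRUE)
}

#' Read and write event annotation files
#'
#' Annotations are stored as `time,kind` CSV rows (e.g. ground-truth
#' R-peaks as kind `r_wave_truth`).
#'
#' @param ev an [event_series] (or a data.frame with `time` and `kind`
#'   columns, allowing mixed kinds in one file).
#' @param path file path.
#' @param kind when reading a mixed file, the kind to extract.
#' @return `read_events` returns an [event_series].
#' @export
write_events <- function(ev, path) {
  df <- if (inherits(ev, "event_series"))
    data.frame(time = ev$times, kind = ev$kind)
  else ev
  stopifnot(all(c("time", "kind") %in% names(df)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,kind", con)
  if (nrow(df))
    writeLines(sprintf("%.10g,%s", df$time, df$kind), con)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, kind = NULL) {
  if (!file.exists(path)) stop_input("input file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (!all(c("time", "kind") %in% names(df)))
    stop_input(path, ": expected header 'time,kind'")
  kinds <- unique(df$kind)
  if (is.null(kind)) {
    if (length(kinds) > 1L)
      stop_input(path, ": multiple kinds present (",
                 paste(kinds, collapse = ", "), "); pass `kind`")
    kind <- kinds
  }
  event_series(sort(df$time[df$kind == kind]), kind)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` or `key: value` (with `#` comments)
#' naming [detector_config()] arguments: `tick`, `decay_rate`,
#' `refractory`, `pulse_width`, `dt_mp`, `decay_law`, `warmup_policy`,
#' `min_hr`, `max_hr`.
#'
#' @param path file path.
#' @return a [detector_config].
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  numeric_keys <- c("tick", "decay_rate", "refractory", "pulse_width",
                    "dt_mp", "min_hr", "max_hr")
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", perl = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop_input(path, ": unparseable line '", ln, "'")
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (key %in% numeric_keys) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop_input(path, ": non-numeric value for ", key)
      args[[key]] <- num
    } else if (key %in% c("decay_law", "warmup_policy")) {
      args[[key]] <- val
    } else {
      stop_input(path, ": unknown configuration key '", key, "'")
    }
  }
  do.call(detector_config, args)
}

#' @rdname read_config_file
#' @param cfg a [detector_config] to write.
#' @export
write_config_file <- function(cfg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(k) sprintf("%s = %.10g", k, cfg[[k]])
  out <- c(num("tick"), num("decay_rate"), num("refractory"),
           num("pulse_width"), num("dt_mp"),
           sprintf("decay_law = %s", cfg$decay_law),
           sprintf("warmup_policy = %s", cfg$warmup_policy))
  if (!is.null(cfg$min_hr)) out <- c(out, num("min_hr"))
  if (!is.null(cfg$max_hr)) out <- c(out, num("max_hr"))
  writeLines(out, con)
  invisible(path)
}

#' Run manifest
#'
#' Every pipeline stage emits one manifest recording the configuration,
#' input/output paths, seed, package version and per-stage wall times,
#' so a run can be reproduced exactly.
#'
#' @param config a [detector_config] (or `NULL`).
#' @param paths named list of input/output paths.
#' @param seed integer seed, or `NULL` for unseeded stages.
#' @param timings named list of per-stage wall times in seconds.
#' @param extra named list of additional fields to record.
#' @return an object of class `run_manifest`.
#' @export
run_manifest <- function(config = NULL, paths = list(), seed = NULL,
                         timings = list(), extra = list()) {
  m <- c(list(
    software = "ecgsync",
    version = as.character(utils::packageVersion("ecgsync")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    seed = seed,
    config = if (is.null(config)) NULL
             else Filter(Negate(is.null), unclass(config)),
    paths = paths,
    timings = timings), extra)
  structure(m, class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path file path for the JSON document.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path), class = "run_manifest")
}
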