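#' Minimal PhysioNet (WFDB) record reader
#'
#' Reads one channel of a WFDB record: the `.hea` header plus a single
#' signal file in format 16 (16-bit little-endian) or 212 (packed
#' 12-bit pairs), the formats covering the common PhysioNet ECG
#' databases.  Samples are converted to physical units as
#' `(adc - baseline) / gain`.  Multi-segment records, skew/offset
#' modifiers and other storage formats are out of scope.
#'
#' @param record path to the record without extension (the reader
#'   appends `.hea`), or the `.hea` path itself.
#' @param channel 1-based channel index.
#' @return a [uniform_signal] in physical units starting at t = 0.
#' @export
read_wfdb <- function(record, channel = 1) {
  record <- sub("\\.hea$", "", record)
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) stop_input("header not found: ", hea)
  lines <- readLines(hea)
  lines <- trimws(lines[!startsWith(trimws(lines), "#")])
  lines <- lines[nzchar(lines)]

  top <- strsplit(lines[1L], "\\s+")[[1L]]
  if (length(top) < 2L) stop_input(hea, ": malformed record line")
  nsig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(strsplit(top[3L], "/")[[1L]][1L])
        else 250
  nsamp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  if (channel < 1L || channel > nsig)
    stop_input("channel ", channel, " out of range (record has ", nsig, ")")

  sig <- vector("list", nsig)
  for (i in seq_len(nsig)) {
    f <- strsplit(lines[1L + i], "\\s+")[[1L]]
    if (length(f) < 2L) stop_input(hea, ": malformed signal line ", i)
    fmt <- sub("[x:+].*$", "", f[2L])
    gain <- 200; baseline <- NA_real_; adczero <- 0
    if (length(f) >= 3L) {
      gspec <- f[3L]
      b <- regmatches(gspec, regexec("\\(([-0-9]+)\\)", gspec))[[1L]]
      if (length(b) == 2L) baseline <- as.numeric(b[2L])
      g <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gspec)))
      if (is.finite(g) && g != 0) gain <- g
    }
    if (length(f) >= 5L) adczero <- as.numeric(f[5L])
    if (is.na(baseline)) baseline <- adczero
    sig[[i]] <- list(file = f[1L], fmt = fmt, gain = gain,
                     baseline = baseline)
  }
  files <- unique(vapply(sig, `[[`, "", "file"))
  fmts <- unique(vapply(sig, `[[`, "", "fmt"))
  if (length(files) != 1L || length(fmts) != 1L)
    stop_input("only records with one shared signal file/format are supported")
  if (!fmts %in% c("16", "212"))
    stop_input("unsupported WFDB format ", fmts, " (supported: 16, 212)")

  dat <- file.path(dirname(hea), files)
  if (!file.exists(dat)) stop_input("signal file not found: ", dat)
  raw <- readBin(dat, "raw", n = file.info(dat)$size)

  adc <- if (fmts == "16") {
    readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
            endian = "little", signed = TRUE)
  } else {
    # format 212: 3 bytes hold two 12-bit two's-complement samples
    nb <- (length(raw) %/% 3L) * 3L
    b <- as.integer(raw[seq_len(nb)])
    b1 <- b[seq(1L, nb, 3L)]; b2 <- b[seq(2L, nb, 3L)]
    b3 <- b[seq(3L, nb, 3L)]
    s1 <- b1 + bitwShiftL(bitwAnd(b2, 15L), 8L)
    s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8L)
    v <- as.vector(rbind(s1, s2))
    ifelse(v >= 2048L, v - 4096L, v)
  }

  n_frames <- length(adc) %/% nsig
  if (!is.na(nsamp)) n_frames <- min(n_frames, nsamp)
  ch <- adc[seq(channel, n_frames * nsig, by = nsig)]
  phys <- (ch - sig[[channel]]$baseline) / sig[[channel]]$gain
  uniform_signal(phys, 1 / fs, 0)
}
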