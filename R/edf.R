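# Minimal European Data Format (EDF, 16-bit) I/O. EDF stores an ASCII
# header (256 bytes + 256 per signal, signal fields stored field-major)
# followed by data records of little-endian int16 samples; physical values
# are reconstructed by the per-signal linear map declared in the header.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width)
    stop("EDF header field too wide: '", x, "' (max ", width, ")", call. = FALSE)
  formatC(x, width = -width)
}

edf_num <- function(x, width = 8L) {
  s <- sprintf("%.7g", x)
  if (nchar(s) > width) s <- sprintf("%.4g", x)
  edf_pad(s, width)
}

#' Write a recording as a 16-bit EDF file
#'
#' Each channel is scaled to its own symmetric physical range and quantized
#' to 16 bits, so the round-trip error per channel is bounded by
#' `physical_range / 2^15` (half a quantization step is `max|x| / 32767 / 2`).
#' Labels and the sampling rate are preserved exactly. The whole recording is
#' written as a single data record.
#'
#' @param rec an [eeg_recording()]; all samples finite, labels unique.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$samples
  C <- nrow(x); N <- ncol(x)
  if (!all(is.finite(x))) stop("cannot write non-finite samples to EDF", call. = FALSE)
  # one digit string per channel, used verbatim for +max and -min so the
  # declared range is exactly symmetric; rounded up so |x| <= pm always
  fmt_phys <- function(p) {
    for (prec in 6:2) {
      s <- sprintf("%.*g", prec, p)
      if (nchar(s) <= 7L) return(s)
    }
    sprintf("%.1g", p)
  }
  pm_str <- vapply(seq_len(C), function(i) {
    p <- max(abs(x[i, ]))
    if (p == 0) p <- 1
    s <- fmt_phys(p)
    guard <- 0L
    while (as.numeric(s) < p && guard < 60L) {
      p <- p * 1.01
      s <- fmt_phys(p)
      guard <- guard + 1L
    }
    s
  }, character(1))
  pm <- as.numeric(pm_str)
  dur <- N / rec$fs
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open EDF path: ", path, call. = FALSE))
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad("Startdate X X X X", 80))
  wr(edf_pad("01.01.26", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256L * (C + 1L), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(1L, 8))           # one data record
  wr(edf_num(dur, 8))
  wr(edf_pad(C, 4))
  for (lab in rec$channel_labels) wr(edf_pad(lab, 16))
  for (i in seq_len(C)) wr(edf_pad("", 80))          # transducer
  for (i in seq_len(C)) wr(edf_pad("uV", 8))         # physical dimension
  for (i in seq_len(C)) wr(edf_pad(paste0("-", pm_str[i]), 8)) # physical min
  for (i in seq_len(C)) wr(edf_pad(pm_str[i], 8))              # physical max
  for (i in seq_len(C)) wr(edf_pad(-32767L, 8))      # digital min
  for (i in seq_len(C)) wr(edf_pad(32767L, 8))       # digital max
  for (i in seq_len(C)) wr(edf_pad("", 80))          # prefiltering
  for (i in seq_len(C)) wr(edf_pad(N, 8))            # samples per record
  for (i in seq_len(C)) wr(edf_pad("", 32))
  for (i in seq_len(C)) {
    dig <- as.integer(round(x[i, ] / pm[i] * 32767))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file into a recording
#'
#' Supports plain EDF with any number of data records; all signals must share
#' one sampling rate (samples-per-record proportional to record duration).
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0L || nchar(s, type = "bytes") < n)
      stop("corrupt EDF header: ", path, call. = FALSE)
    trimws(s)
  }
  rd(8)                                # version
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  dur <- suppressWarnings(as.numeric(rd(8)))
  C <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(header_bytes, n_rec, dur, C)) || C < 1L || n_rec < 1L || dur <= 0)
    stop("corrupt EDF header: ", path, call. = FALSE)
  if (header_bytes != 256L * (C + 1L))
    stop("corrupt EDF header (size mismatch): ", path, call. = FALSE)
  labels <- vapply(seq_len(C), function(i) rd(16), character(1))
  for (i in seq_len(C)) rd(80)
  for (i in seq_len(C)) rd(8)
  phys_min <- vapply(seq_len(C), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(C), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(C), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(C), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(C)) rd(80)
  spr <- vapply(seq_len(C), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(C)) rd(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr)) || any(spr < 1L))
    stop("corrupt EDF signal header: ", path, call. = FALSE)
  fs <- spr / dur
  if (max(fs) - min(fs) > 1e-9)
    stop("EDF signals with differing sampling rates are not supported", call. = FALSE)
  out <- matrix(0, C, spr[1L] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(C)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L,
                     endian = "little", signed = TRUE)
      if (length(dig) != spr[i]) stop("truncated EDF data: ", path, call. = FALSE)
      gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      out[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (dig - dig_min[i]) * gain + phys_min[i]
    }
  }
  eeg_recording(out, fs[1L], labels)
}
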