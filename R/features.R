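# Spectral features: Welch-averaged one-sided PSD per epoch-channel,
# integrated over the five canonical bands (trapezoidal rule), optionally
# normalized to relative power; plus the frame tokenizer that tiles each
# epoch-channel trace into the fixed-length frames the transformer consumes.

# One-sided Welch PSD (density scaling: integral over frequency ~ variance).
welch_psd <- function(x, fs, seg_len = min(length(x), 256L), overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq.int(0L, seg_len - 1L) / (seg_len - 1L))
  U <- sum(w^2)
  nfreq <- floor(seg_len / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * U)
  # fold negative frequencies into the one-sided estimate
  if (seg_len %% 2L == 0L) psd[2:(nfreq - 1L)] <- 2 * psd[2:(nfreq - 1L)]
  else psd[2:nfreq] <- 2 * psd[2:nfreq]
  list(freq = (seq_len(nfreq) - 1L) * fs / seg_len, psd = psd)
}

trapz_integral <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

# integrate a sampled PSD over [lo, hi], interpolating at the band edges
band_integral <- function(freq, psd, lo, hi) {
  lo <- max(lo, freq[1L]); hi <- min(hi, freq[length(freq)])
  if (hi <= lo) return(0)
  inner <- freq > lo & freq < hi
  xs <- c(lo, freq[inner], hi)
  ys <- stats::approx(freq, psd, xout = xs, rule = 2)$y
  trapz_integral(xs, ys)
}

#' Per-epoch, per-channel canonical band powers
#'
#' Estimates a Welch PSD per epoch-channel trace (Hamming window, segment
#' length `min(L, 256)`, 50% overlap) and integrates it over each band with
#' the trapezoidal rule. With `normalize = TRUE` the five values per
#' (epoch, channel) are divided by their sum (relative power). Note that a
#' 2-s epoch offers limited resolution at the 0.5 Hz delta edge; the
#' estimate is still computed.
#'
#' @param epochs an [eeg_epochs()].
#' @param edges named list of band edges (default [eeg_bands()]); all upper
#'   edges must lie below the Nyquist frequency.
#' @param normalize logical: return relative power per (epoch, channel).
#' @return An object of class `band_power_table`: list with `powers`
#'   (E x C x n_bands array), `band_edges`, `normalization`,
#'   `channel_labels`, `labels`.
#' @export
band_powers <- function(epochs, edges = eeg_bands(), normalize = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$epochs)
  if (d[1L] == 0L) stop("empty epoch set", call. = FALSE)
  hi <- max(vapply(edges, `[`, numeric(1), 2L))
  if (hi >= epochs$fs / 2)
    stop("band edge ", hi, " Hz is at or above Nyquist (", epochs$fs / 2,
         " Hz)", call. = FALSE)
  nb <- length(edges)
  out <- array(0, c(d[1L], d[2L], nb),
               dimnames = list(NULL, NULL, names(edges)))
  for (e in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      tr <- epochs$epochs[e, ch, ]
      if (all(tr == 0)) next
      ps <- welch_psd(tr, epochs$fs)
      for (b in seq_len(nb))
        out[e, ch, b] <- band_integral(ps$freq, ps$psd,
                                       edges[[b]][1L], edges[[b]][2L])
    }
  }
  if (normalize) {
    tot <- apply(out, c(1L, 2L), sum)
    tot[tot == 0] <- 1
    out <- out / as.vector(tot)  # recycles over the band dimension
  }
  structure(list(powers = out, band_edges = edges,
                 normalization = if (normalize) "per-epoch-channel relative" else "none",
                 channel_labels = epochs$channel_labels,
                 labels = epochs$labels),
            class = "band_power_table")
}

#' @export
print.band_power_table <- function(x, ...) {
  d <- dim(x$powers)
  cat(sprintf("<band_power_table> %d epochs x %d channels x %d bands (%s)\n",
              d[1], d[2], d[3], x$normalization))
  invisible(x)
}

#' Export a band-power table as CSV (channel rows, band columns)
#'
#' Writes the epoch-averaged table in the conventional layout: one row per
#' channel, one column per canonical band.
#'
#' @param bp a `band_power_table` from [band_powers()].
#' @param path CSV output path.
#' @return The written data.frame, invisibly.
#' @export
write_band_power_csv <- function(bp, path) {
  stopifnot(inherits(bp, "band_power_table"))
  m <- apply(bp$powers, c(2L, 3L), mean)
  cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  nm <- vapply(names(bp$band_edges), function(b)
    sprintf("%s (%g-%g Hz)", cap(b),
            bp$band_edges[[b]][1], bp$band_edges[[b]][2]), character(1))
  df <- data.frame(`EEG channel` = bp$channel_labels, check.names = FALSE)
  for (b in seq_along(nm)) df[[nm[b]]] <- m[, b]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Tile epochs into fixed-length frames (transformer tokens)
#'
#' Each epoch-channel trace of length L is cut into `n_frames` contiguous
#' frames of `L / n_frames` samples (the epoch length must be divisible).
#' Layout `"raw_frames"` keeps the sample vectors; `"band_frames"` replaces
#' each frame by its 5-band power vector.
#'
#' @param epochs an [eeg_epochs()].
#' @param n_frames frames per epoch (default 16).
#' @param layout `"raw_frames"` or `"band_frames"`.
#' @return An object of class `frame_sequence`: list with `frames`
#'   (E x C x P x F array), `frame_length`, `layout`, `fs`, `labels`.
#' @export
frame_epochs <- function(epochs, n_frames = 16L,
                         layout = c("raw_frames", "band_frames")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  layout <- match.arg(layout)
  d <- dim(epochs$epochs)
  L <- d[3L]
  if (L %% n_frames != 0L)
    stop("epoch length ", L, " is not divisible by n_frames = ", n_frames,
         call. = FALSE)
  fl <- L %/% n_frames
  if (layout == "raw_frames") {
    fr <- array(0, c(d[1L], d[2L], n_frames, fl))
    for (p in seq_len(n_frames))
      fr[, , p, ] <- epochs$epochs[, , ((p - 1L) * fl + 1L):(p * fl)]
  } else {
    bands <- eeg_bands()
    fr <- array(0, c(d[1L], d[2L], n_frames, 5L))
    for (p in seq_len(n_frames)) {
      sub <- eeg_epochs(
        epochs$epochs[, , ((p - 1L) * fl + 1L):(p * fl), drop = FALSE],
        epochs$fs, fl / epochs$fs, channel_labels = epochs$channel_labels)
      bp <- band_powers(sub, bands)
      fr[, , p, ] <- bp$powers
    }
  }
  structure(list(frames = fr, frame_length = fl, layout = layout,
                 fs = epochs$fs, labels = epochs$labels),
            class = "frame_sequence")
}
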