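# Seeded synthetic EEG: class-dependent band-power signatures realized as
# band-limited oscillatory sources mixed across channels, plus eye-blink-like
# low-frequency transients, optional mains sinusoid, and calibrated additive
# Gaussian noise. Ground truth (labels, events, mixing matrix) is returned
# alongside so every downstream stage has an oracle.

#' Canonical EEG frequency bands
#'
#' Delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-50 Hz.
#' @return A named list of `c(low, high)` band edges in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 50))
}

# run code under a temporary RNG state so generators are pure in (spec, seed)
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Specification for the synthetic EEG generator
#'
#' Defaults emulate a 64-channel, 256 Hz acquisition. Classes are defined by
#' relative band-power signatures over the five canonical bands; the default
#' two-class task opposes an alpha-dominant and a theta-dominant signature,
#' the kind of rhythmic contrast (e.g. relaxed-wakeful vs drowsy) that
#' band-power features resolve.
#'
#' @param n_channels channel count (default 64).
#' @param fs sampling rate in Hz (default 256); must exceed twice the highest
#'   band edge carrying weight.
#' @param duration_s seconds per recording.
#' @param n_recordings number of recordings a simulation run produces.
#' @param class_signatures named list: class label -> named numeric vector of
#'   non-negative relative power weights for delta/theta/alpha/beta/gamma.
#' @param artifact_rate expected eye-blink-like transients per minute.
#' @param line_noise_hz mains frequency, 50 or 60 Hz.
#' @param line_noise_amp amplitude of the mains sinusoid relative to the
#'   clean per-channel SD (0 disables line noise).
#' @param noise_sigma_pct additive Gaussian noise SD as a percentage of the
#'   clean per-channel SD.
#' @param epoch_window_s epoch length in seconds used for ground-truth
#'   labels (default 2).
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_channels = 64L, fs = 256, duration_s = 20,
                       n_recordings = 1L,
                       class_signatures = list(
                         alpha = c(delta = 0.15, theta = 0.10, alpha = 1.00,
                                   beta = 0.20, gamma = 0.05),
                         theta = c(delta = 0.15, theta = 1.00, alpha = 0.10,
                                   beta = 0.20, gamma = 0.05)),
                       artifact_rate = 0, line_noise_hz = 50,
                       line_noise_amp = 0, noise_sigma_pct = 0,
                       epoch_window_s = 2, seed = 1L) {
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (n_channels < 1) stop("need at least one channel", call. = FALSE)
  if (noise_sigma_pct < 0) stop("`noise_sigma_pct` must be >= 0", call. = FALSE)
  if (artifact_rate < 0) stop("`artifact_rate` must be >= 0", call. = FALSE)
  bands <- eeg_bands()
  for (cl in names(class_signatures)) {
    w <- class_signatures[[cl]]
    if (is.null(names(w))) names(w) <- names(bands)
    if (!all(names(bands) %in% names(w)))
      stop("class signature '", cl, "' must weight all five bands", call. = FALSE)
    if (any(w < 0))
      stop("band weights must be non-negative (class '", cl, "')", call. = FALSE)
    class_signatures[[cl]] <- w[names(bands)]
  }
  # Nyquist guard against the highest band edge that carries weight
  top <- 0
  for (w in class_signatures)
    for (b in names(bands)) if (w[[b]] > 0) top <- max(top, bands[[b]][2])
  if (fs <= 2 * top)
    stop("fs = ", fs, " Hz is below Nyquist for requested bands (top edge ",
         top, " Hz)", call. = FALSE)
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 duration_s = duration_s, n_recordings = as.integer(n_recordings),
                 class_signatures = class_signatures,
                 artifact_rate = artifact_rate, line_noise_hz = line_noise_hz,
                 line_noise_amp = line_noise_amp,
                 noise_sigma_pct = noise_sigma_pct,
                 epoch_window_s = epoch_window_s, seed = as.integer(seed)),
            class = "synth_spec")
}

# unit-SD band-limited source by frequency-domain synthesis: random complex
# Gaussian amplitudes on the FFT bins inside [lo, hi], zero elsewhere, so
# the source carries (numerically) no power outside its band
band_limited_source <- function(n, fs, edges) {
  freqs <- (0:(n %/% 2L)) * fs / n
  # guard margin keeps source power resolvably inside the band when
  # analysed at ~1 Hz spectral resolution
  guard <- max(0.5, 0.075 * (edges[2L] - edges[1L]))
  lo <- edges[1L] + guard; hi <- edges[2L] - guard
  if (hi <= lo) { lo <- edges[1L]; hi <- edges[2L] }
  keep <- which(freqs >= lo & freqs <= hi)
  keep <- setdiff(keep, 1L)           # never excite DC
  spec <- complex(n)
  if (length(keep) == 0L) {           # band narrower than one bin: pure tone
    f0 <- mean(edges)
    phase <- stats::runif(1L, 0, 2 * pi)
    y <- sin(2 * pi * f0 * (seq_len(n) - 1L) / fs + phase)
    return(y / stats::sd(y))
  }
  spec[keep] <- complex(real = stats::rnorm(length(keep)),
                        imaginary = stats::rnorm(length(keep)))
  # hermitian completion for a real signal
  spec[n - (keep - 2L)] <- Conj(spec[keep])
  y <- Re(stats::fft(spec, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate one synthetic EEG recording with ground truth
#'
#' Builds one band-limited oscillatory source per channel (bands cycled
#' across channels, amplitudes set by the class signature as the square root
#' of the band weight so power is proportional to weight), mixes them with a
#' random full-rank square matrix, then adds eye-blink-like frontal
#' transients at a Poisson rate, an optional mains sinusoid, and additive
#' Gaussian noise calibrated to the clean per-channel SD.
#'
#' @param spec a [synth_spec()].
#' @param class_label one of `names(spec$class_signatures)`.
#' @param seed optional seed overriding `spec$seed` (used when generating
#'   recording collections).
#' @return list with `recording` (an [eeg_recording()]) and `truth`: list of
#'   `class`, `epoch_labels` (one per `epoch_window_s` window), `events`
#'   (data.frame time/channel), `mixing` (the mixing matrix applied to the
#'   sources), `sources` (channels x samples clean source matrix).
#' @export
generate_recording <- function(spec, class_label, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!class_label %in% names(spec$class_signatures))
    stop("unknown class label '", class_label, "'", call. = FALSE)
  w <- spec$class_signatures[[class_label]]
  C <- spec$n_channels
  N <- round(spec$duration_s * spec$fs)
  bands <- eeg_bands()
  with_local_seed(seed, {
    # full-rank mixing matrix (redraw in the measure-zero degenerate case)
    repeat {
      A <- matrix(stats::rnorm(C * C), C, C) / sqrt(C)
      if (rcond(A) > 1e-8) break
    }
    S <- matrix(0, C, N)
    # cycle sources over the bands this class actually weights, so every
    # channel carries signal regardless of channel count
    pos <- which(w > 0)
    if (length(pos) == 0L)
      stop("class signature '", class_label, "' has no positive band weight",
           call. = FALSE)
    band_of <- pos[((seq_len(C) - 1L) %% length(pos)) + 1L]
    for (ch in seq_len(C)) {
      S[ch, ] <- sqrt(w[[band_of[ch]]]) *
        band_limited_source(N, spec$fs, bands[[band_of[ch]]])
    }
    X <- A %*% S
    clean_sd <- pmax(apply(X, 1L, stats::sd), .Machine$double.eps)

    # eye-blink-like transients: Poisson arrivals on frontal channels
    events <- data.frame(time = numeric(0), channel = integer(0))
    if (spec$artifact_rate > 0) {
      n_ev <- stats::rpois(1L, spec$artifact_rate * spec$duration_s / 60)
      if (n_ev > 0) {
        frontal <- seq_len(min(8L, C))
        t_ev <- stats::runif(n_ev, 0, spec$duration_s)
        ch_ev <- sample(frontal, n_ev, replace = TRUE)
        blink_len <- round(0.4 * spec$fs)
        pulse <- sin(pi * seq(0, 1, length.out = blink_len))^2
        for (k in seq_len(n_ev)) {
          i0 <- min(round(t_ev[k] * spec$fs) + 1L, N)
          idx <- i0:min(i0 + blink_len - 1L, N)
          X[ch_ev[k], idx] <- X[ch_ev[k], idx] +
            8 * clean_sd[ch_ev[k]] * pulse[seq_along(idx)]
        }
        events <- data.frame(time = t_ev, channel = ch_ev)
      }
    }

    if (spec$line_noise_amp > 0) {
      tt <- (seq_len(N) - 1L) / spec$fs
      phase <- stats::runif(1L, 0, 2 * pi)
      mains <- sin(2 * pi * spec$line_noise_hz * tt + phase)
      X <- X + outer(spec$line_noise_amp * clean_sd, rep(1, N)) *
        matrix(mains, C, N, byrow = TRUE)
    }

    if (spec$noise_sigma_pct > 0) {
      X <- X + (spec$noise_sigma_pct / 100) * clean_sd *
        matrix(stats::rnorm(C * N), C, N)
    }

    n_win <- floor(spec$duration_s / spec$epoch_window_s)
    list(recording = eeg_recording(X, spec$fs, montage_labels(C)),
         truth = list(class = class_label,
                      epoch_labels = rep(class_label, n_win),
                      events = events, mixing = A, sources = S))
  })
}

# 10-20-flavoured labels for up to 64 channels, generic beyond
montage_labels <- function(C) {
  base <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2",
            "FC6", "T7", "C3", "Cz", "C4", "T8", "CP5", "CP1", "CP2", "CP6",
            "P7", "P3", "Pz", "P4", "P8", "PO3", "PO4", "O1", "Oz", "O2",
            "AF3", "AF4", "F5", "F1", "F2", "F6", "FC3", "FCz", "FC4", "C5",
            "C1", "C2", "C6", "CP3", "CPz", "CP4", "P5", "P1", "P2", "P6",
            "PO7", "POz", "PO8", "FT7", "FT8", "TP7", "TP8", "PO5", "PO6",
            "AF7", "AF8", "F9", "F10", "Iz")
  if (C <= length(base)) base[seq_len(C)]
  else c(base, paste0("EX", seq_len(C - length(base))))
}

#' Add calibrated Gaussian noise to a recording or epoch set
#'
#' "X% noise" means zero-mean Gaussian noise whose per-channel standard
#' deviation equals `pct/100` times that channel's clean standard deviation
#' (for epoch sets, the SD of each epoch-channel trace).
#'
#' @param x an [eeg_recording()] or [eeg_epochs()].
#' @param pct noise level in percent (>= 0); 0 returns the input unchanged.
#' @param seed integer RNG seed.
#' @return Object of the same class as `x` with noise added.
#' @export
add_gaussian_noise <- function(x, pct, seed = 1L) {
  if (pct < 0) stop("noise percentage must be >= 0", call. = FALSE)
  UseMethod("add_gaussian_noise")
}

#' @export
add_gaussian_noise.eeg_recording <- function(x, pct, seed = 1L) {
  if (pct == 0) return(x)
  C <- nrow(x$samples); N <- ncol(x$samples)
  with_local_seed(seed, {
    sds <- apply(x$samples, 1L, stats::sd)
    x$samples <- x$samples + (pct / 100) * sds * matrix(stats::rnorm(C * N), C, N)
    x
  })
}

#' @export
add_gaussian_noise.eeg_epochs <- function(x, pct, seed = 1L) {
  if (pct == 0) return(x)
  d <- dim(x$epochs)
  with_local_seed(seed, {
    for (e in seq_len(d[1L])) {
      tr <- x$epochs[e, , , drop = TRUE]
      if (is.null(dim(tr))) tr <- matrix(tr, 1L)
      sds <- apply(tr, 1L, stats::sd)
      x$epochs[e, , ] <- tr + (pct / 100) * sds *
        matrix(stats::rnorm(d[2L] * d[3L]), d[2L], d[3L])
    }
    x
  })
}

#' Generate a labelled synthetic epoch classification task
#'
#' Produces a balanced, labelled [eeg_epochs()] set by generating whole
#' recordings per class (each cut into `epoch_window_s` windows) with
#' deterministic per-recording seeds derived from `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @param epochs_per_class number of epochs per class label.
#' @param classes class labels to include (default: all in the spec).
#' @param epochs_per_recording windows generated per recording (sets the
#'   recording duration).
#' @return An [eeg_epochs()] with labels, plus attribute `"truths"` holding
#'   per-recording ground truth.
#' @export
synthetic_task <- function(spec, epochs_per_class = 100L,
                           classes = names(spec$class_signatures),
                           epochs_per_recording = 10L) {
  stopifnot(inherits(spec, "synth_spec"), length(classes) >= 1L)
  win <- spec$epoch_window_s
  spec$duration_s <- epochs_per_recording * win
  L <- round(win * spec$fs)
  all_ep <- list(); all_lab <- character(0); truths <- list()
  k <- 0L
  for (ci in seq_along(classes)) {
    got <- 0L; ri <- 0L
    while (got < epochs_per_class) {
      ri <- ri + 1L
      gr <- generate_recording(spec, classes[ci],
                               seed = (spec$seed + 7919L * ci + ri) %% 2147483647)
      ep <- segment_epochs(gr$recording, window_s = win)
      take <- min(n_epochs(ep), epochs_per_class - got)
      k <- k + 1L
      all_ep[[k]] <- ep$epochs[seq_len(take), , , drop = FALSE]
      all_lab <- c(all_lab, rep(classes[ci], take))
      truths[[k]] <- gr$truth
      got <- got + take
    }
  }
  E <- length(all_lab)
  out <- array(0, c(E, spec$n_channels, L))
  at <- 0L
  for (blk in all_ep) {
    nb <- dim(blk)[1L]
    out[(at + 1L):(at + nb), , ] <- blk
    at <- at + nb
  }
  ep <- eeg_epochs(out, spec$fs, win, (seq_len(E) - 1) * win, all_lab,
                   montage_labels(spec$n_channels))
  attr(ep, "truths") <- truths
  ep
}
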