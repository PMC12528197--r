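# Preprocessing: FastICA source recovery, artifact-component rejection,
# zero-phase band-pass contracts, segmentation arithmetic.

make_mixed_pair <- function(seed, N = 2560L, fs = 256) {
  set.seed(seed)
  t <- (seq_len(N) - 1) / fs
  s1 <- sin(2 * pi * 10 * t)
  s2 <- 2 * ((2 * t) %% 1) - 1         # 2 Hz sawtooth
  S <- rbind(s1, s2)
  repeat {
    A <- matrix(rnorm(4), 2, 2)
    if (abs(det(A)) > 0.2) break
  }
  list(S = S, A = A, rec = eeg_recording(A %*% S, fs))
}

best_abs_cor <- function(est, true) {
  cm <- abs(cor(t(est), t(true)))
  # best assignment over the two permutations
  max(min(cm[1, 1], cm[2, 2]), min(cm[1, 2], cm[2, 1]))
}

test_that("FastICA recovers a known 2x2 mix of sine and sawtooth", {
  for (seed in 1:5) {
    mp <- make_mixed_pair(seed)
    ica <- run_ica(mp$rec, seed = seed)
    expect_gt(best_abs_cor(ica$sources, mp$S), 0.95)
    # reconstruction identity: mixing %*% sources gives the centered input
    expect_equal(ica$mixing %*% ica$sources,
                 mp$rec$samples - rowMeans(mp$rec$samples),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # sources mutually decorrelated
    expect_lt(abs(cor(ica$sources[1, ], ica$sources[2, ])), 0.05)
  }
})

test_that("identity mixing is recovered up to sign and permutation", {
  # harmonically unrelated sources (3 Hz sawtooth has no 10 Hz component),
  # so the pair is actually uncorrelated and recoverable to r ~ 1
  t <- (0:2559) / 256
  S <- rbind(sin(2 * pi * 10 * t), 2 * ((3 * t) %% 1) - 1)
  ica <- run_ica(eeg_recording(S, 256), seed = 1)
  expect_gt(best_abs_cor(ica$sources, S), 0.99)
})

test_that("rank-deficient input is refused", {
  x <- rnorm(1000)
  rec <- eeg_recording(rbind(x, x), 256)
  expect_error(run_ica(rec), "rank-deficient")
  expect_error(run_ica(eeg_recording(matrix(rnorm(20), 2), 256)),
               "10 samples per channel")
})

test_that("an injected eye-blink component is flagged and removal helps", {
  spec_art <- synth_spec(n_channels = 4L, duration_s = 20,
                         artifact_rate = 30, seed = 3L)
  spec_cln <- synth_spec(n_channels = 4L, duration_s = 20,
                         artifact_rate = 0, seed = 3L)
  dirty <- generate_recording(spec_art, "alpha")$recording
  clean <- generate_recording(spec_cln, "alpha")$recording
  ica <- reject_artifact_components(run_ica(dirty, seed = 1))
  expect_gt(length(ica$rejected_components), 0L)
  r_before <- cor(as.vector(dirty$samples), as.vector(clean$samples))
  r_after <- cor(as.vector(ica$cleaned$samples), as.vector(clean$samples))
  expect_gt(r_after, r_before)
})

test_that("artifact-free band-limited Gaussian sources are not flagged", {
  flagged <- vapply(1:5, function(seed) {
    spec <- synth_spec(n_channels = 4L, duration_s = 20, seed = seed,
                       class_signatures = list(
                         mix = c(delta = 0, theta = 0.8, alpha = 1,
                                 beta = 0.6, gamma = 0.3)))
    rec <- generate_recording(spec, "mix")$recording
    ica <- suppressWarnings(run_ica(rec, seed = seed))
    length(reject_artifact_components(ica)$rejected_components)
  }, numeric(1))
  expect_lte(mean(flagged > 0), 0.2)
})

test_that("flag-everything criteria are refused", {
  spec <- synth_spec(n_channels = 3L, duration_s = 10, seed = 4L)
  ica <- suppressWarnings(run_ica(generate_recording(spec, "alpha")$recording))
  expect_error(reject_artifact_components(ica, kurtosis_threshold = -10),
               "refusing")
})

test_that("band-pass suppresses 60 Hz and passes 10 Hz", {
  t <- (0:(256 * 20 - 1)) / 256
  tone60 <- eeg_recording(matrix(sin(2 * pi * 60 * t), 1), 256)
  tone10 <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), 256)
  f60 <- bandpass(tone60, 0.5, 50)
  f10 <- bandpass(tone10, 0.5, 50)
  expect_lt(rms(f60$samples) / rms(tone60$samples), 0.10)
  expect_lt(abs(rms(f10$samples) / rms(tone10$samples) - 1), 0.05)
  # DC is outside the passband: interior of a filtered constant is ~ 0
  dc <- bandpass(eeg_recording(matrix(1, 1, 5120), 256), 0.5, 50)
  expect_lt(max(abs(dc$samples[1, 2048:3072])), 1e-3)
})

test_that("filtering is linear and validates its spec", {
  set.seed(8)
  x <- matrix(rnorm(2000), 1)
  y <- matrix(rnorm(2000), 1)
  fx <- bandpass(eeg_recording(x, 256), 1, 40)$samples
  fy <- bandpass(eeg_recording(y, 256), 1, 40)$samples
  fxy <- bandpass(eeg_recording(2 * x - 3 * y, 256), 1, 40)$samples
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-5)
  rec <- eeg_recording(x, 256)
  expect_error(bandpass(rec, 0.5, 130), "Nyquist")
  expect_error(bandpass(rec, 50, 10), "low_hz")
  expect_error(bandpass(eeg_recording(matrix(rnorm(10), 1), 256), 0.5, 50),
               "warm-up")
})

test_that("segmentation arithmetic matches the windowing rule", {
  rec <- eeg_recording(matrix(rnorm(2 * 2560), 2), 256)
  ep <- segment_epochs(rec, 2)
  expect_identical(dim(ep$epochs), c(5L, 2L, 512L))
  expect_equal(ep$start_times, c(0, 2, 4, 6, 8))
  # trailing partial window dropped
  rec2 <- eeg_recording(matrix(rnorm(2 * 2660), 2), 256)
  ep2 <- segment_epochs(rec2, 2)
  expect_identical(dim(ep2$epochs)[1], 5L)
  # overlap 1 s: starts 0..8 s
  ep3 <- segment_epochs(rec, 2, 1)
  expect_identical(dim(ep3$epochs)[1], 9L)
  expect_equal(ep3$start_times, 0:8)
  # sample conservation at zero overlap: E * L + dropped = N
  expect_identical(5L * 512L + (2660L - 5L * 512L), 2660L)
  expect_error(segment_epochs(eeg_recording(matrix(1:100, 1), 256), 2),
               "shorter than one window")
  expect_error(segment_epochs(rec, 2, 2), "overlap_s")
})

test_that("epoch windows reproduce the raw samples (half-open intervals)", {
  rec <- eeg_recording(matrix(seq_len(1024), 1), 256)
  ep <- segment_epochs(rec, 2)
  expect_equal(ep$epochs[1, 1, ], 1:512)
  expect_equal(ep$epochs[2, 1, ], 513:1024)
})
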