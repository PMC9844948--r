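test_that("spectral config ties the window to the frame rate", {
  sc <- spectral_config()
  expect_equal(sc$window, 640L)     # 16000 Hz / 25 fps
  expect_equal(sc$hop, sc$window)   # non-overlapping
  expect_equal(sc$n_fft, sc$window)
  expect_error(spectral_config(feature_kind = "mfcc", n_mels = 10, n_mfcc = 10),
               "config error")
})

test_that("waveform normalization scales to peak one and resamples", {
  w <- list(samples = c(0, 0.25, -0.5, 0.1), rate = 16000L)
  out <- normalize_waveform(w)
  expect_equal(max(abs(out$samples)), 1)
  expect_equal(out$samples, w$samples / 0.5)
  z <- normalize_waveform(list(samples = numeric(10), rate = 16000L))
  expect_true(all(z$samples == 0))
  p <- list(samples = sin(2 * pi * 3 * seq(0, 1, length.out = 16000)), rate = 16000L)
  expect_equal(normalize_waveform(p)$samples, p$samples / max(abs(p$samples)))
  # resampling halves the length for a 32 kHz input
  r <- normalize_waveform(list(samples = rnorm(3200), rate = 32000L))
  expect_equal(length(r$samples), 1600L)
  expect_equal(r$rate, 16000L)
  expect_error(normalize_waveform(list(samples = numeric(0), rate = 16000L)),
               "empty")
})

test_that("stft yields one row per video frame", {
  sc <- spectral_config()
  s48 <- list(samples = rnorm(48000), rate = 16000L)   # 3 s
  expect_equal(nrow(frame_sync_stft(s48, sc)), 75L)
  s1 <- list(samples = rnorm(640), rate = 16000L)
  expect_equal(dim(frame_sync_stft(s1, sc)), c(1L, 321L))
  # partial final window is zero padded
  expect_equal(nrow(frame_sync_stft(list(samples = rnorm(650), rate = 16000L), sc)), 2L)
})

test_that("an exact-bin sine concentrates its energy in the Hann mainlobe", {
  # the Hann window spreads an exact-bin sinusoid over bins k-1, k, k+1
  # with amplitude ratio 1/2 : 1 : 1/2 (power 1/4 : 1 : 1/4), so the peak
  # bin holds 2/3 of the row power and the mainlobe virtually all of it
  sc <- spectral_config()
  for (k in c(8, 40, 128)) {
    f <- 25 * k
    t <- (0:(16000 - 1)) / 16000
    p <- frame_sync_stft(list(samples = sin(2 * pi * f * t), rate = 16000L), sc)
    row <- p[5, ]
    expect_equal(which.max(row), k + 1L)
    expect_gt(sum(row[k:(k + 2)]) / sum(row), 0.999)
    expect_equal(row[k + 1] / sum(row[k:(k + 2)]), 1 / 1.5, tolerance = 1e-6)
  }
})

test_that("mel filterbank has positive band sums and local support", {
  sc <- spectral_config(n_mels = 40)
  fb <- mel_filterbank(sc)
  expect_equal(dim(fb), c(40L, 321L))
  expect_true(all(rowSums(fb) > 0))
  # an impulse in one FFT bin excites at most two mel bands
  p <- matrix(0, 1, 321); p[1, 101] <- 1
  lm <- mel_spectrogram(p, sc)
  floor_val <- log(1e-10)
  expect_lte(sum(lm[1, ] > floor_val + 1e-9), 2L)
  expect_error(mel_filterbank(spectral_config(feature_kind = "mel", n_mels = 400)),
               "config error")
})

test_that("mel chain matches an independently coded oracle", {
  # oracle built from first principles: explicit DFT framing, textbook
  # Slaney mel points, explicit triangle evaluation, explicit DCT-II sums
  sc <- spectral_config(n_mels = 16, n_mfcc = 6)
  set.seed(8)
  x <- rnorm(640 * 3)
  p <- frame_sync_stft(list(samples = x, rate = 16000L), sc)
  # oracle power spectrogram
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:639) / 640)
  for (fr in 1:3) {
    seg <- x[(fr - 1) * 640 + 1:640] * hann
    ft <- sapply(0:320, function(k) sum(seg * exp(-2i * pi * k * (0:639) / 640)))
    expect_equal(p[fr, ], Mod(ft)^2, tolerance = 1e-8)
  }
  hz2mel <- function(f) ifelse(f < 1000, f * 3 / 200, 15 + 27 * log(f / 1000) / log(6.4))
  mel2hz <- function(m) ifelse(m < 15, m * 200 / 3, 1000 * 6.4^((m - 15) / 27))
  edges <- mel2hz(seq(hz2mel(0), hz2mel(8000), length.out = 18))
  freqs <- (0:320) * 25
  fb_oracle <- t(sapply(1:16, function(k) {
    up <- (freqs - edges[k]) / (edges[k + 1] - edges[k])
    down <- (edges[k + 2] - freqs) / (edges[k + 2] - edges[k + 1])
    pmax(0, pmin(up, down)) * 2 / (edges[k + 2] - edges[k])
  }))
  lm <- mel_spectrogram(p, sc)
  expect_equal(lm, log(pmax(p %*% t(fb_oracle), 1e-10)), tolerance = 1e-8)
  m <- mfcc(lm, sc)
  expect_equal(dim(m), c(3L, 6L))
  dct_oracle <- function(v) {
    n <- length(v)
    sapply(1:(n - 1), function(k) sqrt(2 / n) * sum(v * cos(pi * k * (0:(n - 1) + 0.5) / n)))
  }
  for (fr in 1:3) expect_equal(m[fr, ], dct_oracle(lm[fr, ])[1:6], tolerance = 1e-8)
})

test_that("mfcc drops the average-power coefficient and truncates", {
  sc <- spectral_config(n_mels = 40, n_mfcc = 24)
  const <- matrix(3.7, 2, 40)
  expect_true(all(abs(mfcc(const, sc)) < 1e-12))
  expect_equal(ncol(mfcc(matrix(rnorm(80), 2, 40), sc)), 24L)
  # a log-mel row matching DCT basis k=1 excites only coefficient 1
  n <- 40
  row <- cos(pi * 1 * ((0:(n - 1)) + 0.5) / n)
  out <- mfcc(rbind(row), sc)
  expect_gt(abs(out[1, 1]), 0.5)
  expect_lt(max(abs(out[1, -1])), 1e-10)
  expect_error(mfcc(matrix(0, 1, 10), spectral_config(n_mels = 40, n_mfcc = 24)),
               "config error")
})

test_that("feature extraction is frame-aligned for synthesized audio", {
  cfg <- synth_config()
  set.seed(5)
  wav <- synth_audio("i need help", cfg)
  n_frames <- length(wav$samples) / 640
  for (kind in c("mfcc", "mel")) {
    sc <- spectral_config(feature_kind = kind, n_mels = 40, n_mfcc = 12)
    f <- extract_features(wav, sc)
    expect_equal(nrow(f), n_frames)
    expect_equal(ncol(f), sc$d_af)
  }
  f75 <- extract_features(wav, spectral_config(n_mfcc = 12), n_frames = 75L)
  expect_equal(nrow(f75), 75L)
})

test_that("normalizer hand example, zero-variance error and inversion", {
  norm <- fit_normalizer(list(rbind(c(0, 2)), rbind(c(2, 4))))
  expect_equal(unname(norm$mean), c(1, 3))
  expect_equal(unname(norm$sd), c(1, 1))   # population std
  expect_error(fit_normalizer(list(rbind(c(1, 2), c(1, 5)))), "coefficient")
  set.seed(13)
  mats <- replicate(4, matrix(rnorm(60, sd = 3), 10, 6), simplify = FALSE)
  nz <- fit_normalizer(mats)
  normed <- lapply(mats, apply_normalizer, norm = nz)
  pooled <- do.call(rbind, normed)
  expect_lt(max(abs(colMeans(pooled))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(sweep(pooled, 2, colMeans(pooled))^2)) - 1)), 1e-9)
  # apply then invert is the identity; a row equal to the mean maps to zero
  back <- invert_normalizer(normed[[1]], nz)
  expect_lt(max(abs(back - mats[[1]])), 1e-12)
  expect_true(all(abs(apply_normalizer(rbind(nz$mean), nz)) < 1e-12))
  expect_error(apply_normalizer(matrix(0, 2, 3), nz), "mismatch")
})

test_that("features round-trip through the binary cache", {
  f <- matrix(rnorm(75 * 12), 75, 12)
  path <- tempfile()
  write_features(f, path, cfg = spectral_config(n_mfcc = 12))
  expect_equal(read_features(path), f)
})
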