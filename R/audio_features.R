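#' Spectral configuration for frame-synchronized features
#'
#' Window, hop and FFT length all equal `rate / fps` samples (640 at 16 kHz
#' and 25 fps) so one feature row covers exactly one video frame. Windows
#' are left-aligned and non-overlapping: row `t` covers samples
#' `[640 t, 640 (t + 1))`.
#'
#' @param feature_kind `"mfcc"` or `"mel"`.
#' @param n_mels number of Mel bands (40, 80 or 120 in the study grid).
#' @param n_mfcc number of kept cepstral coefficients (6, 12 or 24), counted
#'   after dropping coefficient 0 (average power).
#' @param rate audio sample rate in Hz.
#' @param fps video frame rate.
#' @param fmin,fmax Mel filterbank frequency range in Hz.
#' @return a `vsr_spectral_config`.
#' @export
spectral_config <- function(feature_kind = c("mfcc", "mel"), n_mels = 40L,
                            n_mfcc = 24L, rate = 16000L, fps = 25L,
                            fmin = 0, fmax = 8000) {
  feature_kind <- match.arg(feature_kind)
  window <- rate / fps
  stopifnot(window == round(window))
  if (feature_kind == "mfcc" && n_mfcc >= n_mels) {
    stop("config error: n_mfcc must be smaller than n_mels")
  }
  structure(
    list(feature_kind = feature_kind, n_mels = as.integer(n_mels),
         n_mfcc = as.integer(n_mfcc), rate = as.integer(rate),
         fps = as.integer(fps), window = as.integer(window),
         hop = as.integer(window), n_fft = as.integer(window),
         fmin = fmin, fmax = fmax,
         d_af = if (feature_kind == "mfcc") as.integer(n_mfcc) else as.integer(n_mels)),
    class = "vsr_spectral_config"
  )
}

#' Normalize (and resample) a waveform
#'
#' Resamples to 16 kHz if needed (polyphase filtering) and scales by the
#' maximum absolute value so the signal peaks at 1. An all-zero signal is
#' returned unchanged.
#'
#' @param wave list with `samples` and `rate`.
#' @param target_rate target sample rate (16000).
#' @return waveform list at `target_rate` with samples in `[-1, 1]`.
#' @export
normalize_waveform <- function(wave, target_rate = 16000L) {
  if (length(wave$samples) == 0L) stop("empty waveform")
  x <- wave$samples
  if (wave$rate != target_rate) {
    g <- gcd_int(as.integer(target_rate), as.integer(wave$rate))
    x <- signal::resample(x, target_rate / g, wave$rate / g)
  }
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  list(samples = as.numeric(x), rate = as.integer(target_rate))
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Frame-synchronized power spectrogram
#'
#' Non-overlapping, left-aligned Hann-windowed STFT with window = hop =
#' `rate/fps` samples; the final partial window is zero-padded, so audio of
#' `len` samples yields `ceil(len / window)` rows.
#'
#' @param wave waveform list (`rate` must equal `cfg$rate`).
#' @param cfg a [spectral_config()].
#' @return `T x (n_fft/2 + 1)` matrix of power values `|FFT|^2`.
#' @export
frame_sync_stft <- function(wave, cfg = spectral_config()) {
  stopifnot(wave$rate == cfg$rate)
  x <- wave$samples
  win <- cfg$window
  n_frames <- ceiling(length(x) / win)
  padded <- c(x, numeric(n_frames * win - length(x)))
  frames <- matrix(padded, nrow = win, ncol = n_frames)
  frames <- frames * hann_window(win)
  spec <- stats::mvfft(frames)[seq_len(win / 2 + 1), , drop = FALSE]
  t(Mod(spec)^2)
}

hz_to_mel <- function(f) {
  # Slaney-style curve: linear below 1 kHz, logarithmic above
  f_sp <- 200 / 3
  logstep <- log(6.4) / 27
  ifelse(f < 1000, f / f_sp, 15 + log(pmax(f, 1000) / 1000) / logstep)
}

mel_to_hz <- function(m) {
  f_sp <- 200 / 3
  logstep <- log(6.4) / 27
  ifelse(m < 15, m * f_sp, 1000 * exp(logstep * (m - 15)))
}

#' Triangular Mel filterbank matrix
#'
#' Slaney-style Mel curve with area normalization: band `k` is a triangle
#' between mel-spaced edge frequencies scaled by `2 / bandwidth`.
#'
#' @param cfg a [spectral_config()].
#' @return `n_mels x (n_fft/2 + 1)` matrix.
#' @export
mel_filterbank <- function(cfg = spectral_config()) {
  n_bins <- cfg$n_fft / 2 + 1
  if (cfg$n_mels > n_bins) {
    stop("config error: n_mels exceeds number of spectral bins")
  }
  fft_freqs <- (0:(n_bins - 1)) * cfg$rate / cfg$n_fft
  mel_edges <- seq(hz_to_mel(cfg$fmin), hz_to_mel(cfg$fmax),
                   length.out = cfg$n_mels + 2)
  hz_edges <- mel_to_hz(mel_edges)
  fb <- matrix(0, cfg$n_mels, n_bins)
  for (k in seq_len(cfg$n_mels)) {
    lower <- (fft_freqs - hz_edges[k]) / (hz_edges[k + 1] - hz_edges[k])
    upper <- (hz_edges[k + 2] - fft_freqs) / (hz_edges[k + 2] - hz_edges[k + 1])
    fb[k, ] <- pmax(0, pmin(lower, upper)) * 2 / (hz_edges[k + 2] - hz_edges[k])
  }
  fb
}

#' Log-Mel spectrogram
#'
#' Applies the triangular filterbank to the power spectrogram, then the
#' natural log with floor `log_floor` (energies are summed within each band
#' before taking the log, the standard MFCC chain).
#'
#' @param power `T x (n_fft/2+1)` power spectrogram.
#' @param cfg a [spectral_config()].
#' @param log_floor lower clamp before the log (default 1e-10).
#' @return `T x n_mels` matrix.
#' @export
mel_spectrogram <- function(power, cfg = spectral_config(), log_floor = 1e-10) {
  fb <- mel_filterbank(cfg)
  log(pmax(power %*% t(fb), log_floor))
}

dct_matrix <- function(n) {
  # orthonormal DCT-II
  k <- 0:(n - 1)
  m <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' Mel frequency cepstral coefficients
#'
#' Orthonormal DCT-II along the Mel axis; coefficient 0 (average power) is
#' dropped and coefficients `1..n_mfcc` kept, discarding the higher-order
#' spectral detail.
#'
#' @param logmel `T x n_mels` log-Mel matrix from [mel_spectrogram()].
#' @param cfg a [spectral_config()].
#' @return `T x n_mfcc` matrix.
#' @export
mfcc <- function(logmel, cfg = spectral_config()) {
  n_mels <- ncol(logmel)
  if (cfg$n_mfcc >= n_mels) stop("config error: n_mfcc must be < n_mels")
  d <- dct_matrix(n_mels)
  (logmel %*% t(d))[, 2:(cfg$n_mfcc + 1), drop = FALSE]
}

#' Extract frame-aligned audio features
#'
#' Full chain STFT -> log-Mel (-> MFCC). When `n_frames` is given the
#' waveform is zero-padded to `n_frames * window` samples first, so
#' features stay aligned with black-padded video frames.
#'
#' @param wave normalized waveform list at 16 kHz.
#' @param cfg a [spectral_config()].
#' @param n_frames optional target frame count (e.g. 75).
#' @return `T x d_AF` feature matrix.
#' @export
extract_features <- function(wave, cfg = spectral_config(), n_frames = NULL) {
  if (!is.null(n_frames)) {
    need <- n_frames * cfg$window
    if (length(wave$samples) > need) {
      stop("waveform longer than n_frames * window")
    }
    wave$samples <- c(wave$samples, numeric(need - length(wave$samples)))
  }
  p <- frame_sync_stft(wave, cfg)
  lm <- mel_spectrogram(p, cfg)
  if (cfg$feature_kind == "mfcc") mfcc(lm, cfg) else lm
}

#' Per-coefficient dataset normalizer
#'
#' Pools all rows of all feature sequences and records, per coefficient,
#' the mean and the population (1/N) standard deviation, so that applying
#' the normalizer to its fitting set yields zero mean and unit standard
#' deviation per coefficient.
#'
#' @param features list of `T x d_AF` matrices (or a single matrix).
#' @return a `vsr_normalizer` with `mean` and `sd` vectors.
#' @export
fit_normalizer <- function(features) {
  if (is.matrix(features)) features <- list(features)
  pooled <- do.call(rbind, features)
  if (nrow(pooled) < 2L) stop("need at least two feature rows")
  mu <- colMeans(pooled)
  sd_ <- sqrt(colMeans(sweep(pooled, 2, mu)^2))
  bad <- which(sd_ <= 0)
  if (length(bad) > 0) {
    stop("zero-variance coefficient(s): ", paste(bad, collapse = ", "))
  }
  structure(list(mean = mu, sd = sd_, d_af = length(mu)),
            class = "vsr_normalizer")
}

#' Apply / invert a feature normalizer
#'
#' `(x - mean) / sd` per coefficient, and its exact inverse.
#'
#' @param seq `T x d_AF` feature matrix.
#' @param norm a `vsr_normalizer`.
#' @return matrix of the same shape.
#' @export
apply_normalizer <- function(seq, norm) {
  if (ncol(seq) != norm$d_af) stop("feature dimension mismatch")
  sweep(sweep(seq, 2, norm$mean), 2, norm$sd, "/")
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(seq, norm) {
  if (ncol(seq) != norm$d_af) stop("feature dimension mismatch")
  sweep(sweep(seq, 2, norm$sd, "*"), 2, norm$mean, "+")
}

#' Cache features to disk
#'
#' Raw little-endian doubles plus a JSON sidecar recording the matrix shape,
#' the spectral configuration and (optionally) normalizer statistics.
#'
#' @param features `T x d_AF` matrix.
#' @param path output path (sidecar at `<path>.json`).
#' @param cfg the [spectral_config()] used.
#' @param norm optional `vsr_normalizer`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, cfg = NULL, norm = NULL) {
  con <- file(path, "wb")
  writeBin(as.numeric(features), con, size = 8, endian = "little")
  close(con)
  meta <- list(nrow = nrow(features), ncol = ncol(features))
  if (!is.null(cfg)) meta$config <- unclass(cfg)
  if (!is.null(norm)) meta$normalizer <- list(mean = norm$mean, sd = norm$sd)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  x <- readBin(con, "double", n = meta$nrow * meta$ncol, size = 8,
               endian = "little")
  close(con)
  matrix(x, meta$nrow, meta$ncol)
}
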