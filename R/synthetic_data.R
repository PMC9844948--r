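# Synthetic audiovisual corpus generator.
#
# Generates desk-scale paired video/audio/transcript data with the
# structural properties of the real recordings: 25 fps clips of at most 75
# frames, 16 kHz mono audio whose length is exactly n_frames * 640 samples,
# lowercase transcripts over the 27-symbol text alphabet, and exact mouth
# landmarks. Each text symbol is assigned a distinct mouth shape (aperture,
# horizontal spread) and a pair of pure tones on the 25 Hz STFT bin grid,
# so frames and audio are two renderings of one articulation trajectory:
# visually legible mouths and nearly noiseless audio feature targets.

icu_phrases <- function() {
  c("i feel happy", "im hot", "im hungry", "i need water", "im cold",
    "i am tired", "im thirsty", "call the nurse", "i need help",
    "im in pain", "yes please", "no thank you", "i feel sick",
    "my head hurts", "i want to sleep", "im scared", "i feel dizzy",
    "please stay", "it hurts", "im okay")
}

grid_slots <- function() {
  list(
    command = c("bin", "lay", "set"),
    color = c("red", "blue"),
    preposition = c("at", "in"),
    letter = c("b", "f", "j", "n", "s"),
    digit = c("one", "two", "six", "nine"),
    adverb = c("now", "soon", "again")
  )
}

#' Synthetic corpus configuration
#'
#' @param mode `"icu"` (free-phrase list modeled on essential patient
#'   communication) or `"grid"` (fixed command-color-preposition-letter-
#'   digit-adverb slot grammar with reduced slot inventories).
#' @param n_videos number of clips to generate.
#' @param frames_per_char frames spent on each character (default 4 for
#'   ICU mode; 3 for the longer GRID-style sentences so every clip fits in
#'   75 frames).
#' @param canvas `c(height, width)` of the rendered face canvas.
#' @param mouth_center `c(x, y)` mouth center in pixels.
#' @param mouth_base `c(half_width, half_height)` of a fully open mouth.
#' @param jitter per-frame mouth-center jitter amplitude in pixels.
#' @param noise_floor audio noise standard deviation before peak scaling.
#' @param fps,rate frame and audio sampling rates.
#' @param seed RNG seed.
#' @return a `vsr_synth_config`.
#' @export
synth_config <- function(mode = c("icu", "grid"), n_videos = 100L,
                         frames_per_char = NULL, canvas = c(120L, 160L),
                         mouth_center = c(80, 70), mouth_base = c(18, 12),
                         jitter = 1, noise_floor = 0.002, fps = 25L,
                         rate = 16000L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(frames_per_char)) {
    frames_per_char <- if (mode == "grid") 3L else 4L
  }
  structure(
    list(mode = mode, n_videos = as.integer(n_videos),
         frames_per_char = as.integer(frames_per_char), canvas = canvas,
         mouth_center = mouth_center, mouth_base = mouth_base,
         jitter = jitter, noise_floor = noise_floor, fps = as.integer(fps),
         rate = as.integer(rate), seed = as.integer(seed)),
    class = "vsr_synth_config"
  )
}

#' Articulation table mapping text symbols to mouth shape and tones
#'
#' Deterministic table over `a`-`z` and space: per symbol a mouth aperture
#' and spread in `[0, 1]` and two tone frequencies on exact multiples of
#' 25 Hz (the STFT bin spacing at window 640 / rate 16 kHz), so each tone
#' occupies a single spectral bin. Space is a closed mouth and silence.
#'
#' @return data.frame with columns `symbol`, `aperture`, `spread`, `f1`,
#'   `f2`, `amplitude`.
#' @export
build_articulation_table <- function() {
  i <- 0:25
  # 6 x 5 grid of (aperture, spread) levels: adjacent levels differ by a
  # few pixels of relative lip geometry after crop normalization, so
  # characters stay visually distinguishable in the 50 x 100 mouth crop
  letters_tab <- data.frame(
    symbol = letters,
    aperture = 0.1 + 0.9 * (i %% 6) / 5,
    spread = 0.1 + 0.9 * (i %/% 6) / 4,
    f1 = 200 + 100 * i,
    f2 = 3100 + 100 * i,
    amplitude = 1,
    stringsAsFactors = FALSE
  )
  rbind(letters_tab,
        data.frame(symbol = " ", aperture = 0, spread = 0, f1 = 0, f2 = 0,
                   amplitude = 0, stringsAsFactors = FALSE))
}

# per-frame articulation trajectory: each character holds for
# frames_per_char frames; the last frame of a character blends 50/50 with
# the next one (one-frame inter-character transition)
articulation_trajectory <- function(sentence, cfg) {
  tab <- build_articulation_table()
  chars <- strsplit(sentence, "", fixed = TRUE)[[1]]
  rows <- match(chars, tab$symbol)
  if (anyNA(rows)) stop("unencodable sentence for synthesis: ", sentence)
  fpc <- cfg$frames_per_char
  n_frames <- length(chars) * fpc
  traj <- data.frame(frame = seq_len(n_frames), char_idx = rep(seq_along(chars), each = fpc))
  traj$aperture <- tab$aperture[rows[traj$char_idx]]
  traj$spread <- tab$spread[rows[traj$char_idx]]
  traj$f1 <- tab$f1[rows[traj$char_idx]]
  traj$f2 <- tab$f2[rows[traj$char_idx]]
  traj$amplitude <- tab$amplitude[rows[traj$char_idx]] * traj$aperture
  blend <- which(traj$frame %% fpc == 0 & traj$char_idx < length(chars))
  if (length(blend) > 0) {
    nxt <- rows[traj$char_idx[blend] + 1L]
    traj$aperture[blend] <- 0.5 * (traj$aperture[blend] + tab$aperture[nxt])
    traj$spread[blend] <- 0.5 * (traj$spread[blend] + tab$spread[nxt])
    traj$amplitude[blend] <- 0.5 * (traj$amplitude[blend] +
                                      tab$amplitude[nxt] * tab$aperture[nxt])
  }
  traj
}

render_mouth_frame <- function(cfg, cx, cy, a, b, inner_a, inner_b) {
  H <- cfg$canvas[1]; W <- cfg$canvas[2]
  x <- matrix(rep(0:(W - 1), each = H), H, W)
  y <- matrix(rep(0:(H - 1), W), H, W)
  frame <- matrix(160, H, W)
  # face oval for context
  face <- ((x - cfg$mouth_center[1]) / 55)^2 + ((y - cfg$mouth_center[2] + 15) / 65)^2 <= 1
  frame[face] <- 200
  lips <- ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
  frame[lips] <- 90
  # open inner mouth: its size RELATIVE to the lip outline carries the
  # articulation signal, since the landmark-based crop rescales the outer
  # lips to a fixed extent
  mouth <- ((x - cx) / inner_a)^2 + ((y - cy) / inner_b)^2 <= 1
  frame[mouth] <- 20
  frame
}

#' Render the video frames (and exact landmarks) for a sentence
#'
#' The mouth is an ellipse whose horizontal/vertical half-axes follow the
#' sentence's articulation trajectory; landmarks are the ellipse extremal
#' points, so they are exact by construction. A small seeded jitter moves
#' the mouth center between frames. Frames are 8-bit grayscale replicated
#' to RGB.
#'
#' @param sentence normalized sentence (a-z and space).
#' @param cfg a [synth_config()]; draws jitter from the current RNG stream.
#' @return list with `frames` (list of `H x W x 3` arrays) and `landmarks`
#'   (list of [mouth_landmarks()]).
#' @export
render_video <- function(sentence, cfg = synth_config()) {
  traj <- articulation_trajectory(sentence, cfg)
  frames <- vector("list", nrow(traj))
  lms <- vector("list", nrow(traj))
  for (f in seq_len(nrow(traj))) {
    cx <- cfg$mouth_center[1] + stats::runif(1, -cfg$jitter, cfg$jitter)
    cy <- cfg$mouth_center[2] + stats::runif(1, -cfg$jitter, cfg$jitter)
    a <- max(2, cfg$mouth_base[1] * (0.6 + 0.4 * traj$spread[f]))
    b <- max(1.5, cfg$mouth_base[2] * (0.25 + 0.75 * traj$aperture[f]))
    inner_a <- a * (0.25 + 0.65 * traj$spread[f])
    inner_b <- b * (0.1 + 0.8 * traj$aperture[f])
    g <- render_mouth_frame(cfg, cx, cy, a, b, inner_a, inner_b)
    frames[[f]] <- array(g, c(dim(g), 3L))
    lms[[f]] <- mouth_landmarks(c(cx - a, cy), c(cx + a, cy),
                                c(cx, cy - b), c(cx, cy + b))
  }
  list(frames = frames, landmarks = lms)
}

#' Synthesize the audio track for a sentence
#'
#' For each video frame, 640 samples of the active character's two tones
#' (amplitude proportional to the mouth aperture, silence for space) plus
#' a low noise floor; the waveform is peak-normalized. Length is exactly
#' `n_frames * 640` samples.
#'
#' @param sentence normalized sentence.
#' @param cfg a [synth_config()]; noise uses the current RNG stream.
#' @return waveform list (`samples`, `rate`).
#' @export
synth_audio <- function(sentence, cfg = synth_config()) {
  traj <- articulation_trajectory(sentence, cfg)
  spf <- cfg$rate / cfg$fps
  n <- nrow(traj) * spf
  t <- (0:(n - 1)) / cfg$rate
  amp <- rep(traj$amplitude, each = spf)
  f1 <- rep(traj$f1, each = spf)
  f2 <- rep(traj$f2, each = spf)
  x <- amp * (sin(2 * pi * f1 * t) + 0.5 * sin(2 * pi * f2 * t))
  x <- x + stats::rnorm(n, 0, cfg$noise_floor)
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  list(samples = x, rate = cfg$rate)
}

# deterministic per-sample seed so samples can be regenerated one at a
# time (streaming) identically to batch generation
sample_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483646) + 1L
}

sample_sentence <- function(cfg) {
  if (cfg$mode == "icu") {
    sample(icu_phrases(), 1L)
  } else {
    paste(vapply(grid_slots(), sample, character(1), size = 1L), collapse = " ")
  }
}

#' Generate one synthetic sample
#'
#' @param sentence normalized sentence.
#' @param cfg a [synth_config()].
#' @param speaker_id,view_tag labels recorded on the sample.
#' @return a [raw_sample()] with exact landmarks.
#' @export
generate_sample <- function(sentence, cfg = synth_config(), speaker_id = "s1",
                            view_tag = "center") {
  rv <- render_video(sentence, cfg)
  wav <- synth_audio(sentence, cfg)
  raw_sample(rv$frames, wav, sentence, speaker_id = speaker_id,
             view_tag = view_tag, landmarks = rv$landmarks)
}

#' Generate a synthetic corpus
#'
#' Draws `cfg$n_videos` sentences (ICU phrase list or GRID-style grammar),
#' renders each, and either keeps the corpus in memory or writes the
#' on-disk fixture layout (one directory per sample with
#' `frame_0000.png...`, `audio.wav`, `landmarks.csv`, `transcript.txt`,
#' plus a `manifest.csv` with columns sample_dir, speaker_id, view_tag,
#' transcript). Reproducible under `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory, or `NULL` (default) for an in-memory corpus.
#' @return a `vsr_corpus_data`: list with `samples` (when in memory),
#'   `manifest` data.frame and `config`.
#' @export
generate_corpus <- function(cfg = synth_config(), dir = NULL) {
  set.seed(cfg$seed)
  sentences <- replicate(cfg$n_videos, sample_sentence(cfg))
  speakers <- paste0("s", 1 + (seq_len(cfg$n_videos) - 1L) %% 3L)
  manifest <- data.frame(
    sample_dir = sprintf("sample_%04d", seq_len(cfg$n_videos)),
    speaker_id = speakers,
    view_tag = "center",
    transcript = sentences,
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    # stream to disk: generate, write, discard, one sample at a time
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(cfg$n_videos)) {
      set.seed(sample_seed(cfg$seed, i))
      s <- generate_sample(sentences[i], cfg, speaker_id = speakers[i])
      write_sample_dir(s, file.path(dir, manifest$sample_dir[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    samples <- NULL
  } else {
    samples <- vector("list", cfg$n_videos)
    for (i in seq_len(cfg$n_videos)) {
      set.seed(sample_seed(cfg$seed, i))
      samples[[i]] <- generate_sample(sentences[i], cfg, speaker_id = speakers[i])
    }
  }
  structure(list(samples = samples, manifest = manifest, config = cfg,
                 dir = dir),
            class = "vsr_corpus_data")
}

#' @export
print.vsr_corpus_data <- function(x, ...) {
  cat(sprintf("<vsr_corpus_data> %d videos (%s mode)%s\n",
              nrow(x$manifest), x$config$mode,
              if (is.null(x$dir)) " in memory" else paste0(" at ", x$dir)))
  invisible(x)
}

#' Write / read the on-disk fixture layout for one sample
#'
#' @param sample a `vsr_raw_sample`.
#' @param path sample directory.
#' @return the path (write) or a `vsr_raw_sample` (read).
#' @export
write_sample_dir <- function(sample, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(sample$frames)) {
    fr <- sample$frames[[i]]
    if (length(dim(fr)) == 3L) fr <- to_grayscale(fr)
    png::writePNG(fr / 255, file.path(path, sprintf("frame_%04d.png", i - 1L)))
  }
  write_wav(sample$waveform$samples, sample$waveform$rate,
            file.path(path, "audio.wav"))
  lm <- do.call(rbind, lapply(seq_along(sample$landmarks), function(i) {
    l <- sample$landmarks[[i]]
    data.frame(frame_index = i - 1L,
               lx = l$left_corner[1], ly = l$left_corner[2],
               rx = l$right_corner[1], ry = l$right_corner[2],
               ux = l$upper_mid[1], uy = l$upper_mid[2],
               dx = l$lower_mid[1], dy = l$lower_mid[2])
  }))
  utils::write.csv(lm, file.path(path, "landmarks.csv"), row.names = FALSE)
  writeLines(sample$transcript, file.path(path, "transcript.txt"))
  invisible(path)
}

#' @rdname write_sample_dir
#' @param speaker_id,view_tag labels to attach on read.
#' @export
read_sample_dir <- function(path, speaker_id = "s1", view_tag = "center") {
  pngs <- sort(list.files(path, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  if (length(pngs) == 0L) stop("no frames found in ", path)
  frames <- lapply(pngs, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    round(img * 255)
  })
  wav <- read_wav(file.path(path, "audio.wav"))
  lmdf <- utils::read.csv(file.path(path, "landmarks.csv"))
  lms <- lapply(seq_len(nrow(lmdf)), function(i) {
    mouth_landmarks(c(lmdf$lx[i], lmdf$ly[i]), c(lmdf$rx[i], lmdf$ry[i]),
                    c(lmdf$ux[i], lmdf$uy[i]), c(lmdf$dx[i], lmdf$dy[i]))
  })
  transcript <- readLines(file.path(path, "transcript.txt"), warn = FALSE)[1]
  raw_sample(frames, wav, transcript, speaker_id = speaker_id,
             view_tag = view_tag, landmarks = lms)
}

#' Streaming (lazily generated) corpus
#'
#' Draws the sentence list and manifest up front but defers rendering:
#' consumers regenerate each sample on demand from a deterministic
#' per-sample seed, so even large corpora never hold raw frames in
#' memory and the samples are identical to what [generate_corpus()]
#' produces for the same configuration.
#'
#' @param cfg a [synth_config()].
#' @return a `vsr_corpus_data` with `samples = NULL`, `dir = NULL` and the
#'   generating `config` attached.
#' @export
stream_corpus <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  sentences <- replicate(cfg$n_videos, sample_sentence(cfg))
  speakers <- paste0("s", 1 + (seq_len(cfg$n_videos) - 1L) %% 3L)
  manifest <- data.frame(
    sample_dir = sprintf("sample_%04d", seq_len(cfg$n_videos)),
    speaker_id = speakers,
    view_tag = "center",
    transcript = sentences,
    stringsAsFactors = FALSE
  )
  structure(list(samples = NULL, manifest = manifest, config = cfg,
                 dir = NULL),
            class = "vsr_corpus_data")
}

#' Load a corpus previously written by [generate_corpus()]
#'
#' @param dir corpus directory containing `manifest.csv`.
#' @return a `vsr_corpus_data` with samples in memory.
#' @export
load_corpus <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              colClasses = "character")
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    read_sample_dir(file.path(dir, manifest$sample_dir[i]),
                    speaker_id = manifest$speaker_id[i],
                    view_tag = manifest$view_tag[i])
  })
  structure(list(samples = samples, manifest = manifest, config = NULL,
                 dir = dir),
            class = "vsr_corpus_data")
}
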