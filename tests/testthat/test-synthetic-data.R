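test_that("articulation table covers the text alphabet distinctively", {
  tab <- build_articulation_table()
  expect_equal(nrow(tab), 27L)
  expect_setequal(tab$symbol, c(letters, " "))
  sp <- tab[tab$symbol == " ", ]
  expect_equal(sp$aperture, 0)
  expect_equal(sp$amplitude, 0)
  # distinct symbols have distinct articulation triples, and (aperture, f1)
  # alone is injective
  expect_equal(anyDuplicated(tab[, c("aperture", "spread", "f1")]), 0L)
  expect_equal(anyDuplicated(tab[, c("aperture", "f1")]), 0L)
  # tones sit on the 25 Hz STFT bin grid
  expect_true(all(tab$f1 %% 25 == 0))
  expect_true(all(tab$f2 %% 25 == 0))
})

test_that("rendering produces the expected frame count and exact landmarks", {
  cfg <- synth_config()
  set.seed(1)
  rv <- render_video("hello", cfg)
  expect_equal(length(rv$frames), 5 * cfg$frames_per_char)
  expect_equal(length(rv$landmarks), length(rv$frames))
  # landmark invariants hold on every frame
  for (lm in rv$landmarks) {
    expect_gt(lm$right_corner[1], lm$left_corner[1])
    expect_gt(lm$lower_mid[2], lm$upper_mid[2])
  }
  expect_error(render_video("héllo!", cfg), "unencodable")
  set.seed(9); f1 <- render_video("ab", cfg)$frames
  set.seed(9); f2 <- render_video("ab", cfg)$frames
  expect_identical(f1, f2)
})

test_that("synthesized audio is frame-aligned, silent on spaces", {
  cfg <- synth_config()
  set.seed(3)
  w <- synth_audio("im hot", cfg)
  expect_equal(length(w$samples), 6 * cfg$frames_per_char * 640)
  expect_equal(w$rate, 16000L)
  expect_lte(max(abs(w$samples)), 1)
  # a space frame is near-silent relative to a voiced frame
  traj_space <- which(strsplit("im hot", "")[[1]] == " ")
  sp_idx <- ((traj_space - 1) * cfg$frames_per_char) * 640 + 1:640
  voiced_idx <- 1:640
  expect_lt(stats::sd(w$samples[sp_idx]), 0.05 * stats::sd(w$samples[voiced_idx]))
})

test_that("characters are separable in MFCC space well above the noise floor", {
  cfg <- synth_config()
  sc <- spectral_config(n_mfcc = 12)
  mf <- function(sentence, seed) {
    set.seed(seed)
    extract_features(synth_audio(sentence, cfg), sc)
  }
  # same character, different noise draws
  reps <- sapply(1:6, function(s) mf("aaaa", s)[2, ])
  noise_sd <- mean(apply(reps, 1, stats::sd))
  a_row <- rowMeans(reps)
  b_row <- rowMeans(sapply(1:6, function(s) mf("bbbb", s)[2, ]))
  sep <- sqrt(sum((a_row - b_row)^2))
  expect_gt(sep, 5 * max(noise_sd, 1e-12))
})

test_that("generated corpora respect mode grammar and reproduce under seed", {
  cfg <- synth_config(mode = "grid", n_videos = 12L, seed = 7L)
  corp <- generate_corpus(cfg)
  expect_equal(nrow(corp$manifest), 12L)
  slots <- vsr2stage:::grid_slots()
  for (s in corp$manifest$transcript) {
    words <- strsplit(s, " ")[[1]]
    expect_equal(length(words), 6L)
    for (j in seq_along(words)) expect_true(words[j] %in% slots[[j]])
  }
  # every clip fits the 75-frame budget with aligned audio
  for (smp in corp$samples) {
    expect_lte(length(smp$frames), 75L)
    expect_equal(length(smp$waveform$samples), length(smp$frames) * 640L)
  }
  corp2 <- generate_corpus(cfg)
  expect_identical(corp$manifest, corp2$manifest)
  expect_identical(corp$samples[[3]]$frames, corp2$samples[[3]]$frames)
})

test_that("icu mode draws from the phrase list and encodes cleanly", {
  corp <- generate_corpus(synth_config(n_videos = 15L, seed = 2L))
  expect_true(all(corp$manifest$transcript %in% vsr2stage:::icu_phrases()))
  for (tr in corp$manifest$transcript) {
    expect_identical(normalize_text(tr), tr)
  }
})

test_that("the on-disk fixture layout round-trips", {
  dir <- file.path(tempdir(), "fixture_rt")
  unlink(dir, recursive = TRUE)
  cfg <- synth_config(n_videos = 3L, seed = 4L)
  generate_corpus(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 3L)
  s <- read_sample_dir(file.path(dir, man$sample_dir[1]))
  expect_s3_class(s, "vsr_raw_sample")
  expect_equal(s$transcript, man$transcript[1])
  expect_equal(length(s$frames), length(s$landmarks))
  expect_equal(length(s$waveform$samples), length(s$frames) * 640L)
  # frames survive the 8-bit PNG round trip exactly (they are integers)
  mem <- generate_corpus(cfg)
  gray <- to_grayscale(mem$samples[[1]]$frames[[1]])
  expect_equal(s$frames[[1]], gray)
  # preprocessing the reloaded sample works end to end
  fr <- preprocess_video(s)
  expect_false(is_rejected(fr))
  expect_equal(dim(fr$tensor), c(75L, 50L, 100L, 1L))
})

test_that("generated data carry enough signal to drive CTC training to zero", {
  # learnability: the micro STT overfits ten generated samples (via their
  # ground-truth features) far below CTC loss 0.1, showing the frames and
  # audio encode the transcript; a high-rate phase then a low-rate phase
  fx <- tiny_corpus(10)
  f1 <- train_stt(fx$features, fx$labels,
                  build_stt(micro_stt_config(12), seed = 1),
                  training_config(lr = 1e-2, epochs = 250L, batch_size = 10L,
                                  seed = 1))
  f2 <- train_stt(fx$features, fx$labels, f1$model,
                  training_config(lr = 2e-3, epochs = 250L, batch_size = 10L,
                                  seed = 2))
  expect_lt(tail(f2$history$train_loss, 1), 0.1)
  # the overfit model transcribes its training sentences exactly
  out <- model_forward(f2$model, stack_batch_mat_test(fx$features))$out
  hyps <- vapply(seq_along(fx$labels), function(i) {
    greedy_decode(matrix(out[i, , ], 75, 29))
  }, character(1))
  expect_equal(hyps, normalize_text(fx$corpus$manifest$transcript))
})

test_that("wav files round-trip through the PCM writer/reader", {
  x <- sin(2 * pi * 440 * (0:6399) / 16000) * 0.7
  path <- tempfile(fileext = ".wav")
  write_wav(x, 16000L, path)
  back <- read_wav(path)
  expect_equal(back$rate, 16000L)
  expect_equal(length(back$samples), length(x))
  expect_lt(max(abs(back$samples - x)), 1 / 32000)
})
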