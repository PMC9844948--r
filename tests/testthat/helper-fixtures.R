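# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# small in-memory synthetic corpus with preprocessed frames and features
tiny_corpus <- function(n = 10L, seed = 5L, n_mfcc = 12L) {
  key <- sprintf("tiny_%d_%d_%d", n, seed, n_mfcc)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  corp <- generate_corpus(synth_config(n_videos = n, seed = seed))
  sc <- spectral_config(n_mfcc = n_mfcc)
  frames <- lapply(corp$samples, preprocess_video)
  feats <- lapply(corp$samples, function(s) {
    extract_features(normalize_waveform(s$waveform), sc, n_frames = 75L)
  })
  norm <- fit_normalizer(feats)
  out <- list(
    corpus = corp,
    spectral = sc,
    frames = frames,
    features = lapply(feats, apply_normalizer, norm = norm),
    raw_features = feats,
    normalizer = norm,
    labels = lapply(corp$manifest$transcript, encode_transcript)
  )
  .fixtures[[key]] <- out
  out
}

# random CharProbSequence with rows summing to one
random_probs <- function(T_, K, concentration = 1) {
  p <- matrix(stats::rexp(T_ * K)^concentration, T_, K)
  p / rowSums(p)
}

# deterministic checkerboard-ish test image
gradient_image <- function(H, W) {
  outer(seq_len(H), seq_len(W), function(i, j) (i * 7 + j * 13) %% 251)
}

expect_rel_equal <- function(a, b, tol = 1e-9) {
  expect_lt(abs(a - b) / max(abs(b), 1e-12), tol)
}

stack_batch_mat_test <- function(mats) {
  out <- array(0, c(length(mats), dim(mats[[1]])))
  for (i in seq_along(mats)) out[i, , ] <- mats[[i]]
  out
}
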