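# Training behavior on small synthetic sets. These are the slowest unit
# tests; sizes are chosen so each block stays in the tens of seconds.

test_that("the AFE overfits a tiny set and halves its training loss", {
  fx <- tiny_corpus(10)
  ds <- lapply(1:10, function(i) list(frames = fx$frames[[i]],
                                      features = fx$features[[i]]))
  afe <- build_afe(micro_afe_config(12), seed = 1)
  fit <- train_afe(ds, afe, training_config(lr = 3e-3, epochs = 200L,
                                            batch_size = 5L, seed = 1))
  h <- fit$history
  expect_equal(nrow(h), 200L)
  expect_lt(tail(h$train_loss, 1), 0.5 * h$train_loss[1])
  expect_error(train_afe(list(), afe, training_config()), "empty")
})

test_that("AFE training is reproducible under a fixed seed without augmentation", {
  fx <- tiny_corpus(10)
  ds <- lapply(1:6, function(i) list(frames = fx$frames[[i]],
                                     features = fx$features[[i]]))
  tc <- training_config(lr = 1e-3, epochs = 3L, batch_size = 3L, seed = 7L)
  f1 <- train_afe(ds, build_afe(micro_afe_config(12), seed = 2), tc)
  f2 <- train_afe(ds, build_afe(micro_afe_config(12), seed = 2), tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("validation loss is logged every epoch and drives early weights", {
  fx <- tiny_corpus(10)
  ds <- lapply(1:8, function(i) list(frames = fx$frames[[i]],
                                     features = fx$features[[i]]))
  vd <- lapply(9:10, function(i) list(frames = fx$frames[[i]],
                                      features = fx$features[[i]]))
  fit <- train_afe(ds, build_afe(micro_afe_config(12), seed = 1),
                   training_config(lr = 1e-3, epochs = 4L, seed = 1),
                   validation = vd)
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_equal(nrow(fit$history), 4L)
})

test_that("the STT overfits a tiny set and halves its CTC loss", {
  fx <- tiny_corpus(10)
  stt <- build_stt(micro_stt_config(12), seed = 1)
  fit <- train_stt(fx$features, fx$labels, stt,
                   training_config(lr = 1e-2, epochs = 50L, batch_size = 5L,
                                   seed = 1))
  h <- fit$history
  expect_lt(tail(h$train_loss, 1), 0.5 * h$train_loss[1])
  # training is deterministic under seed + fixed init
  fit2 <- train_stt(fx$features, fx$labels,
                    build_stt(micro_stt_config(12), seed = 1),
                    training_config(lr = 1e-2, epochs = 3L, batch_size = 5L,
                                    seed = 3))
  fit3 <- train_stt(fx$features, fx$labels,
                    build_stt(micro_stt_config(12), seed = 1),
                    training_config(lr = 1e-2, epochs = 3L, batch_size = 5L,
                                    seed = 3))
  expect_identical(fit2$model$params, fit3$model$params)
})

test_that("STT training rejects labels inadmissible for 75 frames", {
  fx <- tiny_corpus(10)
  bad <- c(fx$labels[1:2], list(rep(1L, 76L)))
  feats <- c(fx$features[1:2], fx$features[3])
  expect_error(train_stt(feats, bad, build_stt(micro_stt_config(12)),
                         training_config(epochs = 1L)),
               "sample 3")
})

test_that("STT loss is near zero on oracle one-hot probabilities", {
  ab <- build_alphabet()
  ids <- encode_transcript("im hot", ab)
  # lay the label out as a valid alignment padded with blanks
  path <- rep(ab$blank_index, 75)
  path[seq(2, by = 3, length.out = length(ids))] <- ids
  p <- matrix(1e-12, 75, 29)
  p[cbind(1:75, path)] <- 1
  p <- p / rowSums(p)
  expect_lt(ctc_loss(p, ids, ab$blank_index), 1e-6)
})

test_that("fine-tuning starts from the pretrained STT and freezes the AFE", {
  fx <- tiny_corpus(10)
  ds <- lapply(1:10, function(i) list(frames = fx$frames[[i]],
                                      features = fx$features[[i]]))
  afe <- train_afe(ds, build_afe(micro_afe_config(12), seed = 1),
                   training_config(lr = 3e-3, epochs = 3L, seed = 1))$model
  stt0 <- train_stt(fx$features, fx$labels,
                    build_stt(micro_stt_config(12), seed = 1),
                    training_config(lr = 1e-2, epochs = 3L, seed = 1))$model
  vids <- lapply(1:10, function(i) list(frames = fx$frames[[i]],
                                        label = fx$labels[[i]]))
  afe_before <- afe$params
  ft <- finetune_stt(stt0, afe, vids, training_config(lr = 1e-3, epochs = 2L,
                                                      seed = 1))
  expect_identical(afe$params, afe_before)       # frozen first stage
  expect_false(identical(ft$model$params, stt0$params))
  expect_equal(nrow(ft$history), 2L)
})

test_that("predict_text composes the stages and is lm-word-local", {
  fx <- tiny_corpus(10)
  afe <- build_afe(micro_afe_config(12), seed = 1)
  stt <- build_stt(micro_stt_config(12), seed = 1)
  out <- predict_text(afe, stt, fx$frames[[1]], dump = TRUE)
  expect_equal(dim(out$features), c(75L, 12L))
  expect_equal(dim(out$char_probs), c(75L, 29L))
  expect_type(out$text, "character")
  # deterministic given fixed weights
  expect_identical(predict_text(afe, stt, fx$frames[[1]]),
                   predict_text(afe, stt, fx$frames[[1]]))
  # LM correction can only substitute word-by-word: word count is preserved
  corp <- fit_corpus(fx$corpus$manifest$transcript)
  raw <- predict_text(afe, stt, fx$frames[[1]])
  fixed <- predict_text(afe, stt, fx$frames[[1]], lm = corp)
  if (nzchar(raw)) {
    expect_equal(length(strsplit(fixed, " ")[[1]]),
                 length(strsplit(raw, " ")[[1]]))
  }
})
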