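# Orchestration: dataset splitting, the three training phases, the 2x2
# evaluation grid (fine-tuning x language model) and single-video
# prediction.

#' Train/validation/test split specification
#'
#' @param train,val,test fractions summing to 1 (default 0.8/0.1/0.1).
#' @param seed shuffle seed; the same seed is used throughout a run so all
#'   phases see the same training samples and the test set stays unseen
#'   until final evaluation.
#' @return a `vsr_split_spec`.
#' @export
split_spec <- function(train = 0.8, val = 0.1, test = 0.1, seed = 1L) {
  stopifnot(abs(train + val + test - 1) < 1e-9)
  structure(list(train = train, val = val, test = test, seed = as.integer(seed)),
            class = "vsr_split_spec")
}

#' Split a manifest into train/validation/test
#'
#' Seeded shuffle followed by partition: validation and test each receive
#' `floor(val * n)` / `floor(test * n)` samples, the remainder trains.
#'
#' @param manifest data.frame of samples (one row per video).
#' @param spec a [split_spec()].
#' @return list of three manifests `train`, `val`, `test` (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(manifest, spec = split_spec()) {
  n <- nrow(manifest)
  if (n < 10L) stop("too few samples to split: ", n)
  set.seed(spec$seed)
  ord <- sample.int(n)
  n_val <- floor(spec$val * n)
  n_test <- floor(spec$test * n)
  idx_val <- ord[seq_len(n_val)]
  idx_test <- ord[n_val + seq_len(n_test)]
  idx_train <- ord[-seq_len(n_val + n_test)]
  list(train = manifest[idx_train, , drop = FALSE],
       val = manifest[idx_val, , drop = FALSE],
       test = manifest[idx_test, , drop = FALSE])
}

#' Full run configuration
#'
#' Bundles every stage's configuration. The defaults describe a desk-scale
#' run: micro model configs, 12 MFCCs, augmentation on, fine-tuning on,
#' language model on.
#'
#' @param spectral a [spectral_config()].
#' @param afe an [afe_config()].
#' @param stt an [stt_config()].
#' @param tc_afe,tc_stt,tc_ft [training_config()]s for the three phases.
#' @param augmenter an [augmenter_config()] or `NULL` (off).
#' @param split a [split_spec()].
#' @param lm fit and apply the unigram spell corrector.
#' @param finetune run phase 3 (STT fine-tuning on AFE predictions).
#' @param whole_dataset_normalizer fit the feature normalizer on the whole
#'   dataset instead of the training split only.
#' @param decoder `"greedy"` or `"beam"`.
#' @param seed master seed; stage seeds derive from it.
#' @return a `vsr_run_config`.
#' @export
run_config <- function(spectral = spectral_config(n_mfcc = 12L),
                       afe = micro_afe_config(d_af = 12L),
                       stt = micro_stt_config(d_af = 12L),
                       tc_afe = training_config(lr = 3e-3, epochs = 38L,
                                                batch_size = 4L),
                       tc_stt = training_config(lr = 1e-2, epochs = 25L),
                       tc_ft = training_config(lr = 3e-3, epochs = 35L),
                       augmenter = augmenter_config(),
                       split = split_spec(),
                       lm = TRUE, finetune = TRUE,
                       whole_dataset_normalizer = FALSE,
                       decoder = "greedy", seed = 1L) {
  stopifnot(afe$d_af == spectral$d_af, stt$d_af == spectral$d_af)
  cfg <- structure(
    list(spectral = spectral, afe = afe, stt = stt, tc_afe = tc_afe,
         tc_stt = tc_stt, tc_ft = tc_ft, augmenter = augmenter,
         split = split, lm = lm, finetune = finetune,
         whole_dataset_normalizer = whole_dataset_normalizer,
         decoder = decoder, seed = as.integer(seed)),
    class = "vsr_run_config"
  )
  cfg$hash <- config_hash(cfg)
  cfg
}

# FNV-1a over the JSON serialization; recorded in run outputs so results
# can be tied to the exact configuration
config_hash <- function(cfg) {
  x <- cfg
  x$hash <- NULL
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(x), auto_unbox = TRUE,
                                      digits = NA, force = TRUE))
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777.0) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# one-at-a-time sample access so disk-backed corpora never hold all raw
# frames in memory
corpus_provider <- function(corpus) {
  if (!is.null(corpus$samples)) {
    function(i) corpus$samples[[i]]
  } else if (is.null(corpus$dir) && !is.null(corpus$config)) {
    # streaming corpus: regenerate sample i from its per-sample seed
    cfg <- corpus$config
    man <- corpus$manifest
    function(i) {
      set.seed(sample_seed(cfg$seed, i))
      generate_sample(man$transcript[i], cfg, speaker_id = man$speaker_id[i])
    }
  } else if (!is.null(corpus$dir)) {
    man <- corpus$manifest
    function(i) read_sample_dir(file.path(corpus$dir, man$sample_dir[i]),
                                speaker_id = man$speaker_id[i],
                                view_tag = man$view_tag[i])
  } else {
    stop("corpus has neither samples nor a directory")
  }
}

phase <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("phase '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full training pipeline
#'
#' Phases: (0) preprocess every video and extract frame-aligned audio
#' features; split 80/10/10; fit the per-coefficient feature normalizer on
#' the training split (or the whole dataset with
#' `whole_dataset_normalizer`); (1) train the AFE on frame/feature pairs;
#' (2) train the STT on ground-truth features; (3) optionally fine-tune
#' the STT on the frozen AFE's predictions; finally fit the unigram
#' corpus. Test samples are never touched before [evaluate_artifacts()].
#'
#' @param corpus a `vsr_corpus_data` (from [generate_corpus()] or
#'   [load_corpus()]) or a corpus directory path.
#' @param run a [run_config()].
#' @param verbose print per-epoch losses.
#' @return a `vsr_artifacts` list: models, normalizer, corpus LM, split
#'   manifests, per-sample frames/features/labels, histories and the
#'   config (with hash).
#' @export
run_training <- function(corpus, run = run_config(), verbose = FALSE) {
  if (is.character(corpus)) {
    dir <- corpus
    corpus <- structure(
      list(samples = NULL,
           manifest = utils::read.csv(file.path(dir, "manifest.csv"),
                                      colClasses = "character"),
           config = NULL, dir = dir),
      class = "vsr_corpus_data")
  }
  get_sample <- corpus_provider(corpus)
  manifest <- corpus$manifest
  manifest$row_id <- seq_len(nrow(manifest))
  alphabet <- build_alphabet()

  prep <- phase("preprocess", {
    n <- nrow(manifest)
    frames <- vector("list", n)
    feats <- vector("list", n)
    labels <- vector("list", n)
    rejected <- logical(n)
    for (i in seq_len(n)) {
      s <- get_sample(i)
      fr <- preprocess_video(s)
      if (is_rejected(fr)) {
        rejected[i] <- TRUE
        next
      }
      frames[[i]] <- fr
      feats[[i]] <- extract_features(normalize_waveform(s$waveform),
                                     run$spectral, n_frames = 75L)
      labels[[i]] <- encode_transcript(s$transcript, alphabet)
    }
    if (any(rejected)) {
      manifest <- manifest[!rejected, , drop = FALSE]
      frames <- frames[!rejected]
      feats <- feats[!rejected]
      labels <- labels[!rejected]
    }
    list(frames = frames, feats = feats, labels = labels)
  })

  splits <- phase("split", split_dataset(manifest, run$split))
  id_train <- splits$train$row_id
  id_val <- splits$val$row_id

  norm <- phase("normalizer", {
    fit_on <- if (run$whole_dataset_normalizer) seq_along(prep$feats) else
      match(id_train, manifest$row_id)
    fit_normalizer(prep$feats[fit_on])
  })
  nfeats <- lapply(prep$feats, apply_normalizer, norm = norm)

  tr <- match(id_train, manifest$row_id)
  va <- match(id_val, manifest$row_id)

  afe_fit <- phase("train_afe", {
    ds <- lapply(tr, function(i) list(frames = prep$frames[[i]],
                                      features = nfeats[[i]]))
    vd <- lapply(va, function(i) list(frames = prep$frames[[i]],
                                      features = nfeats[[i]]))
    train_afe(ds, build_afe(run$afe, seed = run$seed), run$tc_afe,
              augmenter = run$augmenter,
              validation = if (length(vd)) vd else NULL, verbose = verbose)
  })

  stt_fit <- phase("train_stt", {
    train_stt(nfeats[tr], prep$labels[tr],
              build_stt(run$stt, seed = run$seed), run$tc_stt,
              validation = if (length(va)) list(features = nfeats[va],
                                                labels = prep$labels[va]) else NULL,
              verbose = verbose)
  })

  stt_ft <- NULL; ft_history <- NULL
  if (run$finetune) {
    ft <- phase("finetune_stt", {
      ds <- lapply(tr, function(i) list(frames = prep$frames[[i]],
                                        label = prep$labels[[i]]))
      # validate on the AFE's (un-augmented) predictions: that is the input
      # distribution the fine-tuned STT sees at runtime
      val <- NULL
      if (length(va)) {
        val <- list(features = afe_predict(afe_fit$model, prep$frames[va]),
                    labels = prep$labels[va])
      }
      finetune_stt(stt_fit$model, afe_fit$model, ds, run$tc_ft,
                   augmenter = run$augmenter, validation = val,
                   verbose = verbose)
    })
    stt_ft <- ft$model
    ft_history <- ft$history
  }

  lm <- if (run$lm) phase("language_model", fit_corpus(manifest$transcript)) else NULL

  structure(
    list(afe = afe_fit$model, stt = stt_fit$model, stt_ft = stt_ft,
         normalizer = norm, lm = lm, splits = splits, manifest = manifest,
         frames = prep$frames, features = nfeats, labels = prep$labels,
         history = list(afe = afe_fit$history, stt = stt_fit$history,
                        finetune = ft_history),
         config = run, alphabet = alphabet),
    class = "vsr_artifacts"
  )
}

#' @export
print.vsr_artifacts <- function(x, ...) {
  cat(sprintf(
    "<vsr_artifacts> config %s: AFE + STT%s, %d train / %d val / %d test\n",
    x$config$hash, if (!is.null(x$stt_ft)) " (+fine-tuned)" else "",
    nrow(x$splits$train), nrow(x$splits$val), nrow(x$splits$test)))
  invisible(x)
}

decode_split <- function(artifacts, stt_model, idx, lm) {
  afe <- artifacts$afe
  hyps <- character(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    hyps[j] <- predict_text(afe, stt_model, artifacts$frames[[i]],
                            decoder = artifacts$config$decoder, lm = lm,
                            alphabet = artifacts$alphabet)
  }
  hyps
}

#' Evaluate trained artifacts on a split
#'
#' Computes CER/WER over the 2x2 grid of fine-tuning (when a fine-tuned
#' STT exists) and language-model correction. Side-effect free: model
#' weights are only read.
#'
#' @param artifacts a `vsr_artifacts` from [run_training()].
#' @param split `"test"` (default), `"val"` or `"train"`.
#' @return list with `grid` (data.frame: finetuned, lm, cer, wer as
#'   percentages) and `predictions` (per-sample data.frame).
#' @export
evaluate_artifacts <- function(artifacts, split = c("test", "val", "train")) {
  split <- match.arg(split)
  man <- artifacts$splits[[split]]
  idx <- match(man$row_id, artifacts$manifest$row_id)
  refs <- normalize_text(man$transcript)
  models <- list(`TRUE` = artifacts$stt_ft, `FALSE` = artifacts$stt)
  grid <- NULL
  preds <- NULL
  for (ft in c(TRUE, FALSE)) {
    stt_model <- models[[as.character(ft)]]
    if (is.null(stt_model)) next
    for (lm_on in c(TRUE, FALSE)) {
      lm <- if (lm_on) artifacts$lm else NULL
      hyps <- decode_split(artifacts, stt_model, idx, lm)
      c_rep <- cer(refs, hyps)
      w_rep <- wer(refs, hyps)
      grid <- rbind(grid, data.frame(
        finetuned = ft, lm = lm_on,
        cer = 100 * c_rep$rate, wer = 100 * w_rep$rate))
      preds <- rbind(preds, data.frame(
        finetuned = ft, lm = lm_on, reference = refs, hypothesis = hyps,
        stringsAsFactors = FALSE))
    }
  }
  list(grid = grid, predictions = preds)
}

#' Write an evaluation report
#'
#' Per-sample predictions as CSV plus a JSON summary of the CER/WER grid.
#'
#' @param evaluation result of [evaluate_artifacts()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(evaluation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(evaluation$predictions,
                   file.path(dir, "predictions.csv"), row.names = FALSE)
  jsonlite::write_json(evaluation$grid, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Predict the transcript of one video
#'
#' Preprocesses the sample (or sample directory), runs the two-stage model
#' and decodes; rejected preprocessing yields an explicit
#' "face/landmarks unavailable" result rather than an error.
#'
#' @param artifacts a `vsr_artifacts`.
#' @param video a `vsr_raw_sample` or a sample directory path.
#' @param use_finetuned use the fine-tuned STT when available.
#' @param lm_on apply the spell corrector.
#' @param dump also return predicted features and character probabilities.
#' @return decoded text (or a list when `dump = TRUE`); `NA_character_`
#'   with attribute `reason` when preprocessing rejects the video.
#' @export
predict_video <- function(artifacts, video, use_finetuned = TRUE,
                          lm_on = TRUE, dump = FALSE) {
  if (is.character(video)) video <- read_sample_dir(video)
  fr <- preprocess_video(video)
  if (is_rejected(fr)) {
    out <- NA_character_
    attr(out, "reason") <- paste("face/landmarks unavailable:", fr$reason)
    return(out)
  }
  stt_model <- if (use_finetuned && !is.null(artifacts$stt_ft)) artifacts$stt_ft
               else artifacts$stt
  predict_text(artifacts$afe, stt_model, fr,
               decoder = artifacts$config$decoder,
               lm = if (lm_on) artifacts$lm else NULL,
               alphabet = artifacts$alphabet, dump = dump)
}
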