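# Training loops for the two stages and the combined predictor.
#
# Datasets are plain lists: AFE training consumes pairs of preprocessed
# frames and normalized ground-truth audio features; STT training consumes
# normalized feature matrices plus encoded labels; fine-tuning consumes
# frames plus labels and routes them through the frozen AFE.

frames_tensor <- function(x) {
  if (inherits(x, "vsr_frames")) x$tensor else x
}

stack_batch <- function(tensors) {
  stack_arrays_cpp(lapply(tensors, frames_tensor))
}

stack_batch_mat <- function(mats) {
  stack_arrays_cpp(mats)
}

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

maybe_augment <- function(tensor, augmenter) {
  if (is.null(augmenter)) return(tensor)
  params <- sample_params(augmenter)
  apply_augmentation(tensor, params)
}

#' Train the Audio Feature Estimator
#'
#' Minimizes the mean-absolute-error between predicted and ground-truth
#' normalized audio features with Adam. When an augmenter configuration is
#' given, each training video is augmented with per-video parameters every
#' epoch; validation data is never augmented. With a validation set, early
#' stopping (patience from the training config) restores the best weights.
#'
#' @param dataset list of `list(frames = vsr_frames, features = 75 x d_af
#'   matrix)` pairs.
#' @param afe a `vsr_model` from [build_afe()].
#' @param tc a [training_config()] (AFE default learning rate 1e-4).
#' @param augmenter optional [augmenter_config()].
#' @param validation optional dataset of the same structure.
#' @param verbose print per-epoch losses.
#' @return list with `model` and `history` (data.frame epoch/train/val loss).
#' @export
train_afe <- function(dataset, afe, tc = training_config(lr = 1e-4),
                      augmenter = NULL, validation = NULL, verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty dataset")
  set.seed(tc$seed)
  params <- afe$params
  state <- adam_init(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  gt <- lapply(dataset, function(s) s$features)
  tensors <- lapply(dataset, function(s) s$frames)
  best_val <- Inf; best_params <- params; wait <- 0L
  for (ep in seq_len(tc$epochs)) {
    ord <- sample.int(length(dataset))
    ep_loss <- 0; n_b <- 0L
    for (idx in batch_indices(length(ord), tc$batch_size)) {
      ids <- ord[idx]
      xb <- stack_batch(lapply(tensors[ids], maybe_augment, augmenter = augmenter))
      yb <- stack_batch_mat(gt[ids])
      afe$params <- params
      fw <- model_forward(afe, xb, keep_caches = TRUE)
      diff <- fw$out - yb
      ep_loss <- ep_loss + mean(abs(diff)); n_b <- n_b + 1L
      dout <- sign(diff) / length(diff)
      bw <- model_backward(afe, fw$caches, dout)
      upd <- adam_step(params, bw$grads, state, tc$lr, tc$beta1, tc$beta2, tc$eps)
      params <- upd$params; state <- upd$state
    }
    afe$params <- params
    val_loss <- NA_real_
    if (!is.null(validation)) {
      vx <- stack_batch(lapply(validation, function(s) frames_tensor(s$frames)))
      vy <- stack_batch_mat(lapply(validation, function(s) s$features))
      val_loss <- afe_loss(model_forward(afe, vx)$out, vy)
      if (val_loss < best_val) {
        best_val <- val_loss; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / n_b,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("AFE epoch %d: train %.5f val %s", ep, ep_loss / n_b,
                      format(val_loss, digits = 5)))
    }
    if (!is.null(validation) && wait >= tc$patience) break
  }
  if (!is.null(validation)) afe$params <- best_params
  list(model = afe, history = history)
}

ctc_batch_grad <- function(probs_batch, labels, blank_index) {
  n <- dim(probs_batch)[1]
  dout <- array(0, dim(probs_batch))
  loss <- 0
  for (i in seq_len(n)) {
    pi_ <- matrix(probs_batch[i, , ], dim(probs_batch)[2], dim(probs_batch)[3])
    g <- ctc_loss_grad(pi_, labels[[i]], blank_index)
    loss <- loss + g$loss
    dout[i, , ] <- g$grad / n
  }
  list(loss = loss / n, dout = dout)
}

#' Train the Speech-To-Text network on ground-truth features
#'
#' Minimizes the batch-averaged CTC negative log likelihood of each
#' transcript given the (normalized, ground-truth) audio features, with
#' Adam. Labels inadmissible for 75 CTC frames raise a per-sample error up
#' front.
#'
#' @param features list of `75 x d_af` normalized feature matrices.
#' @param labels list of encoded transcripts ([encode_transcript()]).
#' @param stt a `vsr_model` from [build_stt()].
#' @param tc a [training_config()] (STT default learning rate 5e-4).
#' @param validation optional `list(features = , labels = )`.
#' @param verbose print per-epoch losses.
#' @return list with `model` and `history`.
#' @export
train_stt <- function(features, labels, stt, tc = training_config(lr = 5e-4),
                      validation = NULL, verbose = FALSE) {
  if (length(features) == 0L) stop("empty dataset")
  stopifnot(length(features) == length(labels))
  blank <- build_alphabet()$blank_index
  for (i in seq_along(labels)) {
    tryCatch(check_ctc_label(labels[[i]], nrow(features[[i]]), blank),
             error = function(e) stop("sample ", i, ": ", conditionMessage(e)))
  }
  set.seed(tc$seed)
  params <- stt$params
  state <- adam_init(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf; best_params <- params; wait <- 0L
  for (ep in seq_len(tc$epochs)) {
    ord <- sample.int(length(features))
    ep_loss <- 0; n_b <- 0L
    for (idx in batch_indices(length(ord), tc$batch_size)) {
      ids <- ord[idx]
      xb <- stack_batch_mat(features[ids])
      stt$params <- params
      fw <- model_forward(stt, xb, keep_caches = TRUE)
      g <- ctc_batch_grad(fw$out, labels[ids], blank)
      ep_loss <- ep_loss + g$loss; n_b <- n_b + 1L
      bw <- model_backward(stt, fw$caches, g$dout, dout_pre_activation = TRUE)
      upd <- adam_step(params, bw$grads, state, tc$lr, tc$beta1, tc$beta2, tc$eps)
      params <- upd$params; state <- upd$state
    }
    stt$params <- params
    val_loss <- NA_real_
    if (!is.null(validation)) {
      vx <- stack_batch_mat(validation$features)
      vout <- model_forward(stt, vx)$out
      vl <- 0
      for (i in seq_along(validation$labels)) {
        vl <- vl + ctc_loss(matrix(vout[i, , ], dim(vout)[2], dim(vout)[3]),
                            validation$labels[[i]], blank)
      }
      val_loss <- vl / length(validation$labels)
      if (val_loss < best_val) {
        best_val <- val_loss; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / n_b,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("STT epoch %d: train %.5f val %s", ep, ep_loss / n_b,
                      format(val_loss, digits = 5)))
    }
    if (!is.null(validation) && wait >= tc$patience) break
  }
  if (!is.null(validation)) stt$params <- best_params
  list(model = stt, history = history)
}

#' Predict audio features for a list of preprocessed videos
#'
#' @param afe trained AFE model.
#' @param frames_list list of `vsr_frames` (or tensors).
#' @param batch_size forward batch size.
#' @return list of `75 x d_af` matrices.
#' @export
afe_predict <- function(afe, frames_list, batch_size = 16L) {
  out <- vector("list", length(frames_list))
  for (idx in batch_indices(length(frames_list), batch_size)) {
    xb <- stack_batch(lapply(frames_list[idx], frames_tensor))
    yb <- model_forward(afe, xb)$out
    for (j in seq_along(idx)) {
      out[[idx[j]]] <- matrix(yb[j, , ], dim(yb)[2], dim(yb)[3])
    }
  }
  out
}

#' Fine-tune the STT on AFE predictions
#'
#' Continues STT training (starting from the pretrained weights) on the
#' frozen AFE's predicted features instead of the ground-truth features, so
#' the STT adapts to the estimator's runtime errors. When an augmenter is
#' given, the AFE input frames are augmented each epoch (so predictions are
#' recomputed through the frozen AFE); the AFE weights are never updated.
#'
#' @param stt pretrained STT model.
#' @param afe trained AFE model (frozen).
#' @param video_dataset list of `list(frames = vsr_frames, label = ids)`.
#' @param tc a [training_config()].
#' @param augmenter optional [augmenter_config()].
#' @param validation optional `list(features = , labels = )` (ground-truth or
#'   predicted features of held-out videos).
#' @param verbose print per-epoch losses.
#' @return list with `model` (fine-tuned STT) and `history`.
#' @export
finetune_stt <- function(stt, afe, video_dataset, tc = training_config(lr = 5e-4),
                         augmenter = NULL, validation = NULL, verbose = FALSE) {
  if (length(video_dataset) == 0L) stop("empty dataset")
  blank <- build_alphabet()$blank_index
  set.seed(tc$seed + 1L)
  params <- stt$params
  state <- adam_init(params)
  tensors <- lapply(video_dataset, function(s) s$frames)
  labels <- lapply(video_dataset, function(s) s$label)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf; best_params <- params; wait <- 0L
  for (ep in seq_len(tc$epochs)) {
    ord <- sample.int(length(tensors))
    ep_loss <- 0; n_b <- 0L
    for (idx in batch_indices(length(ord), tc$batch_size)) {
      ids <- ord[idx]
      xb <- stack_batch(lapply(tensors[ids], maybe_augment, augmenter = augmenter))
      feats <- model_forward(afe, xb)$out  # frozen first stage
      stt$params <- params
      fw <- model_forward(stt, feats, keep_caches = TRUE)
      g <- ctc_batch_grad(fw$out, labels[ids], blank)
      ep_loss <- ep_loss + g$loss; n_b <- n_b + 1L
      bw <- model_backward(stt, fw$caches, g$dout, dout_pre_activation = TRUE)
      upd <- adam_step(params, bw$grads, state, tc$lr, tc$beta1, tc$beta2, tc$eps)
      params <- upd$params; state <- upd$state
    }
    stt$params <- params
    val_loss <- NA_real_
    if (!is.null(validation)) {
      vx <- stack_batch_mat(validation$features)
      vout <- model_forward(stt, vx)$out
      vl <- 0
      for (i in seq_along(validation$labels)) {
        vl <- vl + ctc_loss(matrix(vout[i, , ], dim(vout)[2], dim(vout)[3]),
                            validation$labels[[i]], blank)
      }
      val_loss <- vl / length(validation$labels)
      if (val_loss < best_val) {
        best_val <- val_loss; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / n_b,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("finetune epoch %d: train %.5f val %s", ep,
                      ep_loss / n_b, format(val_loss, digits = 5)))
    }
    if (!is.null(validation) && wait >= tc$patience) break
  }
  if (!is.null(validation)) stt$params <- best_params
  list(model = stt, history = history)
}

#' End-to-end text prediction for one video
#'
#' Frames through the AFE, predicted features through the STT, CTC
#' decoding, optional unigram spell correction. A pure function of the
#' inputs and the trained weights.
#'
#' @param afe,stt trained models.
#' @param frames a `vsr_frames` (or `(75, 50, 100, 1)` tensor).
#' @param decoder `"greedy"` or `"beam"`.
#' @param lm optional `vsr_corpus` for spell correction.
#' @param beam_width beam width when `decoder = "beam"`.
#' @param alphabet a [build_alphabet()].
#' @param dump if `TRUE`, also return predicted features and the character
#'   probability sequence.
#' @return decoded text, or a list when `dump = TRUE`.
#' @export
predict_text <- function(afe, stt, frames, decoder = c("greedy", "beam"),
                         lm = NULL, beam_width = 8L,
                         alphabet = build_alphabet(), dump = FALSE) {
  decoder <- match.arg(decoder)
  x <- frames_tensor(frames)
  xb <- array(x, c(1L, dim(x)))
  feats <- model_forward(afe, xb)$out
  probs_arr <- model_forward(stt, feats)$out
  probs <- matrix(probs_arr[1, , ], dim(probs_arr)[2], dim(probs_arr)[3])
  text <- if (decoder == "greedy") greedy_decode(probs, alphabet)
          else beam_decode(probs, alphabet, beam_width)
  if (!is.null(lm)) text <- correct_sentence(text, lm)
  if (dump) {
    list(text = text,
         features = matrix(feats[1, , ], dim(feats)[2], dim(feats)[3]),
         char_probs = probs)
  } else {
    text
  }
}

#' Save / load a model checkpoint
#'
#' Parameters as raw little-endian doubles with a JSON sidecar recording
#' the layer specification, shapes and seed.
#'
#' @param model a `vsr_model`.
#' @param path output path (sidecar at `<path>.json`).
#' @return `path` invisibly; `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  con <- file(path, "wb")
  for (nm in names(model$params)) {
    writeBin(as.numeric(model$params[[nm]]), con, size = 8, endian = "little")
  }
  close(con)
  meta <- list(
    layers = model$layers,
    input_shape = model$input_shape,
    seed = model$seed,
    kind = model$kind,
    param_shapes = lapply(model$params, function(p) dim(p) %||% length(p))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  layers <- lapply(meta$layers, function(ly) {
    lapply(ly, function(v) if (is.list(v)) unlist(v) else v)
  })
  model <- init_model(layers, unlist(meta$input_shape), seed = meta$seed %||% 1L)
  con <- file(path, "rb")
  for (nm in names(model$params)) {
    shp <- unlist(meta$param_shapes[[nm]])
    vals <- readBin(con, "double", n = prod(shp), size = 8, endian = "little")
    model$params[[nm]] <- array(vals, dim = shp)
  }
  close(con)
  model$kind <- meta$kind
  model
}
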