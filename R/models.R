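# Model configurations and constructors for the two stages.
#
# The architecture family follows the two-stage design: the Audio Feature
# Estimator (AFE) is a stack of spatio-temporal (3D) convolution blocks
# (each followed by ReLU and optional spatial max pooling) feeding GRU
# layers and a linear per-timestep output of d_AF audio features; the
# Speech-To-Text (STT) network is two 1D-convolution layers followed by
# GRU layers and a 29-way softmax per timestep. Exact filter counts and
# GRU widths are configuration, not code: the full-scale defaults below
# describe a plausible full-scale system, and the "micro" configs are
# small enough to train on a single CPU in seconds-to-minutes while
# exercising every layer type.

#' Audio Feature Estimator configuration
#'
#' @param d_af output feature dimension per timestep (e.g. 24 MFCCs or 40
#'   Mel bands).
#' @param conv list of conv blocks, each
#'   `list(filters, kernel = c(t,h,w), stride = c(1,h,w), pool = c(h,w) | NULL)`.
#' @param gru_units integer vector of GRU widths (stacked).
#' @param bidirectional use bidirectional GRUs.
#' @param front_pool optional spatial average-pool window applied before
#'   the conv stack (used by the micro config to cut compute).
#' @param input_shape per-sample input shape (75 frames, 50 x 100, 1 channel).
#' @return a `vsr_afe_config`.
#' @export
afe_config <- function(d_af = 24L,
                       conv = list(
                         list(filters = 32L, kernel = c(3L, 5L, 5L),
                              stride = c(1L, 2L, 2L), pool = c(2L, 2L)),
                         list(filters = 64L, kernel = c(3L, 5L, 5L),
                              stride = c(1L, 1L, 1L), pool = c(2L, 2L)),
                         list(filters = 96L, kernel = c(3L, 3L, 3L),
                              stride = c(1L, 1L, 1L), pool = c(2L, 2L))
                       ),
                       gru_units = c(256L, 256L),
                       bidirectional = FALSE,
                       front_pool = NULL,
                       input_shape = c(75L, 50L, 100L, 1L)) {
  structure(
    list(d_af = as.integer(d_af), conv = conv, gru_units = gru_units,
         bidirectional = bidirectional, front_pool = front_pool,
         input_shape = input_shape),
    class = "vsr_afe_config"
  )
}

#' Desk-scale AFE configuration (~10k parameters)
#'
#' One strided conv3d block plus a narrow GRU; trains on CPU.
#'
#' @inheritParams afe_config
#' @export
micro_afe_config <- function(d_af = 12L) {
  afe_config(
    d_af = d_af,
    conv = list(list(filters = 8L, kernel = c(3L, 5L, 5L),
                     stride = c(1L, 5L, 5L), pool = NULL)),
    gru_units = 32L,
    front_pool = c(2L, 2L)
  )
}

#' Build the Audio Feature Estimator network
#'
#' @param cfg an [afe_config()].
#' @param seed weight initialization seed.
#' @return a `vsr_model` mapping `(N, 75, 50, 100, 1)` to `(N, 75, d_af)`.
#' @export
build_afe <- function(cfg = afe_config(), seed = 1L) {
  layers <- list()
  if (!is.null(cfg$front_pool)) {
    layers <- c(layers, list(list(type = "avgpool", pool = cfg$front_pool)))
  }
  for (blk in cfg$conv) {
    layers <- c(layers, list(list(type = "conv3d", filters = blk$filters,
                                  kernel = blk$kernel, stride = blk$stride)))
    if (!is.null(blk$pool)) {
      layers <- c(layers, list(list(type = "maxpool", pool = blk$pool)))
    }
  }
  layers <- c(layers, list(list(type = "flatten")))
  for (u in cfg$gru_units) {
    layers <- c(layers, list(list(type = "gru", units = u,
                                  bidirectional = cfg$bidirectional)))
  }
  layers <- c(layers, list(list(type = "dense", units = cfg$d_af,
                                activation = "linear")))
  m <- init_model(layers, cfg$input_shape, seed = seed)
  if (m$output_shape[1] != cfg$input_shape[1]) {
    stop("config error: temporal axis not preserved")
  }
  m$kind <- "afe"
  m
}

#' Speech-To-Text network configuration
#'
#' @param d_af input feature dimension per timestep.
#' @param conv list of `list(filters, kernel)` 1D-conv specs (two layers).
#' @param gru_units integer vector of GRU widths.
#' @param bidirectional use bidirectional GRUs.
#' @param n_symbols alphabet size (29).
#' @param n_frames sequence length (75).
#' @return a `vsr_stt_config`.
#' @export
stt_config <- function(d_af = 24L,
                       conv = list(list(filters = 128L, kernel = 5L),
                                   list(filters = 256L, kernel = 5L)),
                       gru_units = c(256L, 256L),
                       bidirectional = FALSE,
                       n_symbols = 29L, n_frames = 75L) {
  structure(
    list(d_af = as.integer(d_af), conv = conv, gru_units = gru_units,
         bidirectional = bidirectional, n_symbols = as.integer(n_symbols),
         n_frames = as.integer(n_frames)),
    class = "vsr_stt_config"
  )
}

#' Desk-scale STT configuration
#' @inheritParams stt_config
#' @export
micro_stt_config <- function(d_af = 12L) {
  stt_config(
    d_af = d_af,
    conv = list(list(filters = 24L, kernel = 5L),
                list(filters = 24L, kernel = 3L)),
    gru_units = 32L,
    bidirectional = TRUE
  )
}

#' Build the Speech-To-Text network
#'
#' @param cfg an [stt_config()].
#' @param seed weight initialization seed.
#' @return a `vsr_model` mapping `(N, 75, d_af)` to `(N, 75, 29)` row
#'   probability distributions.
#' @export
build_stt <- function(cfg = stt_config(), seed = 1L) {
  layers <- list()
  for (blk in cfg$conv) {
    layers <- c(layers, list(list(type = "conv1d", filters = blk$filters,
                                  kernel = blk$kernel)))
  }
  for (u in cfg$gru_units) {
    layers <- c(layers, list(list(type = "gru", units = u,
                                  bidirectional = cfg$bidirectional)))
  }
  layers <- c(layers, list(list(type = "dense", units = cfg$n_symbols,
                                activation = "softmax")))
  m <- init_model(layers, c(cfg$n_frames, cfg$d_af), seed = seed)
  if (m$output_shape[2] != 29L) stop("config error: STT output width must be 29")
  m$kind <- "stt"
  m
}

#' Mean absolute error between predicted and ground-truth audio features
#'
#' Batch average of the mean absolute elementwise difference, the AFE
#' training objective.
#'
#' @param pred,gt arrays of identical shape (`(N, 75, d_af)` or a single
#'   `(75, d_af)` matrix).
#' @return scalar loss.
#' @export
afe_loss <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("shape mismatch in afe_loss")
  mean(abs(pred - gt))
}

#' Training hyperparameters
#'
#' Adam moments and stabilizer use the standard settings
#' (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-7`); default learning rates
#' are 1e-4 for the AFE and 5e-4 for the STT.
#'
#' @param lr learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param beta1,beta2,eps Adam settings.
#' @param patience early-stopping patience (epochs without validation
#'   improvement) when a validation set is supplied.
#' @param seed RNG seed for shuffling/augmentation; recorded in history.
#' @return a `vsr_training_config`.
#' @export
training_config <- function(lr = 1e-4, epochs = 30L, batch_size = 8L,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-7,
                            patience = 20L, seed = 1L) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1)
  structure(
    list(lr = lr, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), beta1 = beta1, beta2 = beta2,
         eps = eps, patience = as.integer(patience), seed = as.integer(seed)),
    class = "vsr_training_config"
  )
}
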