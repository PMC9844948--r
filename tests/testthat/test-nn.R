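# Analytic backpropagation is validated against central-difference
# numerical gradients on micro configurations of every layer type.

grad_entries <- function(params, per_param = 4L, seed = 1L) {
  set.seed(seed)
  ent <- NULL
  for (nm in names(params)) {
    k <- sample(length(params[[nm]]), min(per_param, length(params[[nm]])))
    ent <- rbind(ent, data.frame(param = nm, index = k,
                                 stringsAsFactors = FALSE))
  }
  ent
}

check_grads <- function(model, x, loss_fn, analytic, tol = 1e-4) {
  ent <- grad_entries(model$params)
  ng <- vsr2stage:::numeric_grad(model$params, loss_fn, ent)
  ag <- mapply(function(nm, j) analytic[[nm]][j], ent$param, ent$index)
  rel <- abs(ng - ag) / pmax(abs(ng) + abs(ag), 1e-6)
  expect_lt(max(rel), tol)
}

test_that("AFE-style network gradients match numerical differentiation", {
  set.seed(42)
  layers <- list(
    list(type = "avgpool", pool = c(2L, 2L)),
    list(type = "conv3d", filters = 2L, kernel = c(3L, 3L, 3L),
         stride = c(1L, 2L, 2L)),
    list(type = "maxpool", pool = c(2L, 2L)),
    list(type = "flatten"),
    list(type = "gru", units = 4L),
    list(type = "dense", units = 3L, activation = "linear"))
  m <- init_model(layers, c(5L, 8L, 12L, 1L), seed = 7)
  x <- array(rnorm(2 * 5 * 8 * 12), c(2, 5, 8, 12, 1))
  gt <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  loss_fn <- function(params) {
    m$params <- params
    mean(abs(model_forward(m, x)$out - gt))
  }
  fw <- model_forward(m, x, keep_caches = TRUE)
  bw <- model_backward(m, fw$caches, sign(fw$out - gt) / length(gt))
  check_grads(m, x, loss_fn, bw$grads)
})

test_that("STT-style network + CTC gradients match numerical differentiation", {
  set.seed(3)
  layers <- list(
    list(type = "conv1d", filters = 5L, kernel = 3L),
    list(type = "gru", units = 4L, bidirectional = TRUE),
    list(type = "dense", units = 6L, activation = "softmax"))
  m <- init_model(layers, c(7L, 4L), seed = 2)
  x <- array(rnorm(2 * 7 * 4), c(2, 7, 4))
  labels <- list(c(1L, 2L), 3L)
  loss_fn <- function(params) {
    m$params <- params
    out <- model_forward(m, x)$out
    (ctc_loss(matrix(out[1, , ], 7, 6), labels[[1]], 6L) +
       ctc_loss(matrix(out[2, , ], 7, 6), labels[[2]], 6L)) / 2
  }
  fw <- model_forward(m, x, keep_caches = TRUE)
  g <- vsr2stage:::ctc_batch_grad(fw$out, labels, 6L)
  bw <- model_backward(m, fw$caches, g$dout, dout_pre_activation = TRUE)
  check_grads(m, x, loss_fn, bw$grads)
})

test_that("model construction reports shapes and rejects bad configs", {
  afe <- build_afe(micro_afe_config(12), seed = 1)
  expect_equal(afe$output_shape, c(75L, 12L))
  stt <- build_stt(micro_stt_config(12), seed = 1)
  expect_equal(stt$output_shape, c(75L, 29L))
  expect_error(init_model(list(list(type = "conv3d", filters = 2L,
                                    kernel = c(3L, 3L, 3L),
                                    stride = c(3L, 1L, 1L))),
                          c(75L, 50L, 100L, 1L)),
               "temporal stride")
  expect_error(build_stt(stt_config(n_symbols = 28L)), "29")
})

test_that("forward passes are deterministic and batch-order preserving", {
  afe <- build_afe(micro_afe_config(12), seed = 3)
  set.seed(1)
  x <- array(runif(3 * 75 * 50 * 100, -1, 1), c(3, 75, 50, 100, 1))
  y1 <- model_forward(afe, x)$out
  y2 <- model_forward(afe, x)$out
  expect_identical(y1, y2)
  # permuting the batch permutes the outputs identically
  y_perm <- model_forward(afe, x[c(3, 1, 2), , , , , drop = FALSE])$out
  expect_equal(y_perm[2, , ], y1[1, , ], tolerance = 1e-12)
  # single-sample STT output rows are probability distributions
  stt <- build_stt(micro_stt_config(12), seed = 3)
  p <- model_forward(stt, array(rnorm(75 * 12), c(1, 75, 12)))$out
  expect_true(all(p >= 0))
  expect_lt(max(abs(apply(p[1, , ], 1, sum) - 1)), 1e-6)
})

test_that("afe_loss follows the batch-mean absolute error definition", {
  a <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  expect_equal(afe_loss(a, a), 0)
  expect_equal(afe_loss(a + 0.37, a), 0.37)
  b <- a; b[1, , ] <- a[1, , ] + 1; b[2, , ] <- a[2, , ] - 0.5
  expect_equal(afe_loss(b, a), (1 + 0.5) / 2)
  expect_gt(afe_loss(a + rnorm(length(a)), a), 0)
  expect_error(afe_loss(a, array(0, c(2, 4, 4))), "shape")
})

test_that("glorot initialization is reproducible from the recorded seed", {
  m1 <- build_afe(micro_afe_config(12), seed = 9)
  m2 <- build_afe(micro_afe_config(12), seed = 9)
  m3 <- build_afe(micro_afe_config(12), seed = 10)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("models round-trip through checkpoints", {
  stt <- build_stt(micro_stt_config(12), seed = 4)
  path <- tempfile()
  save_model(stt, path)
  back <- load_model(path)
  x <- array(rnorm(75 * 12), c(1, 75, 12))
  expect_equal(model_forward(back, x)$out, model_forward(stt, x)$out,
               tolerance = 1e-12)
})
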