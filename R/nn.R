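# A small, self-contained neural network engine: spatio-temporal (3D)
# convolutions, spatial max pooling, temporal (1D) convolutions, GRU layers
# and time-distributed dense layers, with analytic backpropagation and an
# Adam optimizer. Heavy kernels live in src/vsr_kernels.cpp; everything is
# double precision, which keeps numerical-gradient checks tight.
#
# Tensors are R arrays in (N, T, ...) layout: conv3d stages see
# (N, T, H, W, C), sequence stages see (N, T, D).

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

as_nt_mat <- function(x) {
  # (N, T, D) -> (N*T, D) without copy semantics surprises
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

glorot <- function(fan_in, fan_out, dims, rng) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

#' Build a network from a layer specification
#'
#' Layers are lists with a `type` field: `conv3d` (fields `filters`,
#' `kernel` = (t,h,w), `stride` = (t,h,w)), `maxpool` / `avgpool`
#' (`pool` = (h,w), spatial only), `flatten`, `conv1d` (`filters`,
#' `kernel`), `gru` (`units`, `bidirectional`), `dense` (`units`,
#' `activation` one of `"linear"`, `"relu"`, `"softmax"`). Convolutions use "same" padding and
#' a ReLU activation; any configuration that shrinks the 75-step time axis
#' is rejected. Weights are Glorot-uniform initialized from `seed`.
#'
#' @param layers list of layer specs.
#' @param input_shape shape of one sample, e.g. `c(75, 50, 100, 1)`.
#' @param seed integer RNG seed recorded in the model.
#' @return a `vsr_model`.
#' @export
init_model <- function(layers, input_shape, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  params <- list()
  shape <- input_shape
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    nm <- paste0("l", i)
    if (ly$type == "conv3d") {
      if (ly$stride[1] != 1L) {
        stop("config error: temporal stride must be 1 (75-step axis preserved)")
      }
      k <- ly$kernel; C <- shape[4]; F_ <- ly$filters
      fan <- prod(k) * c(C, F_)
      params[[paste0(nm, ".w")]] <- glorot(fan[1], fan[2], c(k, C, F_))
      params[[paste0(nm, ".b")]] <- numeric(F_)
      shape <- c(shape[1], ceiling(shape[2] / ly$stride[2]),
                 ceiling(shape[3] / ly$stride[3]), F_)
    } else if (ly$type == "maxpool" || ly$type == "avgpool") {
      shape <- c(shape[1], shape[2] %/% ly$pool[1], shape[3] %/% ly$pool[2],
                 shape[4])
      if (any(shape[2:3] < 1)) stop("config error: pooling collapses spatial axis")
    } else if (ly$type == "flatten") {
      shape <- c(shape[1], prod(shape[-1]))
    } else if (ly$type == "conv1d") {
      D <- shape[2]; F_ <- ly$filters; k <- ly$kernel
      params[[paste0(nm, ".w")]] <- glorot(k * D, k * F_, c(k, D, F_))
      params[[paste0(nm, ".b")]] <- numeric(F_)
      shape <- c(shape[1], F_)
    } else if (ly$type == "gru") {
      D <- shape[2]; U <- ly$units
      dirs <- if (isTRUE(ly$bidirectional)) c("fw", "bw") else "fw"
      for (dr in dirs) {
        params[[paste0(nm, ".", dr, ".w")]] <- glorot(D, U, c(D, 3 * U))
        params[[paste0(nm, ".", dr, ".u")]] <- glorot(U, U, c(U, 3 * U))
        params[[paste0(nm, ".", dr, ".b")]] <- numeric(3 * U)
      }
      shape <- c(shape[1], U * length(dirs))
    } else if (ly$type == "dense") {
      D <- shape[2]; U <- ly$units
      params[[paste0(nm, ".w")]] <- glorot(D, U, c(D, U))
      params[[paste0(nm, ".b")]] <- numeric(U)
      shape <- c(shape[1], U)
    } else {
      stop("unknown layer type: ", ly$type)
    }
  }
  structure(
    list(layers = layers, params = params, input_shape = input_shape,
         output_shape = shape, seed = seed),
    class = "vsr_model"
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.vsr_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<vsr_model> %d layers, %d parameters, in (%s) -> out (%s)\n",
              length(x$layers), np,
              paste(x$input_shape, collapse = ","),
              paste(x$output_shape, collapse = ",")))
  invisible(x)
}

conv1d_pad <- function(k) (k - 1L) %/% 2L

conv3d_out_dims <- function(xdim, stride) {
  c(xdim[1], ceiling(xdim[2] / stride[1]), ceiling(xdim[3] / stride[2]),
    ceiling(xdim[4] / stride[3]))
}

layer_forward <- function(ly, nm, params, x) {
  if (ly$type == "conv3d") {
    w <- params[[paste0(nm, ".w")]]
    b <- params[[paste0(nm, ".b")]]
    st <- conv3d_fused_fwd_cpp(x, w, b, as.integer(ly$stride))
    a <- relu(st$y)
    list(out = a, cache = list(P = st$P, pre = st$y, xdim = dim(x)))
  } else if (ly$type == "maxpool") {
    mp <- maxpool_fwd_cpp(x, as.integer(ly$pool))
    list(out = mp$y, cache = list(argmax = mp$argmax, xdim = dim(x)))
  } else if (ly$type == "avgpool") {
    list(out = avgpool_fwd_cpp(x, as.integer(ly$pool)),
         cache = list(xdim = dim(x)))
  } else if (ly$type == "flatten") {
    d <- dim(x)
    y <- x
    dim(y) <- c(d[1], d[2], prod(d[-(1:2)]))
    list(out = y, cache = list(xdim = d))
  } else if (ly$type == "conv1d") {
    w <- params[[paste0(nm, ".w")]]; b <- params[[paste0(nm, ".b")]]
    d <- dim(x); N <- d[1]; T_ <- d[2]; D <- d[3]
    k <- dim(w)[1]; F_ <- dim(w)[3]
    pad <- conv1d_pad(k)
    xp <- array(0, c(N, T_ + k - 1L, D))
    xp[, pad + seq_len(T_), ] <- x
    ymat <- matrix(rep(b, each = N * T_), N * T_, F_)
    for (o in seq_len(k)) {
      xs <- xp[, o:(o + T_ - 1L), , drop = FALSE]
      dim(xs) <- c(N * T_, D)
      ymat <- ymat + xs %*% w[o, , ]
    }
    y <- ymat
    dim(y) <- c(N, T_, F_)
    a <- relu(y)
    list(out = a, cache = list(xp = xp, pre = y, xdim = d))
  } else if (ly$type == "gru") {
    if (isTRUE(ly$bidirectional)) {
      fw <- gru_dir_forward(x, params, paste0(nm, ".fw"))
      xr <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
      bw <- gru_dir_forward(xr, params, paste0(nm, ".bw"))
      hb <- bw$h[, rev(seq_len(dim(x)[2])), , drop = FALSE]
      d <- dim(fw$h)
      out <- array(0, c(d[1], d[2], 2 * d[3]))
      out[, , seq_len(d[3])] <- fw$h
      out[, , d[3] + seq_len(d[3])] <- hb
      list(out = out, cache = list(fw = fw, bw = bw, x = x))
    } else {
      fw <- gru_dir_forward(x, params, paste0(nm, ".fw"))
      list(out = fw$h, cache = list(fw = fw, x = x))
    }
  } else if (ly$type == "dense") {
    w <- params[[paste0(nm, ".w")]]; b <- params[[paste0(nm, ".b")]]
    d <- dim(x)
    xm <- as_nt_mat(x)
    y <- sweep(xm %*% w, 2, b, "+")
    act <- ly$activation %||% "linear"
    a <- switch(act,
      linear = y,
      relu = relu(y),
      softmax = {
        e <- exp(y - apply(y, 1, max))
        e / rowSums(e)
      })
    out <- a
    dim(out) <- c(d[1], d[2], ncol(w))
    list(out = out, cache = list(xm = xm, pre = y, act = a, xdim = d))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gru_dir_forward <- function(x, params, pre) {
  st <- gru_fwd_cpp(x, params[[paste0(pre, ".w")]],
                    params[[paste0(pre, ".u")]], params[[paste0(pre, ".b")]])
  list(h = st$h, z = st$z, r = st$r, hh = st$hh, x = x, pre = pre)
}

gru_dir_backward <- function(cache, params, dh_all) {
  pre <- cache$pre
  g <- gru_bwd_cpp(cache$x, params[[paste0(pre, ".w")]],
                   params[[paste0(pre, ".u")]], cache$h, cache$z, cache$r,
                   cache$hh, dh_all)
  grads <- stats::setNames(
    list(g$dw, g$du, g$db),
    paste0(pre, c(".w", ".u", ".b"))
  )
  list(dx = g$dx, grads = grads)
}

layer_backward <- function(ly, nm, params, cache, dout, skip_activation = FALSE) {
  if (ly$type == "conv3d") {
    w <- params[[paste0(nm, ".w")]]
    dpre <- dout * (cache$pre > 0)
    g <- conv3d_fused_bwd_cpp(cache$P, w, dpre, as.integer(cache$xdim),
                              as.integer(ly$stride))
    list(dx = g$dx,
         grads = stats::setNames(list(g$dw, g$db), paste0(nm, c(".w", ".b"))))
  } else if (ly$type == "maxpool") {
    list(dx = maxpool_bwd_cpp(dout, cache$argmax, as.integer(cache$xdim)),
         grads = list())
  } else if (ly$type == "avgpool") {
    list(dx = avgpool_bwd_cpp(dout, as.integer(ly$pool),
                              as.integer(cache$xdim)),
         grads = list())
  } else if (ly$type == "flatten") {
    dx <- dout
    dim(dx) <- cache$xdim
    list(dx = dx, grads = list())
  } else if (ly$type == "conv1d") {
    w <- params[[paste0(nm, ".w")]]
    d <- cache$xdim; N <- d[1]; T_ <- d[2]; D <- d[3]
    k <- dim(w)[1]; F_ <- dim(w)[3]
    pad <- conv1d_pad(k)
    dpre <- dout * (cache$pre > 0)
    dmat <- dpre
    dim(dmat) <- c(N * T_, F_)
    dw <- array(0, dim(w))
    dxp <- array(0, c(N, T_ + k - 1L, D))
    for (o in seq_len(k)) {
      xs <- cache$xp[, o:(o + T_ - 1L), , drop = FALSE]
      dim(xs) <- c(N * T_, D)
      dw[o, , ] <- t(xs) %*% dmat
      contrib <- dmat %*% t(w[o, , ])
      dim(contrib) <- c(N, T_, D)
      dxp[, o:(o + T_ - 1L), ] <- dxp[, o:(o + T_ - 1L), ] + contrib
    }
    dx <- dxp[, pad + seq_len(T_), , drop = FALSE]
    list(dx = dx,
         grads = stats::setNames(list(dw, colSums(dmat)), paste0(nm, c(".w", ".b"))))
  } else if (ly$type == "gru") {
    if (isTRUE(ly$bidirectional)) {
      U <- dim(cache$fw$h)[3]
      dfw <- dout[, , seq_len(U), drop = FALSE]
      dbw <- dout[, , U + seq_len(U), drop = FALSE]
      dbw <- dbw[, rev(seq_len(dim(dbw)[2])), , drop = FALSE]
      g1 <- gru_dir_backward(cache$fw, params, dfw)
      g2 <- gru_dir_backward(cache$bw, params, dbw)
      dx <- g1$dx + g2$dx[, rev(seq_len(dim(g2$dx)[2])), , drop = FALSE]
      list(dx = dx, grads = c(g1$grads, g2$grads))
    } else {
      g <- gru_dir_backward(cache$fw, params, dout)
      list(dx = g$dx, grads = g$grads)
    }
  } else if (ly$type == "dense") {
    w <- params[[paste0(nm, ".w")]]
    d <- cache$xdim
    dmat <- dout
    dim(dmat) <- c(d[1] * d[2], ncol(w))
    act <- ly$activation %||% "linear"
    if (!skip_activation) {
      if (act == "relu") {
        dmat <- dmat * (cache$pre > 0)
      } else if (act == "softmax") {
        a <- cache$act
        dmat <- a * (dmat - rowSums(dmat * a))
      }
    }
    dw <- t(cache$xm) %*% dmat
    dx <- dmat %*% t(w)
    dim(dx) <- d
    list(dx = dx,
         grads = stats::setNames(list(dw, colSums(dmat)), paste0(nm, c(".w", ".b"))))
  }
}

#' Run a model forward
#'
#' @param model a `vsr_model`.
#' @param x batch array, first axis = samples.
#' @param keep_caches retain per-layer caches for [model_backward()].
#' @return list with `out` and (if requested) `caches`.
#' @export
model_forward <- function(model, x, keep_caches = FALSE) {
  caches <- if (keep_caches) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    st <- layer_forward(model$layers[[i]], paste0("l", i), model$params, x)
    x <- st$out
    if (keep_caches) caches[[i]] <- st$cache
  }
  list(out = x, caches = caches)
}

#' Backpropagate through a model
#'
#' @param model a `vsr_model`.
#' @param caches caches from `model_forward(..., keep_caches = TRUE)`.
#' @param dout gradient w.r.t. the model output.
#' @param dout_pre_activation if `TRUE`, `dout` is the gradient w.r.t. the
#'   final layer's pre-activation (used with CTC, whose gradient is taken
#'   w.r.t. logits).
#' @return list with `grads` (named like `model$params`) and `dx`.
#' @export
model_backward <- function(model, caches, dout, dout_pre_activation = FALSE) {
  grads <- list()
  n <- length(model$layers)
  for (i in rev(seq_len(n))) {
    st <- layer_backward(model$layers[[i]], paste0("l", i), model$params,
                         caches[[i]], dout,
                         skip_activation = dout_pre_activation && i == n)
    dout <- st$dx
    grads <- c(grads, st$grads)
  }
  list(grads = grads, dx = dout)
}

#' Adam optimizer state and update
#'
#' @param params named list of parameter arrays.
#' @return optimizer state for [adam_step()].
#' @export
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0L
  )
}

#' @rdname adam_init
#' @param grads named gradient list matching `params`.
#' @param state state from [adam_init()].
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return list with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# central-difference numerical gradient of loss_fn(params) w.r.t. selected
# entries; used by the gradient-check tests
numeric_grad <- function(params, loss_fn, entries, h = 1e-5) {
  out <- numeric(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    nm <- entries$param[i]; j <- entries$index[i]
    p_plus <- params; p_plus[[nm]][j] <- p_plus[[nm]][j] + h
    p_minus <- params; p_minus[[nm]][j] <- p_minus[[nm]][j] - h
    out[i] <- (loss_fn(p_plus) - loss_fn(p_minus)) / (2 * h)
  }
  out
}
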