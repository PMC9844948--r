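#' Visual augmentation configuration
#'
#' Each augmentation step (rotation, translation, shear, scale, noise,
#' brightness) is independently enabled per video with probability `p_aug`;
#' horizontal flipping is enabled with `p_flip`. Parameters are drawn
#' uniformly within the configured ranges, once per video, and applied
#' identically to every frame of that video.
#'
#' @param p_aug per-step application probability (0.8).
#' @param p_flip horizontal-flip probability (0.5).
#' @param rotation maximum |rotation| in degrees.
#' @param translation maximum |shift| in pixels, `c(x, y)`.
#' @param shear maximum |shear| factor.
#' @param scale scale factor range `c(lo, hi)`.
#' @param noise_sigma maximum Gaussian noise standard deviation (on the
#'   `[-1, 1]` pixel scale).
#' @param brightness maximum |luminance offset|.
#' @return a `vsr_augmenter_config`.
#' @export
augmenter_config <- function(p_aug = 0.8, p_flip = 0.5, rotation = 5,
                             translation = c(5, 5), shear = 0.1,
                             scale = c(0.9, 1.1), noise_sigma = 0.05,
                             brightness = 0.2) {
  stopifnot(p_aug >= 0, p_aug <= 1, p_flip >= 0, p_flip <= 1,
            scale[1] <= scale[2])
  structure(
    list(p_aug = p_aug, p_flip = p_flip, rotation = rotation,
         translation = translation, shear = shear, scale = scale,
         noise_sigma = noise_sigma, brightness = brightness),
    class = "vsr_augmenter_config"
  )
}

#' Sample per-video augmentation parameters
#'
#' Draws from the current RNG stream (seed it for reproducibility). One
#' `vsr_augment_params` is sampled per video and reused for all frames.
#'
#' @param cfg an [augmenter_config()].
#' @return a `vsr_augment_params`.
#' @export
sample_params <- function(cfg = augmenter_config()) {
  apply_step <- function() stats::runif(1) < cfg$p_aug
  structure(
    list(
      flip = stats::runif(1) < cfg$p_flip,
      rotate_on = apply_step(),
      rotation = stats::runif(1, -cfg$rotation, cfg$rotation),
      translate_on = apply_step(),
      translation = c(stats::runif(1, -cfg$translation[1], cfg$translation[1]),
                      stats::runif(1, -cfg$translation[2], cfg$translation[2])),
      shear_on = apply_step(),
      shear = stats::runif(1, -cfg$shear, cfg$shear),
      scale_on = apply_step(),
      scale = stats::runif(1, cfg$scale[1], cfg$scale[2]),
      noise_on = apply_step(),
      noise_sigma = stats::runif(1, 0, cfg$noise_sigma),
      noise_seed = sample.int(.Machine$integer.max - 1L, 1L),
      brightness_on = apply_step(),
      brightness = stats::runif(1, -cfg$brightness, cfg$brightness)
    ),
    class = "vsr_augment_params"
  )
}

#' Identity augmentation parameters
#'
#' All steps disabled; [apply_augmentation()] returns the input bit-exactly.
#' @return a `vsr_augment_params`.
#' @export
identity_params <- function() {
  structure(
    list(flip = FALSE, rotate_on = FALSE, rotation = 0, translate_on = FALSE,
         translation = c(0, 0), shear_on = FALSE, shear = 0, scale_on = FALSE,
         scale = 1, noise_on = FALSE, noise_sigma = 0, noise_seed = 1L,
         brightness_on = FALSE, brightness = 0),
    class = "vsr_augment_params"
  )
}

augment_affine_matrix <- function(params, H, W) {
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  A <- diag(2)
  if (params$rotate_on) {
    th <- params$rotation * pi / 180
    A <- A %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  }
  if (params$shear_on) A <- A %*% rbind(c(1, params$shear), c(0, 1))
  if (params$scale_on) A <- A * params$scale
  tr <- if (params$translate_on) params$translation else c(0, 0)
  Ainv <- solve(A)
  # output pixel -> input pixel: p_in = Ainv (p_out - c - t) + c
  cbind(Ainv, c(cx, cy) - Ainv %*% (c(cx, cy) + tr))
}

#' Apply augmentation parameters to a frame sequence
#'
#' Operation order: horizontal flip, then one composed affine transform
#' (rotation about the image center, translation, shear, scale) with
#' bilinear resampling and black (-1) border fill, then zero-mean Gaussian
#' noise, then a constant luminance offset. The result is clipped to
#' `[-1, 1]`. Every frame receives the identical parameters; the noise
#' stream is seeded per video.
#'
#' @param frames `T x H x W` array in `[-1, 1]`, a `T x H x W x 1` tensor,
#'   or a `vsr_frames`.
#' @param params a `vsr_augment_params`.
#' @return augmented frames of the same type/shape.
#' @export
apply_augmentation <- function(frames, params, valid_length = NULL) {
  if (inherits(frames, "vsr_frames")) {
    out <- frames
    x <- frames$tensor
    d4 <- dim(x)
    dim(x) <- d4[1:3]   # same memory layout; avoids a subsetting copy
    x <- apply_augmentation(x, params, valid_length = frames$valid_length)
    dim(x) <- d4
    out$tensor <- x
    return(out)
  }
  d <- dim(frames)
  if (length(d) == 4L) {
    x <- frames
    dim(x) <- d[1:3]
    x <- apply_augmentation(x, params, valid_length = valid_length)
    dim(x) <- d
    return(x)
  }
  T_ <- d[1]; H <- d[2]; W <- d[3]
  x <- frames
  do_affine <- params$rotate_on || params$translate_on || params$shear_on ||
    params$scale_on
  if (params$flip || do_affine) {
    M <- augment_affine_matrix(params, H, W)
    if (params$flip) {
      # flip happens before the affine step: post-compose the mirror
      # x -> W-1-x onto the inverse map; a pure flip then samples exact
      # pixel centers, so double flip is bit-exact
      M[1, 1:2] <- -M[1, 1:2]
      M[1, 3] <- (W - 1) - M[1, 3]
    }
    x <- warp_stack_cpp(x, M, -1,
                        if (is.null(valid_length)) T_ else valid_length)
  }
  if (params$noise_on || params$brightness_on) {
    sigma <- if (params$noise_on) params$noise_sigma else 0
    bright <- if (params$brightness_on) params$brightness else 0
    vl <- if (is.null(valid_length)) T_ else valid_length
    old <- NULL
    if (sigma > 0) {
      old <- .Random.seed_get()
      set.seed(params$noise_seed)
    }
    x <- noise_brightness_clip_cpp(x, sigma, bright, as.integer(vl))
    if (sigma > 0) .Random.seed_set(old)
  }
  x
}
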