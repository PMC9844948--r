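#' Raw audiovisual sample
#'
#' Container for one utterance: video frames (25 fps), the mono waveform,
#' the transcript and bookkeeping labels. Frames are numeric arrays, either
#' `H x W x 3` (RGB) or `H x W` (already grayscale), on a 0..255 scale.
#'
#' @param frames list of frame arrays.
#' @param waveform list with `samples` (numeric vector) and `rate` (Hz).
#' @param transcript transcript text.
#' @param speaker_id,view_tag labels.
#' @param landmarks optional list of per-frame [mouth_landmarks()] (supplied
#'   by the synthetic generator, where they are exact).
#' @return a `vsr_raw_sample`.
#' @export
raw_sample <- function(frames, waveform, transcript, speaker_id = "s1",
                       view_tag = "center", landmarks = NULL) {
  stopifnot(length(frames) >= 1L, length(waveform$samples) > 0L)
  structure(
    list(frames = frames, waveform = waveform, transcript = transcript,
         speaker_id = speaker_id, view_tag = view_tag, landmarks = landmarks,
         fps = 25),
    class = "vsr_raw_sample"
  )
}

#' Mouth landmarks for one frame
#'
#' Four key points: left/right mouth corner and the middle of the upper and
#' lower lip. Coordinates are 0-based pixels, x right, y down.
#'
#' @param left_corner,right_corner,upper_mid,lower_mid numeric `(x, y)` pairs.
#' @return a `vsr_landmarks`.
#' @export
mouth_landmarks <- function(left_corner, right_corner, upper_mid, lower_mid) {
  structure(
    list(left_corner = as.numeric(left_corner),
         right_corner = as.numeric(right_corner),
         upper_mid = as.numeric(upper_mid),
         lower_mid = as.numeric(lower_mid)),
    class = "vsr_landmarks"
  )
}

#' Convert an RGB frame to grayscale luminance
#'
#' ITU-R BT.601 weights (0.299, 0.587, 0.114). Integer-valued inputs (uint8
#' pixel data) yield rounded integer luminance; float inputs are left
#' unrounded.
#'
#' @param frame `H x W x 3` numeric array.
#' @return `H x W` matrix.
#' @export
to_grayscale <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L) {
    stop("invalid input: to_grayscale expects an H x W x 3 array")
  }
  g <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  if (all(frame == floor(frame))) g <- round(g)
  g
}

#' Mouth-centered crop box with half-extent padding
#'
#' The box spans the mouth extent plus a margin of half the mouth width on
#' the left/right and half the mouth height above/below, so the cropped
#' image is twice the mouth size in each dimension. Boxes are half-open
#' `[x0, x1) x [y0, y1)` and may extend past the image; clipping (black
#' fill) happens at crop time.
#'
#' @param landmarks a [mouth_landmarks()].
#' @return numeric `c(x0, y0, x1, y1)`.
#' @export
compute_crop_box <- function(landmarks) {
  lx <- landmarks$left_corner[1]; rx <- landmarks$right_corner[1]
  uy <- landmarks$upper_mid[2];  dy <- landmarks$lower_mid[2]
  w <- rx - lx
  h <- dy - uy
  if (w <= 0 || h <= 0) {
    stop("degenerate landmarks: mouth width and height must be positive")
  }
  c(x0 = lx - w / 2, y0 = uy - h / 2, x1 = rx + w / 2, y1 = dy + h / 2)
}

#' Crop a box out of a frame and resize to 50 x 100
#'
#' Bilinear inverse-mapping resampling of the half-open box `[x0,x1) x
#' [y0,y1)` onto a `50 x 100` (height x width) grid. Box regions outside the
#' image are filled with `fill` (black) rather than shrinking the box, so
#' the mouth stays centered.
#'
#' @param frame grayscale matrix.
#' @param box numeric `c(x0, y0, x1, y1)`.
#' @param out_h,out_w output size (defaults 50 x 100).
#' @param fill border fill value (default 0, black on the 0..255 scale).
#' @return `out_h x out_w` matrix.
#' @export
crop_resize <- function(frame, box, out_h = 50L, out_w = 100L, fill = 0) {
  H <- nrow(frame); W <- ncol(frame)
  if (box[3] <= 0 || box[1] >= W || box[4] <= 0 || box[2] >= H) {
    stop("invalid box: crop box lies entirely outside the image")
  }
  sx <- (box[3] - box[1]) / out_w
  sy <- (box[4] - box[2]) / out_h
  # output pixel center c maps to input x = x0 + (c + 0.5) * sx - 0.5
  M <- rbind(c(sx, 0, box[1] + 0.5 * sx - 0.5),
             c(0, sy, box[2] + 0.5 * sy - 0.5))
  warp_bilinear_cpp(frame, M, as.integer(out_h), as.integer(out_w), fill)
}

#' Map pixel values to [-1, 1] and back
#'
#' The affine map `x -> x / 127.5 - 1` applied before frames enter the AFE;
#' `denormalize_frames` is its exact inverse.
#'
#' @param x numeric array on the 0..255 scale (or [-1,1] for the inverse).
#' @return array of the same shape.
#' @export
normalize_frames <- function(x) x / 127.5 - 1

#' @rdname normalize_frames
#' @export
denormalize_frames <- function(x) (x + 1) * 127.5

#' Pad a frame sequence with black frames to 75 timesteps
#'
#' @param frames `T x 50 x 100` array of normalized frames in `[-1, 1]`.
#' @param target target length (75).
#' @param black padding value (-1, a black pixel after normalization).
#' @return a `vsr_frames`: `tensor` of shape `75 x 50 x 100 x 1` and
#'   `valid_length`.
#' @export
pad_to_length <- function(frames, target = 75L, black = -1) {
  d <- dim(frames)
  if (is.null(d) || length(d) != 3L) stop("frames must be a T x H x W array")
  T_ <- d[1]
  if (T_ == 0L) stop("empty video")
  if (T_ > target) stop("sequence too long: ", T_, " frames > ", target)
  tensor <- array(black, dim = c(target, d[2], d[3], 1L))
  tensor[seq_len(T_), , , 1L] <- frames
  structure(list(tensor = tensor, valid_length = as.integer(T_)),
            class = "vsr_frames")
}

#' @export
print.vsr_frames <- function(x, ...) {
  cat(sprintf("<vsr_frames> %s tensor, valid_length %d\n",
              paste(dim(x$tensor), collapse = "x"), x$valid_length))
  invisible(x)
}

#' Landmark provider backed by a sample's stored landmarks
#'
#' The pipeline consumes landmarks through a pluggable provider so that any
#' face/landmark detector can be dropped in; the synthetic generator stores
#' exact landmarks which this provider replays. A provider is a function
#' `(sample, frame_index) -> vsr_landmarks | NULL` where `NULL` signals
#' detection failure for that frame.
#'
#' @return a landmark provider function.
#' @export
stored_landmark_provider <- function() {
  function(sample, frame_index) {
    if (is.null(sample$landmarks) || frame_index > length(sample$landmarks)) {
      return(NULL)
    }
    sample$landmarks[[frame_index]]
  }
}

#' Preprocess a raw sample into the AFE input tensor
#'
#' Full chain: grayscale conversion, mouth-centered crop (half-extent
#' padding), resize to 50 x 100, normalization to `[-1, 1]`, padding with
#' black frames to length 75. Videos for which the landmark provider fails
#' on any frame are rejected (a `vsr_rejected` value, not an error),
#' mirroring the policy of discarding videos with failed face detection.
#'
#' @param sample a `vsr_raw_sample`.
#' @param landmark_provider see [stored_landmark_provider()].
#' @return a `vsr_frames`, or a `vsr_rejected` object.
#' @export
preprocess_video <- function(sample, landmark_provider = stored_landmark_provider()) {
  n <- length(sample$frames)
  out <- array(0, dim = c(n, 50L, 100L))
  for (i in seq_len(n)) {
    lm <- landmark_provider(sample, i)
    if (is.null(lm)) {
      return(structure(list(reason = sprintf("landmarks unavailable on frame %d", i)),
                       class = "vsr_rejected"))
    }
    fr <- sample$frames[[i]]
    if (length(dim(fr)) == 3L) fr <- to_grayscale(fr)
    box <- compute_crop_box(lm)
    out[i, , ] <- crop_resize(fr, box)
  }
  pad_to_length(normalize_frames(out))
}

#' @export
print.vsr_rejected <- function(x, ...) {
  cat("<vsr_rejected>", x$reason, "\n")
  invisible(x)
}

#' Test for a rejected preprocessing result
#' @param x object returned by [preprocess_video()].
#' @return `TRUE` if the video was rejected.
#' @export
is_rejected <- function(x) inherits(x, "vsr_rejected")
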