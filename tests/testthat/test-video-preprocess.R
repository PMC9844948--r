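test_that("grayscale conversion uses BT.601 luminance", {
  mk <- function(r, g, b) {
    fr <- array(0, c(2, 2, 3))
    fr[, , 1] <- r; fr[, , 2] <- g; fr[, , 3] <- b
    fr
  }
  expect_true(all(to_grayscale(mk(255, 255, 255)) == 255))
  expect_true(all(to_grayscale(mk(97, 97, 97)) == 97))
  expect_true(all(to_grayscale(mk(255, 0, 0)) == 76))
  # float input keeps fractional luminance
  expect_equal(to_grayscale(mk(0.5, 0.5, 0.5))[1, 1], 0.5)
  expect_error(to_grayscale(matrix(1, 3, 3)), "invalid input")
})

test_that("crop box follows the half-padding rule", {
  lm <- mouth_landmarks(c(40, 60), c(80, 60), c(60, 50), c(60, 70))
  expect_equal(unname(compute_crop_box(lm)), c(20, 40, 100, 80))
  lm2 <- mouth_landmarks(c(0, 10), c(10, 10), c(5, 8), c(5, 12))
  expect_equal(unname(compute_crop_box(lm2)), c(-5, 6, 15, 14))
  # box is twice the mouth extent before clipping
  set.seed(4)
  for (i in 1:20) {
    w <- runif(1, 1, 40); h <- runif(1, 1, 20)
    cx <- runif(1, 10, 90); cy <- runif(1, 10, 90)
    b <- compute_crop_box(mouth_landmarks(c(cx - w / 2, cy), c(cx + w / 2, cy),
                                          c(cx, cy - h / 2), c(cx, cy + h / 2)))
    expect_equal(unname(b[3] - b[1]), 2 * w)
    expect_equal(unname(b[4] - b[2]), 2 * h)
  }
  expect_error(compute_crop_box(mouth_landmarks(c(50, 10), c(50, 10),
                                                c(50, 8), c(50, 12))),
               "degenerate")
})

test_that("crop_resize is near-identity on a same-shaped box", {
  img <- gradient_image(50, 100)
  out <- crop_resize(img, c(0, 0, 100, 50))
  expect_equal(dim(out), c(50L, 100L))
  expect_equal(out, img, tolerance = 1e-12)
})

test_that("crop_resize preserves constants and matches a bilinear oracle", {
  img <- matrix(42, 30, 60)
  out <- crop_resize(img, c(5, 5, 25, 15))
  expect_true(all(abs(out - 42) < 1e-12))
  # 2x downsample of a known pattern vs direct bilinear interpolation oracle
  img <- gradient_image(100, 200)
  out <- crop_resize(img, c(0, 0, 200, 100))
  oracle <- matrix(0, 50, 100)
  for (r in 1:50) for (c in 1:100) {
    x <- (c - 0.5) * 2 - 0.5; y <- (r - 0.5) * 2 - 0.5
    x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
    px <- function(yy, xx) {
      if (xx < 0 || xx > 199 || yy < 0 || yy > 99) 0 else img[yy + 1, xx + 1]
    }
    oracle[r, c] <- (1 - fx) * (1 - fy) * px(y0, x0) + fx * (1 - fy) * px(y0, x0 + 1) +
      (1 - fx) * fy * px(y0 + 1, x0) + fx * fy * px(y0 + 1, x0 + 1)
  }
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_error(crop_resize(img, c(500, 0, 600, 50)), "invalid box")
})

test_that("frame normalization is the stated affine map with exact inverse", {
  expect_equal(normalize_frames(0), -1)
  expect_equal(normalize_frames(255), 1)
  expect_equal(normalize_frames(127.5), 0)
  x <- runif(1000, -1, 1)
  expect_lt(max(abs(normalize_frames(denormalize_frames(x)) - x)), 1e-12)
})

test_that("padding to 75 frames appends black and records valid length", {
  fr <- array(runif(40 * 50 * 100, -1, 1), c(40, 50, 100))
  p <- pad_to_length(fr)
  expect_equal(dim(p$tensor), c(75L, 50L, 100L, 1L))
  expect_equal(p$valid_length, 40L)
  expect_true(all(p$tensor[41:75, , , 1] == -1))
  expect_equal(p$tensor[1:40, , , 1], fr)
  full <- pad_to_length(array(0.5, c(75, 50, 100)))
  expect_equal(full$valid_length, 75L)
  expect_error(pad_to_length(array(0, c(76, 50, 100))), "too long")
  expect_error(pad_to_length(array(0, c(0, 50, 100))), "empty")
})

test_that("preprocess_video runs the full chain deterministically", {
  set.seed(21)
  s <- generate_sample("im hot", synth_config())
  a <- preprocess_video(s)
  set.seed(21)
  b <- preprocess_video(generate_sample("im hot", synth_config()))
  expect_identical(a$tensor, b$tensor)
  expect_equal(a$valid_length, length(s$frames))
  expect_true(all(a$tensor >= -1 & a$tensor <= 1))
})

test_that("videos with failing landmark detection are rejected, not errored", {
  set.seed(2)
  s <- generate_sample("yes please", synth_config())
  flaky <- function(sample, i) if (i == 3) NULL else sample$landmarks[[i]]
  out <- preprocess_video(s, flaky)
  expect_true(is_rejected(out))
  expect_match(out$reason, "frame 3")
  ok <- preprocess_video(s)
  expect_false(is_rejected(ok))
})
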