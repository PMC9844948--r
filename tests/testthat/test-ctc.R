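test_that("ctc loss matches the closed-form two-frame example", {
  # two frames, symbols {a, blank}, uniform rows: valid alignments of "a"
  # are aa, a_, _a with total probability 3/4
  p <- matrix(0.5, 2, 2)
  expect_rel_equal(ctc_loss(p, 1L, blank_index = 2L), -log(0.75))
  expect_rel_equal(ctc_bruteforce(p, 1L, blank_index = 2L), -log(0.75))
})

test_that("one-hot probabilities on a valid alignment give zero loss", {
  ab <- build_alphabet()
  ids <- encode_transcript("ab", ab)
  p <- matrix(1e-12, 6, 29)
  path <- c(ids[1], ab$blank_index, ids[2], ab$blank_index, ab$blank_index,
            ab$blank_index)
  for (t in 1:6) p[t, path[t]] <- 1
  p <- p / rowSums(p)
  expect_lt(ctc_loss(p, ids, ab$blank_index), 1e-8)
})

test_that("dynamic program equals brute-force enumeration on 200 instances", {
  set.seed(42)
  done <- 0
  while (done < 200) {
    T_ <- sample(2:6, 1); K <- sample(2:4, 1)
    L <- sample(0:3, 1)
    label <- if (L > 0) sample(K - 1, L, replace = TRUE) else integer(0)
    need <- L + if (L > 1) sum(label[-1] == label[-L]) else 0
    if (need > T_) next
    p <- random_probs(T_, K)
    dp <- ctc_loss(p, label, blank_index = K)
    bf <- ctc_bruteforce(p, label, blank_index = K)
    expect_rel_equal(dp, bf, tol = 1e-9)
    done <- done + 1
  }
})

test_that("alignment classes partition path space on tiny instances", {
  # summing exp(-loss) over all admissible labels must give exactly 1
  set.seed(17)
  for (rep in 1:5) {
    T_ <- 4; K <- 3   # symbols {1,2}, blank = 3
    p <- random_probs(T_, K)
    labels <- list(integer(0))
    for (L in 1:T_) {
      grid <- as.matrix(expand.grid(rep(list(1:(K - 1)), L)))
      labels <- c(labels, lapply(seq_len(nrow(grid)), function(i) unname(grid[i, ])))
    }
    total <- 0
    for (lab in labels) {
      L <- length(lab)
      need <- L + if (L > 1) sum(lab[-1] == lab[-L]) else 0
      if (need > T_) next
      total <- total + exp(-ctc_loss(p, lab, blank_index = K))
    }
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("inadmissible and malformed labels error", {
  p <- random_probs(3, 3)
  # "aa" needs at least 3 frames (repeat separator); "aaa" needs 5
  expect_rel_equal(ctc_loss(p, c(1L, 1L), blank_index = 3L),
                   ctc_bruteforce(p, c(1L, 1L), blank_index = 3L))
  expect_error(ctc_loss(p, c(1L, 1L, 1L), blank_index = 3L), "inadmissible")
  expect_error(ctc_loss(p, c(1L, 3L), blank_index = 3L), "blank")
  expect_error(ctc_bruteforce(random_probs(9, 2), 1L, 2L), "refused")
  # empty label with all-blank mass: loss is -sum log p_t(blank)
  p2 <- random_probs(4, 3)
  expect_rel_equal(ctc_loss(p2, integer(0), 3L), -sum(log(p2[, 3])))
})

test_that("greedy decoding collapses repeats and strips blank and pad", {
  ab <- build_alphabet()
  mk <- function(chars) {
    ids <- ab$index[chars]
    p <- matrix(1e-6, length(ids), 29)
    p[cbind(seq_along(ids), ids)] <- 1
    p / rowSums(p)
  }
  expect_equal(greedy_decode(mk(strsplit("__hh_e_l_ll_o", "")[[1]]), ab), "hello")
  expect_equal(greedy_decode(mk(c("h", "h", "e", "l", "_", "l", "o")), ab), "hello")
  expect_equal(greedy_decode(mk(rep("_", 5)), ab), "")
  expect_equal(greedy_decode(mk(c("a", "a", "_", "a")), ab), "aa")
  expect_equal(greedy_decode(mk(c("a", "<pad>", "b")), ab), "ab")
  # appending pure-blank rows never changes the decode
  p <- random_probs(6, 29)
  blanks <- matrix(1e-9, 3, 29); blanks[, ab$blank_index] <- 1
  blanks <- blanks / rowSums(blanks)
  expect_equal(greedy_decode(rbind(p, blanks), ab), greedy_decode(p, ab))
})

test_that("beam search matches exhaustive max-posterior collapse", {
  # oracle: enumerate all paths over the symbols with nonzero mass
  # (columns outside `active` are exactly zero, so skipping them is exact),
  # accumulate probability per collapsed string, return the argmax
  exhaustive <- function(p, blank, active) {
    T_ <- nrow(p)
    paths <- as.matrix(expand.grid(rep(list(active), T_)))
    acc <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(paths))) {
      path <- paths[i, ]
      key <- paste0("s", paste(sprintf("%03d", vsr2stage:::ctc_collapse(path, blank)),
                               collapse = ","))
      prob <- prod(p[cbind(1:T_, path)])
      old <- if (exists(key, envir = acc, inherits = FALSE)) get(key, envir = acc) else 0
      assign(key, old + prob, envir = acc)
    }
    keys <- ls(acc)
    vals <- vapply(keys, function(k) get(k, envir = acc), numeric(1))
    best <- sort(keys[vals == max(vals)])[1]
    best <- sub("^s", "", best)
    if (!nzchar(best)) integer(0) else as.integer(strsplit(best, ",")[[1]])
  }
  ab <- build_alphabet()
  set.seed(31)
  for (rep in 1:10) {
    T_ <- sample(3:5, 1)
    # all probability mass on three symbols; the rest is exactly zero
    p <- matrix(0, T_, 29)
    active <- c(sample(1:26, 2), ab$blank_index)
    p[, active] <- matrix(rexp(T_ * 3), T_, 3)
    p <- p / rowSums(p)
    want <- decode_ids(exhaustive(p, ab$blank_index, active), ab)
    expect_equal(beam_decode(p, ab, beam_width = 64L), want)
  }
})

test_that("beam search posterior is monotone in beam width and one-hot agrees with greedy", {
  ab <- build_alphabet()
  set.seed(5)
  ids <- encode_transcript("ab", ab)
  p <- matrix(1e-9, 4, 29)
  p[cbind(1:4, c(ids[1], ab$blank_index, ids[2], ab$blank_index))] <- 1
  p <- p / rowSums(p)
  expect_equal(beam_decode(p, ab, 4L), greedy_decode(p, ab))
  posterior <- function(text, p) {
    lab <- if (nzchar(text)) encode_transcript(text, ab) else integer(0)
    exp(-ctc_loss(p, lab, ab$blank_index))
  }
  for (rep in 1:5) {
    q <- matrix(0, 4, 29)
    active <- c(sample(1:26, 2), ab$blank_index)
    q[, active] <- matrix(rexp(12), 4, 3)
    q <- q / rowSums(q)
    narrow <- posterior(beam_decode(q, ab, 1L), q)
    wide <- posterior(beam_decode(q, ab, 32L), q)
    expect_gte(wide, narrow - 1e-12)
  }
})
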