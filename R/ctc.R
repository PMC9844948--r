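# Connectionist Temporal Classification: log-space forward/backward dynamic
# programs, a brute-force enumeration oracle, and greedy / prefix-beam
# decoding from per-frame character distributions.

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

ctc_n_repeats <- function(label) {
  if (length(label) < 2L) return(0L)
  sum(label[-1L] == label[-length(label)])
}

check_ctc_label <- function(label, n_frames, blank_index) {
  if (any(label == blank_index)) stop("label must not contain the blank id")
  need <- length(label) + ctc_n_repeats(label)
  if (need > n_frames) {
    stop("inadmissible label: needs at least ", need, " frames, have ", n_frames)
  }
}

extended_label <- function(label, blank_index) {
  ext <- rep(blank_index, 2L * length(label) + 1L)
  if (length(label) > 0L) ext[seq(2L, by = 2L, length.out = length(label))] <- label
  ext
}

ctc_alpha <- function(logp, ext, blank_index) {
  T_ <- nrow(logp); S <- length(ext)
  alpha <- matrix(-Inf, T_, S)
  alpha[1, 1] <- logp[1, ext[1]]
  if (S > 1) alpha[1, 2] <- logp[1, ext[2]]
  for (t in seq_len(T_)[-1]) {
    prev <- alpha[t - 1, ]
    a <- prev
    if (S > 1) a[-1] <- logsumexp2(a[-1], prev[-S])
    if (S > 2) {
      skip_ok <- c(rep(FALSE, 2), ext[3:S] != blank_index & ext[3:S] != ext[1:(S - 2)])
      a[skip_ok] <- logsumexp2(a[skip_ok], prev[which(skip_ok) - 2L])
    }
    alpha[t, ] <- a + logp[t, ext]
  }
  alpha
}

#' CTC loss of a label given per-frame character distributions
#'
#' Negative log probability of the label under the CTC alignment model:
#' the sum over all length-`T` symbol paths whose collapse (merge adjacent
#' repeats, then delete blanks) equals the label. Computed with the
#' standard log-space forward dynamic program over the blank-augmented
#' label.
#'
#' @param probs `T x K` matrix; each row a probability distribution.
#' @param label integer label ids (no blanks). `<pad>` is an ordinary
#'   symbol at loss time.
#' @param blank_index index of the blank symbol (default: last column).
#' @return scalar `-log p(label | probs)`.
#' @export
ctc_loss <- function(probs, label, blank_index = ncol(probs)) {
  check_ctc_label(label, nrow(probs), blank_index)
  logp <- log(probs)
  ext <- extended_label(label, blank_index)
  alpha <- ctc_alpha(logp, ext, blank_index)
  S <- length(ext)
  tot <- if (S > 1) logsumexp2(alpha[nrow(probs), S], alpha[nrow(probs), S - 1]) else alpha[nrow(probs), S]
  -tot
}

# Loss plus gradient with respect to the pre-softmax logits (probs must be
# the softmax of those logits). Used by the STT training loop.
ctc_loss_grad <- function(probs, label, blank_index = ncol(probs)) {
  check_ctc_label(label, nrow(probs), blank_index)
  T_ <- nrow(probs); K <- ncol(probs)
  logp <- log(probs)
  ext <- extended_label(label, blank_index)
  S <- length(ext)
  alpha <- ctc_alpha(logp, ext, blank_index)
  # backward variable on the reversed problem
  beta <- matrix(-Inf, T_, S)
  beta[T_, S] <- logp[T_, ext[S]]
  if (S > 1) beta[T_, S - 1] <- logp[T_, ext[S - 1]]
  if (T_ > 1) {
    for (t in rev(seq_len(T_ - 1))) {
      nxt <- beta[t + 1, ]
      b <- nxt
      if (S > 1) b[-S] <- logsumexp2(b[-S], nxt[-1])
      if (S > 2) {
        skip_ok <- c(ext[1:(S - 2)] != blank_index & ext[1:(S - 2)] != ext[3:S],
                     rep(FALSE, 2))
        b[skip_ok] <- logsumexp2(b[skip_ok], nxt[which(skip_ok) + 2L])
      }
      beta[t, ] <- b + logp[t, ext]
    }
  }
  loglik <- if (S > 1) logsumexp2(alpha[T_, S], alpha[T_, S - 1]) else alpha[T_, S]
  # gamma_tk = p(path passes a state with symbol k at time t | label) ;
  # gradient w.r.t. logits is probs - gamma
  grad <- probs
  ab <- alpha + beta  # includes logp twice
  for (t in seq_len(T_)) {
    contrib <- ab[t, ] - logp[t, ext] - loglik
    for (k in unique(ext)) {
      sel <- ext == k
      grad[t, k] <- grad[t, k] - exp(logsumexp(contrib[sel]))
    }
  }
  list(loss = -loglik, grad = grad)
}

#' Brute-force CTC oracle
#'
#' Enumerates every length-`T` symbol sequence, collapses it (merge
#' adjacent repeats, delete blanks) and sums the probabilities of paths
#' matching the label. Exponential; refuses `T > 8`. Serves as the
#' independent oracle for [ctc_loss()].
#'
#' @inheritParams ctc_loss
#' @return scalar `-log p(label | probs)`.
#' @export
ctc_bruteforce <- function(probs, label, blank_index = ncol(probs)) {
  T_ <- nrow(probs); K <- ncol(probs)
  if (T_ > 8) stop("brute-force enumeration refused for T > 8")
  if (any(label == blank_index)) stop("label must not contain the blank id")
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    path <- paths[i, ]
    collapsed <- rle(path)$values
    collapsed <- collapsed[collapsed != blank_index]
    if (length(collapsed) == length(label) && all(collapsed == label)) {
      total <- total + prod(probs[cbind(seq_len(T_), path)])
    }
  }
  if (total == 0) stop("label has zero probability (inadmissible for T)")
  -log(total)
}

ctc_collapse <- function(ids, blank_index) {
  collapsed <- rle(ids)$values
  collapsed[collapsed != blank_index]
}

#' Greedy (best-path) CTC decoding
#'
#' Per-row argmax, collapse of adjacent repeats, blank deletion, `<pad>`
#' deletion, then mapping ids to characters.
#'
#' @param probs `T x 29` matrix of per-frame character distributions.
#' @param alphabet a [build_alphabet()].
#' @return decoded text.
#' @export
greedy_decode <- function(probs, alphabet = build_alphabet()) {
  ids <- max.col(probs, ties.method = "first")
  decode_ids(ctc_collapse(ids, alphabet$blank_index), alphabet)
}

#' Prefix beam search CTC decoding
#'
#' Standard prefix beam search over collapsed prefixes, accumulating
#' blank/non-blank path mass per prefix. Deterministic: ties in total
#' probability are broken by lexicographic prefix order. With a wide beam
#' on small instances this returns the maximum-posterior collapsed string.
#' Note `beam_width = 1` follows the beam recursion and need not equal
#' greedy best-path decoding.
#'
#' @inheritParams greedy_decode
#' @param beam_width number of prefixes kept per step (>= 1).
#' @return decoded text.
#' @export
beam_decode <- function(probs, alphabet = build_alphabet(), beam_width = 8L) {
  stopifnot(beam_width >= 1L)
  blank <- alphabet$blank_index
  logp <- log(probs)
  T_ <- nrow(probs); K <- ncol(probs)
  beams <- list(list(prefix = integer(0), pb = 0, pnb = -Inf))
  # zero-padded keys so string order equals lexicographic sequence order;
  # "p" prefix keeps the empty prefix a valid environment name
  key <- function(prefix) paste0("p", paste(sprintf("%03d", prefix), collapse = ","))
  for (t in seq_len(T_)) {
    nxt <- new.env(parent = emptyenv())
    bump <- function(prefix, pb_add, pnb_add) {
      k <- key(prefix)
      cur <- if (exists(k, envir = nxt, inherits = FALSE)) get(k, envir = nxt)
             else list(prefix = prefix, pb = -Inf, pnb = -Inf)
      cur$pb <- logsumexp2(cur$pb, pb_add)
      cur$pnb <- logsumexp2(cur$pnb, pnb_add)
      assign(k, cur, envir = nxt)
    }
    for (bm in beams) {
      tot <- logsumexp2(bm$pb, bm$pnb)
      # blank keeps the prefix
      bump(bm$prefix, tot + logp[t, blank], -Inf)
      for (s in seq_len(K)) {
        if (s == blank) next
        last <- if (length(bm$prefix) > 0) bm$prefix[length(bm$prefix)] else 0L
        if (s == last) {
          # same symbol again: merges into the prefix unless a blank
          # intervened, in which case it extends it
          bump(bm$prefix, -Inf, bm$pnb + logp[t, s])
          bump(c(bm$prefix, s), -Inf, bm$pb + logp[t, s])
        } else {
          bump(c(bm$prefix, s), -Inf, tot + logp[t, s])
        }
      }
    }
    beams <- mget(ls(nxt), envir = nxt)
    score <- vapply(beams, function(b) logsumexp2(b$pb, b$pnb), numeric(1))
    keys <- vapply(beams, function(b) key(b$prefix), character(1))
    ord <- order(-score, keys)
    beams <- unname(beams[ord[seq_len(min(beam_width, length(beams)))]])
  }
  best <- beams[[1]]
  decode_ids(best$prefix, alphabet)
}
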