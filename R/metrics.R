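#' Levenshtein distance between two sequences
#'
#' Minimal number of insertions, deletions and substitutions transforming `a`
#' into `b` (no transpositions). Works on arbitrary atomic sequences, so the
#' same routine backs character error rate (character vectors), word error
#' rate (token vectors) and the spell corrector's candidate search.
#'
#' @param a,b atomic vectors (e.g. characters or word tokens).
#' @return non-negative integer distance.
#' @export
levenshtein <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0L) return(lb)
  if (lb == 0L) return(la)
  prev <- 0:lb
  cur <- integer(lb + 1L)
  for (i in seq_len(la)) {
    cur[1L] <- i
    for (j in seq_len(lb)) {
      cost <- if (a[[i]] == b[[j]]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[lb + 1L]
}

#' Levenshtein distance between two strings, character-wise
#'
#' @param a,b single strings.
#' @return integer distance.
#' @export
string_distance <- function(a, b) {
  levenshtein(strsplit(a, "", fixed = TRUE)[[1]], strsplit(b, "", fixed = TRUE)[[1]])
}

to_chars <- function(x) strsplit(x, "", fixed = TRUE)

to_words <- function(x) {
  lapply(strsplit(x, " ", fixed = TRUE), function(w) w[nzchar(w)])
}

error_report <- function(refs, hyps, units_ref, units_hyp, average) {
  edits <- mapply(levenshtein, units_hyp, units_ref)
  lens <- vapply(units_ref, length, integer(1))
  per_sample <- data.frame(
    reference = refs, hypothesis = hyps,
    edits = as.integer(edits), reference_units = lens,
    stringsAsFactors = FALSE
  )
  rate <- if (average == "micro") {
    sum(edits) / sum(lens)
  } else {
    mean(edits / lens)
  }
  structure(
    list(
      total_edits = sum(edits),
      total_reference_units = sum(lens),
      rate = rate,
      average = average,
      per_sample = per_sample
    ),
    class = "vsr_error_report"
  )
}

#' @export
print.vsr_error_report <- function(x, ...) {
  cat(sprintf(
    "<vsr_error_report> %s rate %.4f (%d edits / %d reference units, %d samples)\n",
    x$average, x$rate, x$total_edits, x$total_reference_units, nrow(x$per_sample)
  ))
  invisible(x)
}

check_pairs <- function(refs, hyps) {
  if (length(refs) != length(hyps)) {
    stop("refs and hyps must have equal length")
  }
  if (length(refs) == 0L) stop("empty evaluation set")
}

#' Character error rate
#'
#' Pooled (micro-averaged, default) or per-sentence (macro) character-level
#' Levenshtein edits divided by reference length. Texts are normalized with
#' [normalize_text()] first; spaces count as characters.
#'
#' @param refs,hyps character vectors of equal length.
#' @param average `"micro"` (pooled edits / pooled lengths) or `"macro"`.
#' @return a `vsr_error_report`; the `rate` element is a fraction (0.0833 for
#'   one edit over twelve reference characters).
#' @export
cer <- function(refs, hyps, average = c("micro", "macro")) {
  average <- match.arg(average)
  check_pairs(refs, hyps)
  refs <- normalize_text(refs); hyps <- normalize_text(hyps)
  error_report(refs, hyps, to_chars(refs), to_chars(hyps), average)
}

#' Word error rate
#'
#' Same aggregation as [cer()] over whitespace-delimited tokens.
#'
#' @inheritParams cer
#' @return a `vsr_error_report`.
#' @export
wer <- function(refs, hyps, average = c("micro", "macro")) {
  average <- match.arg(average)
  check_pairs(refs, hyps)
  refs <- normalize_text(refs); hyps <- normalize_text(hyps)
  error_report(refs, hyps, to_words(refs), to_words(hyps), average)
}
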