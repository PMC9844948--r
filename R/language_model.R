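#' Fit a unigram (bag-of-words) corpus
#'
#' Counts word occurrences over a sentence list after [normalize_text()]
#' normalization and whitespace tokenization. The resulting table drives the
#' edit-distance spell corrector applied to decoded sentences.
#'
#' @param sentences character vector with at least one non-empty sentence.
#' @return a `vsr_corpus`: named integer `counts`, `total` token count and
#'   `prob` (counts / total).
#' @export
fit_corpus <- function(sentences) {
  norm <- normalize_text(sentences)
  tokens <- unlist(to_words(norm), use.names = FALSE)
  if (length(tokens) == 0L) stop("empty corpus: no tokens after normalization")
  counts <- table(tokens)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(counts = counts, total = sum(counts), prob = counts / sum(counts)),
    class = "vsr_corpus"
  )
}

#' @export
print.vsr_corpus <- function(x, ...) {
  cat(sprintf("<vsr_corpus> %d distinct words, %d tokens\n",
              length(x$counts), x$total))
  invisible(x)
}

#' Candidate corpus words within a bounded edit distance
#'
#' Returns every corpus word whose Levenshtein distance (insertions,
#' deletions, substitutions; no transpositions) to `word` is at most `d`.
#' Computed by direct distance evaluation against the vocabulary, which is
#' equivalent to generating all d-edit variants and intersecting with the
#' corpus.
#'
#' @param word a single (normalized) word.
#' @param corpus a `vsr_corpus`.
#' @param d maximum edit distance, 1 or 2 (default 2).
#' @return character vector of candidate words (possibly empty).
#' @export
candidates <- function(word, corpus, d = 2) {
  stopifnot(d %in% c(1, 2))
  vocab <- names(corpus$counts)
  wc <- strsplit(word, "", fixed = TRUE)[[1]]
  keep <- vapply(vocab, function(v) {
    # length difference is a lower bound on the distance
    if (abs(nchar(v) - length(wc)) > d) return(FALSE)
    levenshtein(wc, strsplit(v, "", fixed = TRUE)[[1]]) <= d
  }, logical(1))
  unname(vocab[keep])
}

#' Correct a single word against the corpus
#'
#' Default selection (`selection = "distance-first"`): a word already in the
#' corpus is returned unchanged; otherwise, among candidates within distance
#' `d`, the minimal edit distance wins, ties broken by highest corpus
#' probability, then lexicographic order. `selection = "max-likelihood"`
#' instead picks the maximum-likelihood corpus word over all candidates
#' within distance `d` regardless of distance (which may rewrite rare
#' in-corpus words). Words with no candidates pass through unchanged.
#'
#' @param word single word (normalized).
#' @param corpus a `vsr_corpus`.
#' @param d maximum edit distance (default 2).
#' @param selection `"distance-first"` (default) or `"max-likelihood"`.
#' @return the corrected word.
#' @export
correct_word <- function(word, corpus, d = 2,
                         selection = c("distance-first", "max-likelihood")) {
  selection <- match.arg(selection)
  if (!nzchar(word)) return(word)
  in_corpus <- word %in% names(corpus$counts)
  if (selection == "distance-first" && in_corpus) return(word)
  cand <- candidates(word, corpus, d = d)
  if (length(cand) == 0L) return(word)
  if (selection == "max-likelihood") {
    p <- corpus$prob[cand]
    best <- cand[p == max(p)]
    return(sort(best)[1L])
  }
  wc <- strsplit(word, "", fixed = TRUE)[[1]]
  dist <- vapply(cand, function(v) {
    levenshtein(wc, strsplit(v, "", fixed = TRUE)[[1]])
  }, numeric(1))
  cand <- cand[dist == min(dist)]
  p <- corpus$prob[cand]
  best <- cand[p == max(p)]
  sort(best)[1L]
}

#' Spell-correct a sentence word by word
#'
#' Applies [correct_word()] to each whitespace token of the normalized
#' sentence; single-space word separation is restored on output.
#'
#' @param text sentence to correct.
#' @inheritParams correct_word
#' @return corrected sentence.
#' @export
correct_sentence <- function(text, corpus, d = 2,
                             selection = c("distance-first", "max-likelihood")) {
  selection <- match.arg(selection)
  norm <- normalize_text(text)
  if (!nzchar(norm)) return(norm)
  words <- strsplit(norm, " ", fixed = TRUE)[[1]]
  paste(vapply(words, correct_word, character(1),
               corpus = corpus, d = d, selection = selection),
        collapse = " ")
}

#' Persist / restore a unigram corpus as TSV
#'
#' Two tab-separated columns: word, count.
#'
#' @param corpus a `vsr_corpus`.
#' @param path file path.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` a
#'   `vsr_corpus`.
#' @export
write_corpus <- function(corpus, path) {
  utils::write.table(
    data.frame(word = names(corpus$counts), count = corpus$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"))
  counts <- stats::setNames(df$count, df$word)
  structure(
    list(counts = counts, total = sum(counts), prob = counts / sum(counts)),
    class = "vsr_corpus"
  )
}
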