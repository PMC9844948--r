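#' Character inventory for CTC transcription
#'
#' Builds the fixed 29-symbol alphabet used throughout the pipeline: the 26
#' lowercase English letters, whitespace, a padding character `<pad>` and the
#' CTC blank token `_`. The blank occupies the last index so that label
#' sequences (which never contain it) live in a contiguous prefix.
#'
#' @return An object of class `vsr_alphabet` with elements `symbols`
#'   (character vector of length 29), `index` (named integer map),
#'   `blank_index`, `pad_index` and `space_index`.
#' @examples
#' ab <- build_alphabet()
#' ab$size          # 29
#' ab$blank_index   # 29
#' @export
build_alphabet <- function() {
  symbols <- c(letters, " ", "<pad>", "_")
  index <- stats::setNames(seq_along(symbols), symbols)
  structure(
    list(
      symbols = symbols,
      index = index,
      size = length(symbols),
      space_index = index[[" "]],
      pad_index = index[["<pad>"]],
      blank_index = index[["_"]]
    ),
    class = "vsr_alphabet"
  )
}

#' Normalize free text to the transcription character set
#'
#' Lowercases, transliterates German umlauts and eszett (ä→ae, ö→oe, ü→ue,
#' ß→ss), drops every remaining character outside `a-z` and space, collapses
#' whitespace runs and trims. This is the single text-normalization policy
#' shared by transcript encoding, the unigram language model and the error
#' metrics.
#'
#' @param text character vector.
#' @return character vector of normalized text.
#' @export
normalize_text <- function(text) {
  x <- tolower(as.character(text))
  x <- gsub("ä", "ae", x, fixed = TRUE)
  x <- gsub("ö", "oe", x, fixed = TRUE)
  x <- gsub("ü", "ue", x, fixed = TRUE)
  x <- gsub("ß", "ss", x, fixed = TRUE)
  x <- gsub("[^a-z ]", "", x)
  x <- gsub(" +", " ", x)
  trimws(x)
}

#' Encode a transcript as label ids
#'
#' Applies [normalize_text()] and maps each character to its alphabet index.
#' The result never contains the blank or `<pad>` ids.
#'
#' @param text a single transcript string.
#' @param alphabet a `vsr_alphabet`, by default [build_alphabet()].
#' @return integer vector of label ids (1-based, in `1..27`).
#' @export
encode_transcript <- function(text, alphabet = build_alphabet()) {
  stopifnot(length(text) == 1L)
  norm <- normalize_text(text)
  if (!nzchar(norm)) {
    stop("unencodable transcript: no encodable characters in ", sQuote(text))
  }
  chars <- strsplit(norm, "", fixed = TRUE)[[1]]
  unname(alphabet$index[chars])
}

#' Decode label ids back to text
#'
#' Inverse of [encode_transcript()] for id sequences free of blank/`<pad>`;
#' blank and `<pad>` ids, if present, are dropped.
#'
#' @param ids integer vector of alphabet indices.
#' @param alphabet a `vsr_alphabet`.
#' @return a single string.
#' @export
decode_ids <- function(ids, alphabet = build_alphabet()) {
  ids <- ids[ids != alphabet$blank_index & ids != alphabet$pad_index]
  paste(alphabet$symbols[ids], collapse = "")
}
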