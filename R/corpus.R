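#' Split raw text into sentence spans
#'
#' Splits on the CJK and ASCII sentence terminators \code{。！？!?；;} and on
#' newlines. Terminators are dropped and empty spans removed. Splitting is
#' done *before* non-CJK stripping so that context windows never straddle a
#' sentence boundary.
#'
#' @param text character vector of raw text.
#' @return character vector of sentence spans, in input order.
#' @examples
#' split_sentences("伤寒初感。始于太阳。")
#' @export
split_sentences <- function(text) {
  if (length(text) == 0) return(character(0))
  stopifnot(is.character(text))
  spans <- unlist(strsplit(text, "[\u3002\uff01\uff1f!?\uff1b;\r\n]+"),
                  use.names = FALSE)
  if (is.null(spans)) return(character(0))
  spans[nzchar(spans)]
}

#' Retain CJK characters
#'
#' Keeps exactly the characters whose Unicode code point lies in the CJK
#' Unified Ideographs range \code{[U+4E00, U+9FA5]} (both bounds inclusive),
#' in original order; everything else — ASCII, punctuation, digits, other
#' scripts — is removed.
#'
#' @param span character vector.
#' @return character vector of the same length.
#' @examples
#' retain_cjk("伤寒, flu 123")
#' @export
retain_cjk <- function(span) {
  if (length(span) == 0) return(character(0))
  gsub("[^\u4e00-\u9fa5]", "", span, perl = TRUE)
}

#' Convert traditional characters to simplified
#'
#' Per-character table lookup; characters absent from the mapping pass
#' through unchanged, so length is preserved and the operation is
#' idempotent whenever the mapping's image is disjoint from its domain.
#'
#' @param span character vector.
#' @param mapping named character vector: `names(mapping)` are traditional
#'   characters, values their simplified forms (single characters each).
#'   See [read_simplify_map()].
#' @return character vector of the same length as `span`.
#' @export
to_simplified <- function(span, mapping) {
  if (length(span) == 0) return(character(0))
  if (is.null(mapping) || length(mapping) == 0) return(span)
  if (any(nchar(names(mapping)) != 1L) || any(nchar(mapping) != 1L))
    stop("mapping must be single character -> single character")
  vapply(span, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(ch) == 0) return(s)
    hit <- match(ch, names(mapping))
    ch[!is.na(hit)] <- unname(mapping[hit[!is.na(hit)]])
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Dictionary segmentation by forward maximum matching
#'
#' Walks the span left to right; at each position the longest lexicon entry
#' matching a prefix is taken, falling back to a single character when no
#' entry matches. Concatenating the returned tokens reproduces the span
#' exactly.
#'
#' @param span a single string of CJK characters.
#' @param lexicon character vector of dictionary words (non-empty).
#' @return character vector of tokens (a segmented sentence).
#' @examples
#' segment_words("伤寒初感",
#'               c("伤寒", "初感", "伤"))
#' @export
segment_words <- function(span, lexicon) {
  stopifnot(is.character(span), length(span) == 1L)
  if (length(lexicon) == 0) stop("lexicon must be non-empty")
  n <- nchar(span)
  if (n == 0L) return(character(0))
  maxlen <- max(nchar(lexicon))
  toks <- character(0)
  i <- 1L
  while (i <= n) {
    taken <- 1L
    len <- min(maxlen, n - i + 1L)
    while (len > 1L) {
      if (substr(span, i, i + len - 1L) %in% lexicon) { taken <- len; break }
      len <- len - 1L
    }
    toks <- c(toks, substr(span, i, i + taken - 1L))
    i <- i + taken
  }
  toks
}

#' Build a segmented corpus from raw documents
#'
#' Runs the cleaning pipeline per document:
#' [split_sentences()] then [retain_cjk()] then [to_simplified()] then
#' [segment_words()]. Tokens occurring fewer than `min_count` times are
#' excluded from the vocabulary but *retained in the sentences* — they still
#' occupy context-window positions downstream.
#'
#' @param docs character vector of raw document texts (optionally named by
#'   document id).
#' @param lexicon character vector of dictionary words for segmentation.
#' @param mapping optional traditional-to-simplified mapping
#'   (see [to_simplified()]).
#' @param min_count minimum token frequency for vocabulary membership.
#' @return a `cddf_corpus`: list with `sentences` (list of character token
#'   vectors), `vocab` (named integer frequencies, `>= min_count` only,
#'   decreasing), `n_tokens`, and `min_count`.
#' @export
build_corpus <- function(docs, lexicon, mapping = NULL, min_count = 1L) {
  stopifnot(is.character(docs), min_count >= 1)
  sentences <- list()
  for (d in docs) {
    spans <- split_sentences(d)
    spans <- retain_cjk(spans)
    spans <- to_simplified(spans, mapping)
    spans <- spans[nzchar(spans)]
    for (sp in spans) sentences[[length(sentences) + 1L]] <- segment_words(sp, lexicon)
  }
  if (length(sentences) == 0)
    warning("all documents empty after cleaning; corpus is empty")
  new_corpus(sentences, min_count = min_count)
}

#' Construct a corpus from pre-segmented sentences
#'
#' @param sentences list of character vectors (one per sentence).
#' @param min_count minimum token frequency for vocabulary membership.
#' @return a `cddf_corpus` (see [build_corpus()]).
#' @export
new_corpus <- function(sentences, min_count = 1L) {
  toks <- unlist(sentences, use.names = FALSE)
  if (length(toks) > 0 && any(!nzchar(toks)))
    stop("sentences must not contain empty tokens")
  counts <- if (length(toks)) table(toks) else table(character(0))
  freq <- as.integer(counts)
  names(freq) <- names(counts)
  freq <- freq[freq >= min_count]
  # deterministic order: decreasing frequency, then C-locale name
  if (length(freq))
    freq <- freq[order(-freq, names(freq), method = "radix")]
  structure(list(sentences = sentences, vocab = freq,
                 n_tokens = length(toks), min_count = as.integer(min_count)),
            class = "cddf_corpus")
}

#' @export
print.cddf_corpus <- function(x, ...) {
  cat(sprintf("<cddf_corpus> %d sentences, %d tokens, vocabulary %d (min_count %d)\n",
              length(x$sentences), x$n_tokens, length(x$vocab), x$min_count))
  invisible(x)
}

#' Write / read a segmented corpus
#'
#' One sentence per line, tokens space-separated, UTF-8.
#'
#' @param corpus a `cddf_corpus`.
#' @param path file path.
#' @rdname corpus_io
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus$sentences, paste, character(1), collapse = " ")
  writeLines(lines, con = path, useBytes = FALSE)
  invisible(path)
}

#' @param min_count minimum token frequency for the rebuilt vocabulary.
#' @rdname corpus_io
#' @export
read_corpus <- function(path, min_count = 1L) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  new_corpus(strsplit(lines, " ", fixed = TRUE), min_count = min_count)
}

#' Read a traditional-to-simplified mapping table
#'
#' TSV with two columns `traditional<TAB>simplified`, UTF-8, `#` comments.
#'
#' @param path file path.
#' @return named character vector usable with [to_simplified()].
#' @export
read_simplify_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character", fileEncoding = "UTF-8",
                          quote = "")
  if (ncol(df) < 2) stop("expected two tab-separated columns")
  setNames(df[[2]], df[[1]])
}

#' Read a segmentation lexicon
#'
#' One entry per line (or the first tab-separated column), UTF-8,
#' `#` comments.
#'
#' @param path file path.
#' @return character vector of dictionary words.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L))
}
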