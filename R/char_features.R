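#' Construct a character feature table
#'
#' Per-character stroke, structure and pinyin codes used to build subword
#' features. Codes follow the SSP2VEC code book conventions: the stroke code
#' is a non-empty digit string (one digit per ordered pen stroke), the
#' structure code is exactly two digits (spatial composition class, treated
#' as opaque), and the pinyin code is one or more lowercase letters followed
#' by a single uppercase tone letter (e.g. `taiD`).
#'
#' @param char character vector of single CJK characters.
#' @param stroke,structure,pinyin character vectors of codes, parallel to
#'   `char`.
#' @return a `cddf_feature_table`.
#' @export
feature_table <- function(char, stroke, structure, pinyin) {
  stopifnot(length(char) == length(stroke),
            length(char) == length(structure),
            length(char) == length(pinyin))
  if (any(nchar(char) != 1L)) stop("table keys must be single characters")
  if (anyDuplicated(char)) stop("duplicate characters in feature table")
  bad <- !grepl("^[0-9]+$", stroke)
  if (any(bad)) stop("invalid stroke code for: ", paste(char[bad], collapse = " "))
  bad <- !grepl("^[0-9]{2}$", structure)
  if (any(bad)) stop("invalid structure code for: ", paste(char[bad], collapse = " "))
  bad <- !grepl("^[a-z]+[A-Z]$", pinyin)
  if (any(bad)) stop("invalid pinyin code for: ", paste(char[bad], collapse = " "))
  structure(list(stroke = setNames(stroke, char),
                 structure = setNames(structure, char),
                 pinyin = setNames(pinyin, char)),
            class = "cddf_feature_table")
}

#' @export
print.cddf_feature_table <- function(x, ...) {
  cat(sprintf("<cddf_feature_table> %d characters\n", length(x$stroke)))
  invisible(x)
}

#' @export
as.data.frame.cddf_feature_table <- function(x, ...) {
  data.frame(char = names(x$stroke), stroke = unname(x$stroke),
             structure = unname(x$structure), pinyin = unname(x$pinyin),
             stringsAsFactors = FALSE)
}

#' Read a character feature table from TSV
#'
#' Format: `char<TAB>stroke<TAB>structure<TAB>pinyin`, UTF-8, `#` comments.
#'
#' @param path file path.
#' @return a `cddf_feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character", fileEncoding = "UTF-8",
                          quote = "")
  if (ncol(df) < 4) stop("expected four tab-separated columns")
  feature_table(df[[1]], df[[2]], df[[3]], df[[4]])
}

#' Write a character feature table to TSV
#'
#' @param table a `cddf_feature_table`.
#' @param path file path.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  lines <- paste(df$char, df$stroke, df$structure, df$pinyin, sep = "\t")
  writeLines(lines, con = path)
  invisible(path)
}

#' Encode a word as its stroke/structure/pinyin code sequence
#'
#' Concatenates, character by character in word order, each character's
#' stroke code, then its structure code, then its pinyin code. No boundary
#' markers are inserted between characters.
#'
#' @param word a single token.
#' @param table a `cddf_feature_table` covering every character of `word`.
#' @return the code sequence as a single string.
#' @examples
#' tab <- feature_table(c("太", "阳"),
#'                      c("1344", "522511"), c("96", "66"),
#'                      c("taiD", "yangB"))
#' encode_word("太阳", tab)  # "134496taiD52251166yangB"
#' @export
encode_word <- function(word, table) {
  stopifnot(is.character(word), length(word) == 1L)
  if (!inherits(table, "cddf_feature_table")) stop("not a cddf_feature_table")
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  if (length(ch) == 0) return("")
  miss <- unique(ch[!(ch %in% names(table$stroke))])
  if (length(miss))
    stop(errorCondition(
      paste0("character(s) missing from feature table: ",
             paste(miss, collapse = " ")),
      chars = miss, class = "cddf_unknown_char"))
  paste0(table$stroke[ch], table$structure[ch], table$pinyin[ch],
         collapse = "")
}

#' All sliding-window feature substrings of a code sequence
#'
#' For every window length `n` in `[n_min, n_max]`, every contiguous
#' substring of that length is emitted, in position order, as a multiset
#' (repeated substrings are kept as distinct occurrences). With `n_min = 1`
#' and `n_max = L` (the sequence length) the result has `L(L+1)/2`
#' elements.
#'
#' @param seq a code sequence string (see [encode_word()]).
#' @param n_min,n_max window length range; `n_max` greater than the sequence
#'   length is clamped (with a message).
#' @return character vector of substrings.
#' @export
feature_substrings <- function(seq, n_min = 1L, n_max = nchar(seq)) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (L == 0L) return(character(0))
  if (n_max > L) {
    message(sprintf("n_max (%d) clamped to sequence length %d", n_max, L))
    n_max <- L
  }
  stopifnot(n_min >= 1L, n_min <= n_max)
  unlist(lapply(n_min:n_max,
                function(n) substring(seq, 1:(L - n + 1L), n:L)),
         use.names = FALSE)
}

#' Hash a feature substring into a bucket
#'
#' Deterministic, platform-stable FNV-1a (32-bit) over the UTF-8 bytes of
#' the substring, reduced modulo `B`. Collisions are accepted; `B` bounds
#' the input parameter matrix of the embedding model.
#'
#' @param substring character vector of substrings.
#' @param B number of buckets (`>= 1`).
#' @return integer vector of bucket ids in `[0, B)`.
#' @export
hash_bucket <- function(substring, B) {
  cpp_fnv1a_bucket(as.character(substring), as.integer(B))
}

#' Bucket ids for all feature substrings of a word
#'
#' Convenience composition of [encode_word()], [feature_substrings()] and
#' [hash_bucket()]. Duplicated substrings keep their multiplicity, matching
#' the mean-of-substring-rows word representation used in training.
#'
#' @inheritParams encode_word
#' @param n_min,n_max window length range (`n_max` clamped to the sequence
#'   length).
#' @param B number of hash buckets.
#' @return integer vector of bucket ids in `[0, B)`.
#' @export
word_buckets <- function(word, table, n_min = 1L, n_max = 12L, B = 2^21) {
  seq <- encode_word(word, table)
  subs <- feature_substrings(seq, n_min, min(n_max, nchar(seq)))
  hash_bucket(subs, B)
}
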