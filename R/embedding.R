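#' Training configuration for the embedding model
#'
#' @param dim embedding dimension.
#' @param window context width `c`: number of words taken on each side of
#'   the target, truncated at sentence boundaries.
#' @param epochs passes over the corpus.
#' @param alpha initial learning rate, decayed linearly to `alpha * 1e-4`
#'   over training.
#' @param negative number of negative samples `k` per positive pair, drawn
#'   from the unigram distribution raised to 0.75. `0` selects exact
#'   softmax (tractable only for small vocabularies; used by the gradient
#'   oracle).
#' @param n_min,n_max sliding-window length range for feature substrings.
#'   `n_max` is a cap; sequences shorter than the cap use their full
#'   length.
#' @param buckets number of hash buckets `B` for substring features. `0`
#'   disables substring features entirely, so every word falls back to a
#'   dedicated whole-word input row.
#' @param min_count minimum token frequency for vocabulary membership;
#'   rarer tokens keep their sentence positions but are never predicted as
#'   contexts.
#' @param seed integer seed controlling initialization and negative
#'   sampling; identical configuration and seed give bitwise-identical
#'   matrices.
#' @param mode `"ssp2vec"` (subword feature substrings) or `"csg"`
#'   (continuous skip-gram baseline: one input row per vocabulary word, no
#'   subword features).
#' @param aggregate how substring rows combine into a word representation:
#'   `"mean"` (default; scale-stable as substring counts vary) or `"sum"`.
#' @return a `cddf_config` list.
#' @export
training_config <- function(dim = 100L, window = 2L, epochs = 5L,
                            alpha = 0.025, negative = 5L,
                            n_min = 1L, n_max = 12L, buckets = 2^21,
                            min_count = 1L, seed = 1L,
                            mode = c("ssp2vec", "csg"),
                            aggregate = c("mean", "sum")) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  stopifnot(dim >= 1, window >= 1, epochs >= 0, alpha > 0,
            negative >= 0, n_min >= 1, n_max >= n_min, buckets >= 0,
            min_count >= 1)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 epochs = as.integer(epochs), alpha = alpha,
                 negative = as.integer(negative),
                 n_min = as.integer(n_min), n_max = as.integer(n_max),
                 buckets = as.integer(buckets),
                 min_count = as.integer(min_count),
                 seed = as.integer(seed), mode = mode,
                 aggregate = aggregate),
            class = "cddf_config")
}

#' Enumerate skip-gram training pairs
#'
#' For each sentence position `t`, emits `(w_t, w_(t+j))` for
#' `j in [-window, window], j != 0`, truncated at sentence boundaries;
#' windows never cross sentences. No vocabulary filtering is applied here.
#'
#' @param corpus a `cddf_corpus`.
#' @param window context width (words each side).
#' @return two-column character matrix with columns `target`, `context`.
#' @export
training_pairs <- function(corpus, window) {
  stopifnot(inherits(corpus, "cddf_corpus"), window >= 1)
  out <- lapply(corpus$sentences, function(s) {
    len <- length(s)
    if (len < 2) return(NULL)
    tt <- character(0); cc <- character(0)
    for (t in seq_len(len)) {
      lo <- max(1L, t - window); hi <- min(len, t + window)
      ctx <- setdiff(lo:hi, t)
      tt <- c(tt, rep(s[t], length(ctx)))
      cc <- c(cc, s[ctx])
    }
    cbind(tt, cc)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- matrix(character(0), ncol = 2)
  colnames(out) <- c("target", "context")
  out
}

# --- internal: token table construction shared by both training modes -----

# Returns list(tokens, tok_inputs (0-based row lists), tok_ctx (0-based or
# -1), vocab, freq, n_input, fallback (named 0-based rows)).
build_token_maps <- function(corpus, table, config) {
  toks <- unlist(corpus$sentences, use.names = FALSE)
  if (length(toks) == 0) stop("corpus has no tokens")
  counts <- table(toks)
  all_tokens <- names(counts)
  freq_all <- as.integer(counts)
  keep <- freq_all >= config$min_count
  vocab <- all_tokens[keep]
  freq <- freq_all[keep]
  if (length(vocab) == 0) stop("vocabulary empty after min_count filtering")
  ord <- order(-freq, vocab, method = "radix")
  vocab <- vocab[ord]; freq <- freq[ord]
  tok_ctx <- match(all_tokens, vocab)
  tok_ctx[is.na(tok_ctx)] <- 0L
  tok_ctx <- tok_ctx - 1L  # 0-based, -1 = out of vocabulary

  fallback <- integer(0)
  if (config$mode == "csg") {
    n_input <- length(vocab)
    tok_inputs <- lapply(tok_ctx, function(i) if (i >= 0) i else integer(0))
  } else {
    B <- config$buckets
    tok_inputs <- vector("list", length(all_tokens))
    fb_words <- character(0)
    # visit vocabulary words first, in vocabulary (frequency) order, so that
    # fallback rows line up with the csg baseline's per-word rows
    visit <- c(match(vocab, all_tokens),
               setdiff(seq_along(all_tokens), match(vocab, all_tokens)))
    for (i in visit) {
      w <- all_tokens[i]
      rows <- NULL
      if (B > 0 && !is.null(table)) {
        rows <- tryCatch(word_buckets(w, table, config$n_min, config$n_max, B),
                         cddf_unknown_char = function(e) NULL)
      }
      if (is.null(rows)) {
        # whole-word fallback row, appended after the bucket block
        fb_words <- c(fb_words, w)
        rows <- B + length(fb_words) - 1L
      }
      tok_inputs[[i]] <- as.integer(rows)
    }
    fallback <- setNames(B + seq_along(fb_words) - 1L, fb_words)
    n_input <- B + length(fb_words)
  }
  sent_ids <- lapply(corpus$sentences,
                     function(s) match(s, all_tokens) - 1L)
  list(tokens = all_tokens, tok_inputs = tok_inputs, tok_ctx = tok_ctx,
       vocab = vocab, freq = freq, n_input = as.integer(n_input),
       fallback = fallback, sent_ids = sent_ids)
}

# word2vec-style deterministic unigram^0.75 noise table (0-based ctx rows)
build_neg_table <- function(freq, size = 1e5L) {
  p <- freq^0.75
  p <- p / sum(p)
  reps <- diff(c(0L, round(cumsum(p) * size)))
  reps[reps < 0L] <- 0L
  as.integer(rep(seq_along(freq) - 1L, times = reps))
}

#' Train a subword (or whole-word) skip-gram embedding
#'
#' Trains the model on a segmented corpus. In `ssp2vec` mode each target
#' word is represented by the mean (or sum) of the hashed-bucket rows of
#' all sliding-window substrings of its stroke/structure/pinyin code
#' sequence; words containing characters absent from the feature table get
#' a dedicated whole-word input row instead of being dropped. In `csg` mode
#' every vocabulary word has its own input row and no subword features are
#' used. The objective is the negative log-likelihood of context words
#' within width `window` given the target representation, optimized by SGD
#' — exact softmax when `negative = 0`, negative sampling otherwise.
#' Training is single-threaded and bitwise-deterministic given the seed.
#'
#' @param corpus a `cddf_corpus`.
#' @param table a `cddf_feature_table` (required in `ssp2vec` mode unless
#'   `buckets = 0`).
#' @param config a [training_config()].
#' @return a `cddf_embedding`: list with `input` (input-side matrix),
#'   `context` (context matrix, one row per vocabulary word — these are the
#'   semantic vectors `u_t` used downstream), `vocab`, `freq`, `fallback`,
#'   `epoch_loss`, `config`, `table`.
#' @export
train_embedding <- function(corpus, table = NULL, config = training_config()) {
  stopifnot(inherits(corpus, "cddf_corpus"), inherits(config, "cddf_config"))
  if (config$mode == "ssp2vec" && is.null(table) && config$buckets > 0)
    stop("ssp2vec mode needs a feature table (or buckets = 0 for whole-word rows)")
  maps <- build_token_maps(corpus, table, config)
  init <- cpp_init_embedding(maps$n_input, length(maps$vocab),
                             config$dim, config$seed)
  if (config$epochs == 0L) {
    fit <- list(input = init$input, context = init$context,
                epoch_loss = numeric(0))
  } else if (config$negative == 0L) {
    fit <- train_softmax_r(maps, init, config)
  } else {
    neg <- build_neg_table(maps$freq)
    fit <- cpp_train_sgns(maps$sent_ids, maps$tok_inputs, maps$tok_ctx,
                          init$input, init$context,
                          config$window, config$epochs, config$alpha,
                          config$negative, neg, config$seed,
                          as.integer(config$aggregate == "mean"))
  }
  if (!all(is.finite(fit$input)) || !all(is.finite(fit$context)))
    stop("non-finite parameters after training; try a smaller alpha (final epoch losses: ",
         paste(signif(utils::tail(fit$epoch_loss, 3), 4), collapse = ", "), ")")
  rownames(fit$context) <- maps$vocab
  structure(list(input = fit$input, context = fit$context,
                 vocab = maps$vocab, freq = setNames(maps$freq, maps$vocab),
                 fallback = maps$fallback,
                 epoch_loss = as.numeric(fit$epoch_loss),
                 config = config, table = table),
            class = "cddf_embedding")
}

#' @export
print.cddf_embedding <- function(x, ...) {
  cat(sprintf("<cddf_embedding> mode %s, dim %d, vocabulary %d, input rows %d\n",
              x$config$mode, x$config$dim, length(x$vocab), nrow(x$input)))
  if (length(x$epoch_loss))
    cat(sprintf("  mean pair loss: first epoch %.4f, last epoch %.4f\n",
                x$epoch_loss[1], x$epoch_loss[length(x$epoch_loss)]))
  invisible(x)
}

# Exact-softmax SGD in R; tractable for oracle-sized vocabularies only.
train_softmax_r <- function(maps, init, config) {
  A <- init$input; U <- init$context
  dim <- config$dim; window <- config$window
  mean_agg <- config$aggregate == "mean"
  n_pairs <- 0L
  for (s in maps$sent_ids) {
    len <- length(s)
    if (len < 2) next
    for (t in seq_len(len)) {
      if (length(maps$tok_inputs[[s[t] + 1L]]) == 0) next
      lo <- max(1L, t - window); hi <- min(len, t + window)
      for (p in setdiff(lo:hi, t))
        if (maps$tok_ctx[s[p] + 1L] >= 0) n_pairs <- n_pairs + 1L
    }
  }
  total <- n_pairs * config$epochs
  if (total == 0)
    return(list(input = A, context = U, epoch_loss = numeric(0)))
  processed <- 0
  epoch_loss <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    loss_sum <- 0; loss_n <- 0L
    for (s in maps$sent_ids) {
      len <- length(s)
      if (len < 2) next
      for (t in seq_len(len)) {
        rows <- maps$tok_inputs[[s[t] + 1L]] + 1L
        if (length(rows) == 0) next
        lo <- max(1L, t - window); hi <- min(len, t + window)
        for (p in setdiff(lo:hi, t)) {
          o <- maps$tok_ctx[s[p] + 1L] + 1L
          if (o == 0L) next
          lr <- max(config$alpha * (1 - processed / total),
                    config$alpha * 1e-4)
          h <- if (mean_agg) colMeans(A[rows, , drop = FALSE])
               else colSums(A[rows, , drop = FALSE])
          sc <- drop(U %*% h)
          m <- max(sc)
          lse <- m + log(sum(exp(sc - m)))
          loss_sum <- loss_sum + (lse - sc[o])
          pr <- exp(sc - lse)
          gl <- pr; gl[o] <- gl[o] - 1
          gh <- drop(crossprod(U, gl))
          U <- U - lr * tcrossprod(gl, h)
          scale <- if (mean_agg) 1 / length(rows) else 1
          for (r in rows) A[r, ] <- A[r, ] - lr * gh * scale
          processed <- processed + 1
          loss_n <- loss_n + 1L
        }
      }
    }
    epoch_loss[ep] <- loss_sum / loss_n
  }
  list(input = A, context = U, epoch_loss = epoch_loss)
}

#' Exact softmax pair loss and gradient
#'
#' Negative log-likelihood of one (target, context) pair under the exact
#' softmax output layer, with the target represented as the mean (or sum)
#' of the given input rows, and its analytic gradient. These are the
#' quantities stepped by the `negative = 0` training path; exposed so the
#' gradient can be validated against finite differences.
#'
#' @param input input-side parameter matrix.
#' @param context context (output) matrix, one row per vocabulary word.
#' @param rows 1-based input rows representing the target word.
#' @param o 1-based context row of the observed context word.
#' @param aggregate `"mean"` or `"sum"`.
#' @return `exact_softmax_loss`: the scalar loss `log-sum-exp(scores) -
#'   score[o]`. `exact_softmax_grad`: list with `d_input` (gradient shared
#'   by each of `rows`) and `d_context` (full gradient matrix).
#' @export
exact_softmax_loss <- function(input, context, rows, o, aggregate = "mean") {
  h <- if (aggregate == "mean") colMeans(input[rows, , drop = FALSE])
       else colSums(input[rows, , drop = FALSE])
  sc <- drop(context %*% h)
  m <- max(sc)
  (m + log(sum(exp(sc - m)))) - sc[o]
}

#' @rdname exact_softmax_loss
#' @export
exact_softmax_grad <- function(input, context, rows, o, aggregate = "mean") {
  h <- if (aggregate == "mean") colMeans(input[rows, , drop = FALSE])
       else colSums(input[rows, , drop = FALSE])
  sc <- drop(context %*% h)
  m <- max(sc)
  lse <- m + log(sum(exp(sc - m)))
  pr <- exp(sc - lse)
  gl <- pr; gl[o] <- gl[o] - 1
  gh <- drop(crossprod(context, gl))
  scale <- if (aggregate == "mean") 1 / length(rows) else 1
  list(d_input = gh * scale, d_context = tcrossprod(gl, h))
}

#' Input-side representation of a word
#'
#' In `ssp2vec` mode, the mean (or sum, per the model's configuration) of
#' the hashed substring rows of the word's code sequence — or the word's
#' dedicated fallback row when it was unencodable at training time. In
#' `csg` mode, the word's own input row.
#'
#' @param model a `cddf_embedding`.
#' @param word a single token.
#' @return numeric vector of length `dim`.
#' @export
word_representation <- function(model, word) {
  stopifnot(inherits(model, "cddf_embedding"))
  cfg <- model$config
  if (cfg$mode == "csg") {
    i <- match(word, model$vocab)
    if (is.na(i)) stop("out-of-vocabulary word: ", word)
    return(model$input[i, ])
  }
  if (word %in% names(model$fallback))
    return(model$input[model$fallback[[word]] + 1L, ])
  if (is.null(model$table) || cfg$buckets == 0)
    stop("out-of-vocabulary word (no feature table / buckets): ", word)
  rows <- tryCatch(
    word_buckets(word, model$table, cfg$n_min, cfg$n_max, cfg$buckets),
    cddf_unknown_char = function(e)
      stop("out-of-vocabulary word (unencodable): ", word))
  v <- colMeans(model$input[rows + 1L, , drop = FALSE])
  if (cfg$aggregate == "sum") v <- v * length(rows)
  v
}

#' Output semantic vectors
#'
#' Returns the *context-matrix* rows `u_t` for every vocabulary word: the
#' context side, not the input side, is the semantic vector set that feeds
#' the drug network.
#'
#' @param model a `cddf_embedding`.
#' @param side `"context"` (default) or `"input"` (input-side
#'   representations, for comparison experiments).
#' @return numeric matrix, one named row per vocabulary word.
#' @export
output_vectors <- function(model, side = c("context", "input")) {
  stopifnot(inherits(model, "cddf_embedding"))
  side <- match.arg(side)
  if (side == "context") return(model$context)
  m <- t(vapply(model$vocab, function(w) word_representation(model, w),
                numeric(model$config$dim)))
  rownames(m) <- model$vocab
  m
}

#' Export / import word vectors in word2vec text format
#'
#' Header line `N dim`, then one `word v1 ... vdim` line per word, UTF-8,
#' six decimal places; the round trip is exact to `1e-6`.
#'
#' @param vectors numeric matrix with one named row per word.
#' @param path file path.
#' @rdname vector_io
#' @export
export_vectors <- function(vectors, path) {
  stopifnot(is.matrix(vectors))
  vals <- apply(vectors, 1L, function(v)
    paste(sprintf("%.6f", v), collapse = " "))
  lines <- c(paste(nrow(vectors), ncol(vectors)),
             if (nrow(vectors)) paste(rownames(vectors), vals))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con = con)
  invisible(path)
}

#' @rdname vector_io
#' @export
import_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop("empty vector file")
  hdr <- strsplit(trimws(lines[1]), " +")[[1]]
  if (length(hdr) != 2 || anyNA(suppressWarnings(as.integer(hdr))))
    stop("malformed header at line 1: ", lines[1])
  n <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != n)
    stop(sprintf("header says %d rows but file has %d", n, length(body)))
  if (n == 0)
    return(matrix(numeric(0), nrow = 0, ncol = d))
  parts <- strsplit(body, " +")
  bad <- which(lengths(parts) != d + 1L)
  if (length(bad))
    stop(sprintf("malformed row at line %d: expected %d fields, found %d",
                 bad[1] + 1L, d + 1L, lengths(parts)[bad[1]]))
  words <- vapply(parts, `[[`, character(1), 1L)
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  if (anyNA(m)) stop("non-numeric vector entries")
  rownames(m) <- words
  m
}
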