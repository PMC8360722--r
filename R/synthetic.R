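#' Design for a planted-community synthetic corpus
#'
#' Describes a corpus in which groups of drug tokens co-occur with
#' group-specific context tokens, so that embeddings (and the downstream
#' drug network) should cluster by group. Defaults are the validation
#' conditions used throughout the test suite: 3 groups of 8 drugs with 10
#' context words each, 500 sentences of 3 drugs apiece, no cross-group
#' noise.
#'
#' @param n_groups number of planted groups.
#' @param drugs_per_group drug tokens per group.
#' @param context_words_per_group context tokens per group.
#' @param n_sentences sentences to generate.
#' @param drugs_per_sentence drugs sampled (without replacement) per
#'   sentence.
#' @param noise_rate probability that a sentence has one of its drugs
#'   replaced by a drug from a different group.
#' @param seed integer seed.
#' @return a `cddf_design` list.
#' @export
planted_design <- function(n_groups = 3L, drugs_per_group = 8L,
                           context_words_per_group = 10L,
                           n_sentences = 500L, drugs_per_sentence = 3L,
                           noise_rate = 0, seed = 1L) {
  stopifnot(n_groups >= 1, drugs_per_group >= 1,
            context_words_per_group >= 1, n_sentences >= 1,
            drugs_per_sentence >= 1,
            drugs_per_sentence <= drugs_per_group,
            noise_rate >= 0, noise_rate < 1)
  if (n_groups < 2 && noise_rate > 0)
    stop("cross-group noise needs at least two groups")
  structure(list(n_groups = as.integer(n_groups),
                 drugs_per_group = as.integer(drugs_per_group),
                 context_words_per_group = as.integer(context_words_per_group),
                 n_sentences = as.integer(n_sentences),
                 drugs_per_sentence = as.integer(drugs_per_sentence),
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "cddf_design")
}

# Synthetic token names: two-character words from a reserved CJK sub-range
# (per-group blocks starting at U+7A00), so they never collide with the
# packaged real-character fixtures.
synth_tokens <- function(group, n, offset) {
  base <- 0x7A00 + (group - 1L) * 0x100 + offset
  vapply(seq_len(n), function(i)
    intToUtf8(c(base + 2L * (i - 1L), base + 2L * i - 1L)), character(1))
}

#' Generate a synthetic corpus with planted drug communities
#'
#' Each sentence picks a group, samples `drugs_per_sentence` of its drugs
#' (one replaced by a drug from another group with probability
#' `noise_rate`) and interleaves them with context words of the same
#' group: `c1 d1 c2 d2 ... c(m+1)`. Deterministic given the design seed.
#'
#' @param design a [planted_design()].
#' @return list with `corpus` (a `cddf_corpus`), `truth` (named integer
#'   group ids for `drugs` and `contexts`), and `design`.
#' @export
gen_planted_corpus <- function(design = planted_design()) {
  stopifnot(inherits(design, "cddf_design"))
  drugs <- lapply(seq_len(design$n_groups), function(g)
    synth_tokens(g, design$drugs_per_group, 0L))
  ctxs <- lapply(seq_len(design$n_groups), function(g)
    synth_tokens(g, design$context_words_per_group,
                 2L * design$drugs_per_group))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(design$seed)
  m <- design$drugs_per_sentence
  sentences <- vector("list", design$n_sentences)
  grp <- sample.int(design$n_groups, design$n_sentences, replace = TRUE)
  for (i in seq_len(design$n_sentences)) {
    g <- grp[i]
    ds <- sample(drugs[[g]], m)
    if (design$noise_rate > 0 && runif(1) < design$noise_rate) {
      og <- sample(setdiff(seq_len(design$n_groups), g), 1L)
      ds[sample.int(m, 1L)] <- sample(drugs[[og]], 1L)
    }
    cs <- sample(ctxs[[g]], m + 1L, replace = TRUE)
    sent <- character(2L * m + 1L)
    sent[seq(1L, 2L * m + 1L, by = 2L)] <- cs
    sent[seq(2L, 2L * m, by = 2L)] <- ds
    sentences[[i]] <- sent
  }
  truth_drugs <- setNames(rep(seq_len(design$n_groups),
                              each = design$drugs_per_group),
                          unlist(drugs))
  truth_ctx <- setNames(rep(seq_len(design$n_groups),
                            each = design$context_words_per_group),
                        unlist(ctxs))
  list(corpus = new_corpus(sentences), design = design,
       truth = list(drugs = truth_drugs, contexts = truth_ctx))
}

#' Generate a synthetic character feature table
#'
#' Assigns every character of the given tokens a random digit stroke code
#' (length 1–8), a two-digit structure code and a lowercase-plus-tone
#' pinyin code, shaped like real code-book entries. When `groups` is
#' supplied (named group id per token), characters of the same group share
#' a leading two-digit stroke prefix — a synthetic "radical" — so subword
#' features carry group signal.
#'
#' @param tokens character vector of CJK tokens.
#' @param seed integer seed.
#' @param groups optional named integer vector `token -> group id`.
#' @return a `cddf_feature_table`.
#' @export
gen_feature_table <- function(tokens, seed = 1L, groups = NULL) {
  chars <- unique(unlist(strsplit(tokens, "", fixed = TRUE)))
  cp <- utf8ToInt(paste(chars, collapse = ""))
  if (any(cp < 0x4E00 | cp > 0x9FA5))
    stop("tokens must be CJK characters in [U+4E00, U+9FA5]")
  char_group <- rep(NA_integer_, length(chars))
  if (!is.null(groups)) {
    for (tk in names(groups)) {
      for (ch in strsplit(tk, "", fixed = TRUE)[[1]]) {
        i <- match(ch, chars)
        if (is.na(char_group[i])) char_group[i] <- groups[[tk]]
      }
    }
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  gids <- sort(unique(char_group[!is.na(char_group)]))
  prefixes <- setNames(sprintf("%02d", sample(10:99, length(gids))),
                       as.character(gids))
  stroke <- vapply(seq_along(chars), function(i) {
    if (!is.na(char_group[i])) {
      extra <- sample(0:6, 1L)
      paste0(prefixes[[as.character(char_group[i])]],
             paste(sample(0:9, extra, replace = TRUE), collapse = ""))
    } else {
      paste(sample(0:9, sample(1:8, 1L), replace = TRUE), collapse = "")
    }
  }, character(1))
  struct <- sprintf("%02d", sample(0:99, length(chars), replace = TRUE))
  pinyin <- vapply(seq_along(chars), function(i)
    paste0(paste(sample(letters, sample(2:5, 1L), replace = TRUE),
                 collapse = ""),
           sample(LETTERS[1:4], 1L)), character(1))
  feature_table(chars, stroke, struct, pinyin)
}

#' The worked COPRA update example
#'
#' The toy label-propagation state used to illustrate one COPRA node
#' update: a node receives six unit-coefficient labels from its
#' neighbours — yellow three times, pink twice, green once — and the
#' retention threshold is `r = 2`. Normalization gives coefficients 3/6,
#' 2/6 and 1/6; pink and green fall strictly below `1/r = 1/2` and are
#' removed, leaving the single yellow label.
#'
#' @return list with `node` (the drug name in the illustration),
#'   `neighbor_labels` (six single-entry label maps), and `r`.
#' @export
fig5_toy_state <- function() {
  lab <- function(nm) setNames(1.0, nm)
  list(node = "麦冬",
       neighbor_labels = list(lab("yellow"), lab("yellow"), lab("yellow"),
                              lab("pink"), lab("pink"), lab("green")),
       r = 2L)
}

#' Best-match purity of detected communities against planted groups
#'
#' Over major communities only: the sum over communities of the largest
#' overlap with any planted group, divided by the summed community sizes.
#' Members absent from the ground truth count in the denominator.
#'
#' @param communities a `cddf_communities`.
#' @param truth named integer vector `drug -> planted group id`.
#' @param major_only restrict to major communities (default `TRUE`).
#' @return purity in `[0, 1]` (`NaN` when no community qualifies).
#' @export
community_purity <- function(communities, truth, major_only = TRUE) {
  stopifnot(inherits(communities, "cddf_communities"))
  keep <- if (major_only) communities$major else
    rep(TRUE, length(communities$communities))
  comms <- communities$communities[keep]
  tot <- 0L; hit <- 0L
  for (m in comms) {
    tot <- tot + length(m)
    g <- truth[m]
    g <- g[!is.na(g)]
    if (length(g)) hit <- hit + max(table(g))
  }
  hit / tot
}
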