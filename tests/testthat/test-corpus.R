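test_that("sentence splitting keeps spans, drops terminators and empties", {
  expect_equal(split_sentences("伤寒初感。始于太阳。"),
               c("伤寒初感", "始于太阳"))
  expect_equal(split_sentences(""), character(0))
  expect_equal(split_sentences("abc"), "abc")
  expect_equal(split_sentences("一句！二句？三句；四句\n五句"),
               c("一句", "二句", "三句", "四句", "五句"))
})

test_that("CJK retention keeps exactly [U+4E00, U+9FA5], in order", {
  expect_equal(retain_cjk("伤寒, flu 123"), "伤寒")
  expect_equal(retain_cjk("ABC123!?"), "")
  # inclusive lower bound; U+9FA6 is just out of range
  expect_equal(retain_cjk(paste0(intToUtf8(0x4E00), intToUtf8(0x9FA6))),
               intToUtf8(0x4E00))
  expect_equal(retain_cjk(intToUtf8(0x9FA5)), intToUtf8(0x9FA5))
  # idempotent
  x <- "太阳abc发汗123"
  expect_identical(retain_cjk(retain_cjk(x)), retain_cjk(x))
})

test_that("simplification is a per-character lookup, unmapped pass through", {
  expect_equal(to_simplified("醫", c("醫" = "医")), "医")
  expect_equal(to_simplified("伤寒", character(0)), "伤寒")
  expect_equal(to_simplified("醫藥", c("醫" = "医", "藥" = "药")), "医药")
  # length preserved and idempotent when image is disjoint from domain
  m <- c("醫" = "医", "藥" = "药")
  x <- "醫治藥石"
  expect_equal(nchar(to_simplified(x, m)), nchar(x))
  expect_identical(to_simplified(to_simplified(x, m), m), to_simplified(x, m))
})

test_that("forward maximum matching takes longest match with 1-char fallback", {
  expect_equal(segment_words("伤寒初感", c("伤寒", "初感", "伤")),
               c("伤寒", "初感"))
  expect_equal(segment_words("太阳", "心"), c("太", "阳"))
  expect_equal(segment_words("", "心"), character(0))
  expect_error(segment_words("太阳", character(0)), "non-empty")
})

test_that("segmentation agrees with a brute-force greedy oracle", {
  # independent oracle: at each position scan all lexicon entries and
  # take the longest that prefixes the remainder
  fmm_oracle <- function(span, lexicon) {
    toks <- character(0)
    while (nchar(span) > 0) {
      best <- substr(span, 1, 1)
      for (w in lexicon)
        if (nchar(w) > nchar(best) &&
            substr(span, 1, nchar(w)) == w) best <- w
      toks <- c(toks, best)
      span <- substr(span, nchar(best) + 1, nchar(span))
    }
    toks
  }
  set.seed(42)
  alphabet <- strsplit("太阳伤寒初感发汗甘草", "")[[1]]
  for (rep in 1:25) {
    span <- paste(sample(alphabet, sample(1:8, 1), replace = TRUE),
                  collapse = "")
    lexicon <- unique(replicate(sample(1:10, 1), paste(
      sample(alphabet, sample(1:3, 1), replace = TRUE), collapse = "")))
    got <- segment_words(span, lexicon)
    expect_equal(got, fmm_oracle(span, lexicon))
    # character conservation
    expect_equal(paste(got, collapse = ""), span)
  }
})

test_that("corpus building composes the pipeline and counts the vocabulary", {
  lex <- c("伤寒", "初感")
  cp <- build_corpus("伤寒初感。", lexicon = lex)
  expect_length(cp$sentences, 1)
  expect_equal(cp$sentences[[1]], c("伤寒", "初感"))
  expect_equal(sort(names(cp$vocab)), sort(lex))
  expect_true(all(cp$vocab == 1L))

  cp3 <- build_corpus(rep("伤寒初感。", 3), lexicon = lex)
  expect_true(all(cp3$vocab == 3L))

  # below-min_count tokens leave the vocab but keep their positions
  cp5 <- build_corpus(rep("伤寒初感。", 3), lexicon = lex, min_count = 5)
  expect_length(cp5$vocab, 0)
  expect_length(cp5$sentences, 3)
  expect_equal(cp5$n_tokens, 6)

  expect_warning(build_corpus("abc 123!", lexicon = lex), "empty")
})

test_that("traditional text is simplified before segmentation", {
  m <- c("傷" = "伤", "發" = "发")
  cp <- build_corpus("傷寒, cold!發汗。", lexicon = c("伤寒", "发汗"),
                     mapping = m)
  expect_equal(cp$sentences, list("伤寒", "发汗"))
})

test_that("corpus round-trips through the one-sentence-per-line format", {
  cp <- build_corpus(c("伤寒初感。始于太阳。", "发汗为先。"),
                     lexicon = c("伤寒", "初感", "始于", "太阳", "发汗", "为先"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_corpus(cp, path)
  cp2 <- read_corpus(path)
  expect_identical(cp2$sentences, cp$sentences)
  expect_identical(cp2$vocab, cp$vocab)
})

test_that("fixture tables load: simplify map, lexicon, thesaurus", {
  m <- read_simplify_map(system.file("extdata", "simplify_map_demo.tsv",
                                     package = "cddf"))
  expect_gt(length(m), 40)
  expect_equal(unname(m["醫"]), "医")
  lex <- read_lexicon(system.file("extdata", "lexicon_demo.tsv",
                                  package = "cddf"))
  expect_true("伤寒" %in% lex)
  th <- read_thesaurus(system.file("extdata", "drug_thesaurus_demo.tsv",
                                   package = "cddf"))
  expect_true("甘草" %in% th$names)
  expect_equal(unname(th$alias["国老"]), "甘草")
})
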