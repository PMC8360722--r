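test_that("training pairs enumerate the window, truncated at boundaries", {
  cp <- new_corpus(list(c("A", "B", "C")))
  p <- training_pairs(cp, window = 1)
  expect_equal(unname(split(p[, "context"], p[, "target"])),
               list("B", c("A", "C"), "B"))
  expect_equal(nrow(training_pairs(new_corpus(list("A")), window = 3)), 0)

  # brute-force count oracle: sum over positions of min(c, left) + min(c, right)
  s <- c("A", "B", "C", "D", "E")
  cnt <- sum(vapply(seq_along(s), function(t)
    min(2, t - 1) + min(2, length(s) - t), numeric(1)))
  expect_equal(cnt, 14)
  expect_equal(nrow(training_pairs(new_corpus(list(s)), window = 2)), cnt)

  # windows never cross sentence boundaries
  p2 <- training_pairs(new_corpus(list(c("A", "B"), c("C", "D"))), window = 3)
  expect_false(any(p2[, "target"] %in% c("A", "B") &
                   p2[, "context"] %in% c("C", "D")))
})

test_that("zero epochs returns the seeded initialization unchanged", {
  sp <- small_planted(50)
  cfg <- training_config(dim = 8, epochs = 0, buckets = 2^12, seed = 3)
  m <- train_embedding(sp$gen$corpus, sp$table, cfg)
  init <- cpp_init_embedding(nrow(m$input), length(m$vocab), 8L, 3L)
  expect_identical(unname(m$input), unname(init$input))
  expect_identical(unname(m$context), unname(init$context))
  expect_true(all(m$context == 0))
})

test_that("word representation is the mean of its substring-bucket rows", {
  tab <- feature_table("太", "13", "96", "tD")
  cp <- new_corpus(list(c("太", "太")))
  cfg <- training_config(dim = 4, epochs = 0, buckets = 64, n_max = 64,
                         seed = 5)
  m <- train_embedding(cp, tab, cfg)
  rows <- word_buckets("太", tab, 1, 64, 64) + 1L
  expect_equal(word_representation(m, "太"),
               colMeans(m$input[rows, , drop = FALSE]))
  # a single-substring word is that bucket's row verbatim
  tab1 <- feature_table("阳", "1", "22", "yB")  # sequence "122yB"
  m1 <- train_embedding(new_corpus(list(c("阳", "阳"))), tab1,
                        training_config(dim = 4, epochs = 0, buckets = 32,
                                        n_min = 5, n_max = 5, seed = 5))
  r1 <- word_buckets("阳", tab1, 5, 5, 32) + 1L
  expect_length(r1, 1)
  expect_equal(word_representation(m1, "阳"), m1$input[r1, ])
})

test_that("mean epoch loss decreases over the first epochs of training", {
  sp <- small_planted(200)
  cfg <- training_config(dim = 16, window = 2, epochs = 20, buckets = 2^15,
                         seed = 1)
  m <- train_embedding(sp$gen$corpus, sp$table, cfg)
  expect_length(m$epoch_loss, 20)
  first5 <- m$epoch_loss[1:5]
  expect_true(all(diff(first5) < 0))
  expect_true(all(m$epoch_loss >= 0))
})

test_that("exact-softmax analytic gradient matches finite differences", {
  set.seed(123)
  nv <- 5; dim <- 4; nb <- 7
  A <- matrix(rnorm(nb * dim, sd = 0.3), nb, dim)
  U <- matrix(rnorm(nv * dim, sd = 0.3), nv, dim)
  rows <- c(2L, 5L, 6L)
  o <- 3L
  gr <- exact_softmax_grad(A, U, rows, o)
  eps <- 1e-5
  # input side: the gradient is shared by each contributing row
  for (r in rows) for (d in seq_len(dim)) {
    Ap <- A; Am <- A
    Ap[r, d] <- Ap[r, d] + eps
    Am[r, d] <- Am[r, d] - eps
    num <- (exact_softmax_loss(Ap, U, rows, o) -
            exact_softmax_loss(Am, U, rows, o)) / (2 * eps)
    expect_equal(gr$d_input[d], num, tolerance = 1e-4)
  }
  # context side
  for (r in seq_len(nv)) for (d in seq_len(dim)) {
    Up <- U; Um <- U
    Up[r, d] <- Up[r, d] + eps
    Um[r, d] <- Um[r, d] - eps
    num <- (exact_softmax_loss(A, Up, rows, o) -
            exact_softmax_loss(A, Um, rows, o)) / (2 * eps)
    denom <- max(abs(num), 1e-8)
    expect_lt(abs(gr$d_context[r, d] - num) / denom, 1e-4 + 1e-6)
  }
})

test_that("exact-softmax training runs and its loss is non-negative", {
  sp <- small_planted(20)
  cfg <- training_config(dim = 8, epochs = 3, negative = 0, buckets = 2^10,
                         seed = 2)
  m <- train_embedding(sp$gen$corpus, sp$table, cfg)
  expect_true(all(m$epoch_loss >= 0))
  expect_lt(m$epoch_loss[3], m$epoch_loss[1])
})

test_that("training is bitwise deterministic given the seed", {
  sp <- small_planted(60)
  cfg <- training_config(dim = 8, epochs = 3, buckets = 2^12, seed = 9)
  m1 <- train_embedding(sp$gen$corpus, sp$table, cfg)
  m2 <- train_embedding(sp$gen$corpus, sp$table, cfg)
  expect_identical(m1$input, m2$input)
  expect_identical(m1$context, m2$context)
  cfg2 <- training_config(dim = 8, epochs = 3, buckets = 2^12, seed = 10)
  m3 <- train_embedding(sp$gen$corpus, sp$table, cfg2)
  expect_false(identical(m1$context, m3$context))
})

test_that("whole-word fallback rows make subword mode reproduce skip-gram", {
  # with substring buckets disabled every word gets a dedicated input row in
  # vocabulary order — structurally identical to the csg baseline, so the
  # trajectories coincide bitwise at the same seed
  sp <- small_planted(60)
  cfg_fb <- training_config(dim = 8, epochs = 3, buckets = 0, seed = 4,
                            mode = "ssp2vec")
  cfg_cs <- training_config(dim = 8, epochs = 3, buckets = 0, seed = 4,
                            mode = "csg")
  m_fb <- train_embedding(sp$gen$corpus, table = NULL, cfg_fb)
  m_cs <- train_embedding(sp$gen$corpus, table = NULL, cfg_cs)
  expect_identical(m_fb$context, m_cs$context)
  expect_identical(m_fb$input, m_cs$input)
  expect_identical(m_fb$epoch_loss, m_cs$epoch_loss)
})

test_that("output vectors are the context-matrix rows of vocabulary words", {
  sp <- small_planted(60)
  m <- train_embedding(sp$gen$corpus, sp$table,
                       training_config(dim = 8, epochs = 2, buckets = 2^12,
                                       seed = 1))
  v <- output_vectors(m)
  expect_equal(dim(v), c(length(m$vocab), 8))
  w <- m$vocab[3]
  expect_identical(v[w, ], m$context[match(w, m$vocab), ])
  vi <- output_vectors(m, side = "input")
  expect_equal(dim(vi), dim(v))
  expect_false(identical(vi, v))
})

test_that("within-group drug cosine exceeds between-group after training", {
  sp <- small_planted(200)
  m <- train_embedding(sp$gen$corpus, sp$table,
                       training_config(dim = 16, window = 2, epochs = 20,
                                       buckets = 2^15, seed = 1))
  gc <- group_cosines(output_vectors(m), sp$gen$truth$drugs)
  expect_gt(gc["within"], gc["between"])
})

test_that("vectors round-trip through word2vec text format", {
  set.seed(21)
  v <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("甘草", "桂枝", "麻黄"), NULL))
  path <- withr::local_tempfile(fileext = ".txt")
  export_vectors(v, path)
  v2 <- import_vectors(path)
  expect_equal(v2, v, tolerance = 1e-6)
  expect_identical(rownames(v2), rownames(v))

  # empty vocabulary: header only
  export_vectors(v[0, , drop = FALSE], path)
  expect_equal(readLines(path, encoding = "UTF-8"), "0 4")
  expect_equal(dim(import_vectors(path)), c(0, 4))

  # header / row inconsistencies are reported with line numbers
  writeLines(c("2 4", paste("甘草", "1 2 3 4")), path, useBytes = FALSE)
  expect_error(import_vectors(path), "2 rows")
  writeLines(c("1 4", "甘草 1 2 3"), path, useBytes = FALSE)
  expect_error(import_vectors(path), "line 2")
})
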