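test_that("initial state gives each node its own unit label", {
  g <- igraph::make_ring(3)
  igraph::V(g)$name <- c("a", "b", "c")
  st <- copra_init(g)
  expect_length(st, 3)
  for (v in names(st)) {
    expect_identical(names(st[[v]]), v)
    expect_equal(sum(st[[v]]), 1)
  }
  st1 <- copra_init(igraph::make_empty_graph(1, directed = FALSE))
  expect_equal(unname(st1[[1]]), 1)
})

test_that("the worked update example keeps only the majority label", {
  toy <- fig5_toy_state()
  expect_equal(toy$r, 2L)
  tab <- table(unlist(lapply(toy$neighbor_labels, names)))
  expect_equal(as.integer(tab[c("yellow", "pink", "green")]), c(3L, 2L, 1L))

  # pooling + normalization gives 3/6, 2/6, 1/6 before retention
  u <- unlist(toy$neighbor_labels)
  nm <- unlist(lapply(toy$neighbor_labels, names))
  pooled <- vapply(c("yellow", "pink", "green"),
                   function(k) sum(u[nm == k]) / sum(u), numeric(1))
  expect_equal(unname(pooled), c(3 / 6, 2 / 6, 1 / 6))

  # coefficients below 1/r are removed; the node ends with yellow alone
  res <- copra_update_node(toy$neighbor_labels, toy$r)
  expect_identical(names(res), "yellow")
  expect_equal(unname(res), 1.0)
})

test_that("node update normalizes, retains >= 1/r, and breaks ties randomly", {
  expect_equal(copra_update_node(list(c(A = 1)), r = 2), c(A = 1.0))
  # both coefficients equal exactly 1/r: strict < retains them
  res <- copra_update_node(list(c(A = 0.5, B = 0.5)), r = 2)
  expect_equal(res, c(A = 0.5, B = 0.5))
  # three equal labels at r = 2 all fall below 1/2: one survives at random
  set.seed(5)
  res3 <- copra_update_node(list(c(A = 1), c(B = 1), c(C = 1)), r = 2)
  expect_length(res3, 1)
  expect_equal(unname(res3), 1.0)
  expect_true(names(res3) %in% c("A", "B", "C"))
})

test_that("update invariants hold on random label pools", {
  set.seed(17)
  for (rep in 1:40) {
    r <- sample(1:4, 1)
    k <- sample(1:6, 1)
    nbrs <- lapply(seq_len(k), function(i) {
      labs <- sample(LETTERS[1:5], sample(1:3, 1))
      x <- runif(length(labs))
      setNames(x / sum(x), labs)
    })
    res <- copra_update_node(nbrs, r)
    expect_equal(sum(res), 1, tolerance = 1e-9)
    expect_true(all(res >= 1 / r - 1e-12))
    expect_lte(length(res), r)
  }
})

test_that("propagation separates two bridged cliques and unifies K4", {
  g <- clique_bridge_graph()
  ls <- copra_run(g, r = 1, seed = 7)
  expect_true(ls$converged)
  com <- extract_communities(ls, min_size = 3)
  expect_length(com$communities, 2)
  got <- sort(vapply(com$communities,
                     function(m) paste(sort(m), collapse = ","),
                     character(1)))
  want <- sort(c(paste(paste0("a", 1:5), collapse = ","),
                 paste(paste0("b", 1:5), collapse = ",")))
  expect_equal(unname(got), want)

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("n", 1:4)
  com4 <- extract_communities(copra_run(k4, r = 1, seed = 7), min_size = 3)
  expect_length(com4$communities, 1)
  expect_setequal(com4$communities[[1]], paste0("n", 1:4))
})

test_that("edgeless networks converge immediately to singletons", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g)$name <- paste0("x", 1:4)
  ls <- copra_run(g, r = 2, seed = 1)
  expect_true(ls$converged)
  expect_equal(ls$iterations, 1L)
  com <- extract_communities(ls)
  expect_length(com$communities, 4)
  expect_true(all(com$sizes == 1))
  expect_false(any(com$major))
})

test_that("runs are deterministic given the seed and bounded by max_iter", {
  g <- clique_bridge_graph()
  c1 <- extract_communities(copra_run(g, r = 2, seed = 3))
  c2 <- extract_communities(copra_run(g, r = 2, seed = 3))
  expect_identical(c1$communities, c2$communities)
  expect_warning(copra_run(g, r = 2, seed = 3, max_iter = 0), "converge")
})

test_that("communities group by label and overlap is preserved", {
  st <- structure(list(state = list(a = c(X = 1), b = c(X = 1),
                                    c = c(Y = 1)),
                       iterations = 1L, converged = TRUE, r = 2L, seed = 1L),
                  class = "cddf_labelstate")
  names(st$state) <- c("a", "b", "c")
  com <- extract_communities(st, min_size = 3)
  expect_equal(com$communities[["X"]], c("a", "b"))
  expect_equal(com$communities[["Y"]], "c")
  expect_false(any(com$major))

  st$state$b <- c(X = 0.5, Y = 0.5)
  com2 <- extract_communities(st, min_size = 0)
  expect_true("b" %in% com2$communities[["X"]])
  expect_true("b" %in% com2$communities[["Y"]])
})

test_that("every node is covered and memberships are bounded by r", {
  set.seed(23)
  g <- igraph::sample_gnp(30, 0.12)
  igraph::V(g)$name <- paste0("v", 1:30)
  for (r in c(1, 2, 3)) {
    ls <- suppressWarnings(copra_run(g, r = r, seed = 11))
    com <- extract_communities(ls, min_size = 2)
    members <- unlist(com$communities)
    expect_setequal(unique(members), paste0("v", 1:30))
    counts <- table(members)
    expect_lte(max(counts), r)
  }
})

test_that("core drugs are the top-k by degree with stated tie-breaks", {
  # star-like weighted graph with known degrees
  ed <- data.frame(
    from = c("h", "h", "h", "a", "a", "b"),
    to   = c("a", "b", "c", "b", "c", "c"),
    weight = c(1, 1, 1, 0.9, 0.8, 0.7))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  members <- c("a", "b", "c", "h")
  cd <- select_core_drugs(members, g, k = 10)
  expect_equal(nrow(cd), 4)
  expect_equal(cd$degree, c(3L, 3L, 3L, 3L))
  # all tied on degree: strength then name decides
  expect_equal(cd$drug[1], "h")  # strength 3.0
  expect_equal(cd$drug[2], "a")  # strength 2.7 > b's 2.6

  cd2 <- select_core_drugs(members, g, k = 2)
  expect_equal(nrow(cd2), 2)

  # a community of >= 10 members yields exactly 10
  big <- igraph::make_full_graph(12)
  igraph::V(big)$name <- sprintf("d%02d", 1:12)
  cd3 <- select_core_drugs(igraph::V(big)$name, big, k = 10)
  expect_equal(nrow(cd3), 10)
  # equal degrees and strengths: lexicographic order decides
  expect_equal(cd3$drug, sprintf("d%02d", 1:10))
})
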