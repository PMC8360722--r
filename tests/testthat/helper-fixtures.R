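# Shared fixtures for the suite; everything is built in code.

# the canonical two-character example: per-character codes concatenated
# stroke + structure + pinyin, characters in word order
taiyang_table <- function() {
  feature_table(c("太", "阳"),            # 太, 阳
                c("1344", "522511"), c("96", "66"),
                c("taiD", "yangB"))
}
TAIYANG_SEQ <- "134496taiD52251166yangB"

# two 5-cliques joined by a single bridge edge
clique_bridge_graph <- function() {
  g1 <- paste0("a", 1:5)
  g2 <- paste0("b", 1:5)
  ed <- rbind(t(combn(g1, 2)), t(combn(g2, 2)), c("a1", "b1"))
  igraph::graph_from_data_frame(
    data.frame(from = ed[, 1], to = ed[, 2], weight = 1),
    directed = FALSE)
}

# a small planted corpus + matching feature table for embedding tests
small_planted <- function(n_sentences = 200L, seed = 1L) {
  des <- planted_design(n_sentences = n_sentences, seed = seed)
  gen <- gen_planted_corpus(des)
  truth <- c(gen$truth$drugs, gen$truth$contexts)
  tab <- gen_feature_table(names(truth), seed = seed, groups = truth)
  list(gen = gen, table = tab)
}

# hand-rolled breadth-first search, the all-pairs distance oracle
bfs_dist <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n); d[s] <- 0
  q <- s
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
  }
  d
}

# Wasserman-Faust closeness computed from the BFS oracle
closeness_oracle <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  vapply(seq_len(n), function(s) {
    d <- bfs_dist(adj, s)[-s]
    reach <- d[is.finite(d)]
    if (!length(reach)) return(0)
    (length(reach) / sum(reach)) * (length(reach) / (n - 1))
  }, numeric(1))
}

# mean pairwise cosine within / between planted groups
group_cosines <- function(vectors, truth) {
  v <- vectors[names(truth), , drop = FALSE]
  cm <- tcrossprod(v / sqrt(rowSums(v^2)))
  same <- outer(truth, truth, "==") & upper.tri(cm)
  diff <- (!outer(truth, truth, "==")) & upper.tri(cm)
  c(within = mean(cm[same]), between = mean(cm[diff]))
}
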