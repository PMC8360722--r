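#' Construct a drug thesaurus
#'
#' Standard drug names with optional aliases. Aliases are normalized to
#' their standard name before any corpus intersection.
#'
#' @param names character vector of standard drug names.
#' @param alias optional named character vector `alias -> standard name`.
#' @return a `cddf_thesaurus`.
#' @export
drug_thesaurus <- function(names, alias = NULL) {
  names <- unique(names)
  if (length(names) == 0) stop("thesaurus must be non-empty")
  if (!is.null(alias)) {
    if (is.null(base::names(alias))) stop("alias must be a named vector")
    unknown <- setdiff(unname(alias), names)
    if (length(unknown))
      stop("alias targets not in thesaurus: ", paste(unknown, collapse = " "))
  }
  structure(list(names = names, alias = alias), class = "cddf_thesaurus")
}

#' @export
print.cddf_thesaurus <- function(x, ...) {
  cat(sprintf("<cddf_thesaurus> %d standard names, %d aliases\n",
              length(x$names), length(x$alias)))
  invisible(x)
}

#' Read a drug thesaurus from TSV
#'
#' Format: `standard_name[<TAB>alias1,alias2,...]`, UTF-8, `#` comments.
#'
#' @param path file path.
#' @return a `cddf_thesaurus`.
#' @export
read_thesaurus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  std <- vapply(parts, `[[`, character(1), 1L)
  alias <- NULL
  for (p in parts) {
    if (length(p) > 1 && nzchar(p[2])) {
      al <- strsplit(p[2], ",", fixed = TRUE)[[1]]
      alias <- c(alias, setNames(rep(p[1], length(al)), al))
    }
  }
  drug_thesaurus(std, alias)
}

#' Extract drug vectors present in both corpus and thesaurus
#'
#' Keeps the vectors of words that are in the trained vocabulary and
#' (after alias normalization) in the thesaurus; rows are renamed to
#' standard drug names.
#'
#' @param vectors numeric matrix of semantic vectors with one named row per
#'   vocabulary word (see [output_vectors()]).
#' @param thesaurus a `cddf_thesaurus`.
#' @return numeric matrix of drug vectors, rows named by standard drug
#'   name; zero rows (with a warning) when the intersection is empty.
#' @export
extract_drugs <- function(vectors, thesaurus) {
  stopifnot(is.matrix(vectors), inherits(thesaurus, "cddf_thesaurus"))
  words <- rownames(vectors)
  std <- words
  if (!is.null(thesaurus$alias)) {
    hit <- match(words, names(thesaurus$alias))
    std[!is.na(hit)] <- unname(thesaurus$alias[hit[!is.na(hit)]])
  }
  keep <- std %in% thesaurus$names
  if (!any(keep)) {
    warning("no corpus word matches the thesaurus")
    return(vectors[0, , drop = FALSE])
  }
  out <- vectors[keep, , drop = FALSE]
  std <- std[keep]
  if (anyDuplicated(std)) {
    warning("multiple corpus words map to one standard name; keeping the first")
    out <- out[!duplicated(std), , drop = FALSE]
    std <- std[!duplicated(std)]
  }
  rownames(out) <- std
  out
}

#' Cosine similarity of two vectors
#'
#' `dot(u, v) / (|u| |v|)`; defined as 0 (with a message) when either
#' vector is zero.
#'
#' @param u,v numeric vectors of equal length.
#' @return similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    message("zero vector: similarity defined as 0")
    return(0)
  }
  sum(u * v) / (nu * nv)
}

# all-pairs cosine; zero rows give similarity 0 everywhere
cosine_matrix <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  xn <- x / ifelse(nrm > 0, nrm, 1)
  s <- tcrossprod(xn)
  s[nrm == 0, ] <- 0
  s[, nrm == 0] <- 0
  diag(s) <- 1
  s
}

#' Choose a similarity threshold hitting an edge budget
#'
#' Scans the sorted pairwise cosine similarities for the strict threshold
#' whose edge count is closest to `target_edges` (ties can make the exact
#' budget unattainable).
#'
#' @param drugs drug vector matrix (see [extract_drugs()]).
#' @param target_edges desired number of edges.
#' @return a similarity threshold `s`.
#' @export
tune_threshold <- function(drugs, target_edges) {
  stopifnot(nrow(drugs) >= 2, target_edges >= 0)
  s <- cosine_matrix(drugs)
  sims <- s[upper.tri(s)]
  us <- sort(unique(sims), decreasing = TRUE)
  # candidate thresholds just below each unique value include all >= it
  counts <- vapply(us, function(v) sum(sims >= v), integer(1))
  cand_s <- c(us[1] + 1e-8,
              if (length(us) > 1) (us[-length(us)] + us[-1]) / 2,
              us[length(us)] - 1e-8)
  cand_n <- c(0L, counts[-length(counts)], counts[length(counts)])
  best <- which.min(abs(cand_n - target_edges))
  cand_s[best]
}

#' Build the thresholded drug similarity network
#'
#' Undirected graph with one node per drug and an edge between every pair
#' whose cosine similarity is *strictly* greater than `s`; the similarity
#' is stored as the edge weight. Isolated nodes are kept.
#'
#' @param drugs drug vector matrix (see [extract_drugs()]).
#' @param s similarity threshold (ignored when `target_edges` is given).
#' @param target_edges optional edge budget; when supplied, `s` is chosen
#'   by [tune_threshold()].
#' @return an `igraph` graph with vertex `name`s, edge `weight`s and graph
#'   attribute `threshold`.
#' @export
build_network <- function(drugs, s = 0.5, target_edges = NULL) {
  stopifnot(is.matrix(drugs))
  n <- nrow(drugs)
  if (n < 2) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (n == 1) igraph::V(g)$name <- rownames(drugs)
    g <- igraph::set_graph_attr(g, "threshold", s)
    return(g)
  }
  if (!is.null(target_edges)) s <- tune_threshold(drugs, target_edges)
  sim <- cosine_matrix(drugs)
  idx <- which(upper.tri(sim) & sim > s, arr.ind = TRUE)
  edges <- data.frame(from = rownames(drugs)[idx[, 1]],
                      to = rownames(drugs)[idx[, 2]],
                      weight = sim[idx],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = rownames(drugs), stringsAsFactors = FALSE))
  igraph::set_graph_attr(g, "threshold", s)
}

#' Write / read a drug network
#'
#' `format = "tsv"` writes a weighted edge list
#' (`drug_i<TAB>drug_j<TAB>similarity`; isolated nodes are listed at the
#' end as single-column rows). `format = "graphml"` uses GraphML.
#'
#' @param network an `igraph` drug network.
#' @param path file path.
#' @param format `"tsv"` or `"graphml"`.
#' @rdname network_io
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
    return(invisible(path))
  }
  ed <- igraph::as_data_frame(network, what = "edges")
  iso <- setdiff(igraph::V(network)$name, unique(c(ed$from, ed$to)))
  lines <- c(sprintf("%s\t%s\t%.6f", ed$from, ed$to, ed$weight), iso)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con = con)
  invisible(path)
}

#' @rdname network_io
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    # GraphML bytes are UTF-8 but come back with unknown encoding marks
    nm <- igraph::V(g)$name
    if (!is.null(nm)) {
      Encoding(nm) <- "UTF-8"
      igraph::V(g)$name <- nm
    }
    return(g)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  is_edge <- lengths(parts) >= 3
  ed <- do.call(rbind, lapply(parts[is_edge], function(p)
    data.frame(from = p[1], to = p[2], weight = as.numeric(p[3]),
               stringsAsFactors = FALSE)))
  iso <- vapply(parts[!is_edge], `[[`, character(1), 1L)
  verts <- unique(c(if (!is.null(ed)) c(ed$from, ed$to), iso))
  if (is.null(ed))
    ed <- data.frame(from = character(0), to = character(0),
                     weight = numeric(0))
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = data.frame(name = verts))
}
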