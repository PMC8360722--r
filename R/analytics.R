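#' Node degree
#'
#' Count of incident edges in the full network.
#'
#' @param network an `igraph` drug network.
#' @param nodes vertex names (default: all).
#' @return named integer vector.
#' @export
node_degree <- function(network, nodes = igraph::V(network)) {
  deg <- igraph::degree(network, v = nodes)
  setNames(as.integer(deg), names(deg))
}

#' Component-scaled closeness centrality
#'
#' Wasserman–Faust closeness: with `R` the set of nodes reachable from a
#' node (itself excluded), `n` the total node count and `d` unweighted
#' shortest-path distance,
#' `(|R| / sum(d)) * (|R| / (n - 1))`, and 0 for unreachable (isolated)
#' nodes. The component-size scaling keeps values comparable on
#' disconnected networks, where plain within-component closeness would
#' inflate small components. Always in `[0, 1]`.
#'
#' @param network an `igraph` drug network.
#' @param nodes vertex names (default: all).
#' @param scaled if `FALSE`, the within-component closeness
#'   `|R| / sum(d)` is returned instead.
#' @return named numeric vector.
#' @export
closeness_wf <- function(network, nodes = igraph::V(network), scaled = TRUE) {
  n <- igraph::vcount(network)
  d <- igraph::distances(network, v = nodes, weights = NA)
  out <- apply(d, 1L, function(dv) {
    dv <- dv[is.finite(dv) & dv > 0]
    nr <- length(dv)
    if (nr == 0) return(0)
    cl <- nr / sum(dv)
    if (scaled && n > 1) cl * nr / (n - 1) else cl
  })
  setNames(as.numeric(out), rownames(d))
}

#' Distribution summaries of the drug network
#'
#' Community-size histogram over *all* detected communities, plus degree
#' and closeness histograms over all nodes (closeness binned at
#' `closeness_bin`, left-closed bins labelled by their lower edge).
#'
#' @param network an `igraph` drug network.
#' @param communities a `cddf_communities`.
#' @param closeness_bin bin width for the closeness histogram.
#' @return list of class `cddf_distributions` with named-count tables
#'   `community_size`, `degree`, `closeness`.
#' @export
network_distributions <- function(network, communities,
                                  closeness_bin = 0.01) {
  stopifnot(inherits(communities, "cddf_communities"))
  size_h <- table(communities$sizes)
  if (igraph::vcount(network) == 0) {
    deg_h <- table(integer(0))
    clo_h <- table(numeric(0))
  } else {
    deg_h <- table(node_degree(network))
    cl <- closeness_wf(network)
    clo_h <- table(sprintf("%.2f", floor(cl / closeness_bin) * closeness_bin))
  }
  structure(list(community_size = size_h, degree = deg_h, closeness = clo_h),
            class = "cddf_distributions")
}

#' Per-community core-drug metric table and distribution report
#'
#' One row per (community, core drug), in degree order within each
#' community; degree and closeness are computed once on the full network,
#' so a drug belonging to two communities carries the same values in
#' both. Range summaries of the core drugs' closeness and degree and the
#' three distribution histograms are attached.
#'
#' @param network an `igraph` drug network.
#' @param communities a `cddf_communities`.
#' @param k core drugs per community.
#' @param major_only restrict the table to major communities.
#' @return a `cddf_report`: list with `core_table` (data.frame:
#'   `community`, `drug`, `degree`, `closeness`), `distributions`,
#'   `summary` (closeness/degree ranges over core drugs), and network
#'   counts.
#' @export
network_report <- function(network, communities, k = 10L,
                           major_only = TRUE) {
  cores <- core_drugs(communities, network, k = k, major_only = major_only)
  clo <- closeness_wf(network)
  rows <- lapply(names(cores), function(lb) {
    cd <- cores[[lb]]
    if (nrow(cd) == 0) return(NULL)
    data.frame(community = lb, drug = cd$drug, degree = cd$degree,
               closeness = unname(clo[cd$drug]), stringsAsFactors = FALSE)
  })
  core_table <- do.call(rbind, rows)
  if (is.null(core_table))
    core_table <- data.frame(community = character(0), drug = character(0),
                             degree = integer(0), closeness = numeric(0))
  summ <- list(
    closeness_range = if (nrow(core_table)) range(core_table$closeness)
                      else c(NA_real_, NA_real_),
    degree_range = if (nrow(core_table)) range(core_table$degree)
                   else c(NA_real_, NA_real_))
  structure(list(core_table = core_table,
                 distributions = network_distributions(network, communities),
                 summary = summ,
                 n_nodes = igraph::vcount(network),
                 n_edges = igraph::ecount(network),
                 n_communities = length(communities$communities),
                 n_major = sum(communities$major)),
            class = "cddf_report")
}

#' @export
print.cddf_report <- function(x, ...) {
  cat(sprintf("<cddf_report> %d nodes, %d edges, %d communities (%d major)\n",
              x$n_nodes, x$n_edges, x$n_communities, x$n_major))
  if (nrow(x$core_table)) {
    cat(sprintf("  core drugs: %d rows; closeness in [%.2f, %.2f], degree in [%d, %d]\n",
                nrow(x$core_table), x$summary$closeness_range[1],
                x$summary$closeness_range[2], x$summary$degree_range[1],
                x$summary$degree_range[2]))
  }
  invisible(x)
}

#' Write a report as JSON (and optionally TSV)
#'
#' @param report a `cddf_report`.
#' @param path JSON output path.
#' @param tsv optional path for the core-drug table as TSV.
#' @export
write_report <- function(report, path, tsv = NULL) {
  stopifnot(inherits(report, "cddf_report"))
  obj <- list(
    core_table = report$core_table,
    distributions = lapply(unclass(report$distributions), function(h)
      list(value = names(h), count = as.integer(h))),
    summary = report$summary,
    n_nodes = report$n_nodes, n_edges = report$n_edges,
    n_communities = report$n_communities, n_major = report$n_major)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  if (!is.null(tsv))
    utils::write.table(report$core_table, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
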