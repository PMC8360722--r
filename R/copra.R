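#' Initialize COPRA label state
#'
#' Every node starts holding its own unique label with belonging
#' coefficient 1.
#'
#' @param network an `igraph` drug network with vertex names.
#' @return a named list (one entry per node) of named numeric vectors
#'   `label -> belonging coefficient`.
#' @export
copra_init <- function(network) {
  nms <- igraph::V(network)$name
  if (is.null(nms)) nms <- as.character(seq_len(igraph::vcount(network)))
  if (length(nms) == 0) stop("network is empty")
  setNames(lapply(nms, function(v) setNames(1.0, v)), nms)
}

#' One COPRA node update
#'
#' Pools the neighbours' label maps by summing belonging coefficients per
#' label, normalizes to sum 1, deletes labels whose coefficient is
#' *strictly* below `1/r`, and renormalizes. If no label survives, one
#' maximal-coefficient label is kept, chosen uniformly at random among
#' ties (uses the session RNG; [copra_run()] seeds it).
#'
#' @param neighbor_labels list of named numeric vectors, one per
#'   neighbour (optionally pre-scaled by edge weight).
#' @param r retention threshold: a node keeps at most `r` labels, each
#'   with coefficient at least `1/r`.
#' @return named numeric vector summing to 1.
#' @export
copra_update_node <- function(neighbor_labels, r) {
  stopifnot(r >= 1, length(neighbor_labels) >= 1)
  u <- unlist(neighbor_labels, use.names = TRUE)
  # unlist mangles names when entries share labels; rebuild them explicitly
  nm <- unlist(lapply(neighbor_labels, names), use.names = FALSE)
  keys <- unique(nm)
  agg <- vapply(keys, function(k) sum(u[nm == k]), numeric(1))
  coef <- agg / sum(agg)
  keep <- coef >= 1 / r
  if (any(keep)) {
    coef <- coef[keep]
  } else {
    mx <- which(coef == max(coef))
    pick <- if (length(mx) > 1) mx[sample.int(length(mx), 1L)] else mx
    coef <- coef[pick]
  }
  coef / sum(coef)
}

#' Run COPRA overlapping label propagation
#'
#' Asynchronous sweeps: nodes are visited in a fresh seeded random order
#' each sweep and updated labels are visible immediately. Isolated nodes
#' keep their own label. Iteration stops when no node's label *set*
#' (ignoring coefficients) changed over a full sweep
#' (`stop_rule = "labelset"`), or when the per-label node counts are
#' unchanged (`stop_rule = "counts"`, after Gregory's criterion), or at
#' `max_iter` (with a warning). Deterministic given the seed.
#'
#' @param network an `igraph` drug network.
#' @param r retention threshold (maximum community memberships per node).
#' @param max_iter sweep limit.
#' @param seed integer seed for node order and tie-breaking.
#' @param weighted if `TRUE`, neighbour contributions are scaled by edge
#'   weight before pooling (off by default: propagation pools unit
#'   contributions).
#' @param stop_rule `"labelset"` or `"counts"`.
#' @return a `cddf_labelstate`: list with `state` (per-node label maps),
#'   `iterations`, `converged`, `r`, `seed`.
#' @export
copra_run <- function(network, r = 2L, max_iter = 100L, seed = 1L,
                      weighted = FALSE, stop_rule = c("labelset", "counts")) {
  stop_rule <- match.arg(stop_rule)
  state <- copra_init(network)
  n <- length(state)
  nbrs <- lapply(igraph::adjacent_vertices(network, igraph::V(network)),
                 as.integer)
  wts <- NULL
  if (weighted && "weight" %in% igraph::edge_attr_names(network)) {
    wts <- lapply(seq_len(n), function(i) {
      e <- igraph::incident(network, i)
      nb <- nbrs[[i]]
      w <- igraph::E(network)$weight[as.integer(e)]
      # incident() and adjacent_vertices() enumerate in the same order
      w
    })
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  iterations <- 0L
  converged <- FALSE
  label_counts <- function(st) {
    tab <- table(unlist(lapply(st, names), use.names = FALSE))
    tab[order(names(tab), method = "radix")]
  }
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    old_keys <- lapply(state, names)
    old_counts <- if (stop_rule == "counts") label_counts(state)
    ord <- sample.int(n)
    for (i in ord) {
      nb <- nbrs[[i]]
      if (length(nb) == 0) next  # isolated node keeps its own label
      contrib <- state[nb]
      if (!is.null(wts))
        contrib <- lapply(seq_along(nb), function(j) contrib[[j]] * wts[[i]][j])
      state[[i]] <- copra_update_node(contrib, r)
    }
    stable <- if (stop_rule == "labelset") {
      all(vapply(seq_len(n), function(i)
        setequal(old_keys[[i]], names(state[[i]])), logical(1)))
    } else {
      identical(old_counts, label_counts(state))
    }
    if (stable) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("COPRA did not converge within %d sweeps", max_iter))
  structure(list(state = state, iterations = iterations,
                 converged = converged, r = as.integer(r),
                 seed = as.integer(seed)),
            class = "cddf_labelstate")
}

#' @export
print.cddf_labelstate <- function(x, ...) {
  nl <- length(unique(unlist(lapply(x$state, names), use.names = FALSE)))
  cat(sprintf("<cddf_labelstate> %d nodes, %d labels, %d sweeps (%s), r = %d\n",
              length(x$state), nl, x$iterations,
              if (x$converged) "converged" else "not converged", x$r))
  invisible(x)
}

#' Extract overlapping communities from a label state
#'
#' One community per surviving label: its members are all nodes holding
#' that label, so a node holding several labels belongs to several
#' communities. Communities with more than `min_size` members are flagged
#' `major`; smaller ones are retained but flagged minor.
#'
#' @param labelstate a `cddf_labelstate` from [copra_run()].
#' @param min_size size above which a community is flagged major
#'   (reporting default 3, i.e. major means more than three nodes; the
#'   distribution count in [network_distributions()] uses all
#'   communities).
#' @param split if `TRUE`, communities whose members are disconnected in
#'   the induced subgraph of `network` are split into connected
#'   components (off by default).
#' @param network required when `split = TRUE`.
#' @return a `cddf_communities`: list with `communities` (named list of
#'   member vectors), `sizes`, `major` (logical), `min_size`.
#' @export
extract_communities <- function(labelstate, min_size = 3L, split = FALSE,
                                network = NULL) {
  stopifnot(inherits(labelstate, "cddf_labelstate"))
  st <- labelstate$state
  nodes <- rep(names(st), times = vapply(st, length, integer(1)))
  labels <- unlist(lapply(st, names), use.names = FALSE)
  comms <- split(nodes, labels)
  if (split) {
    if (is.null(network)) stop("split = TRUE needs the network")
    out <- list()
    for (lb in names(comms)) {
      sub <- igraph::induced_subgraph(network, comms[[lb]])
      mem <- igraph::components(sub)$membership
      pieces <- split(names(mem), mem)
      if (length(pieces) == 1) out[[lb]] <- comms[[lb]]
      else for (j in seq_along(pieces))
        out[[paste0(lb, ".", j)]] <- pieces[[j]]
    }
    comms <- out
  }
  comms <- lapply(comms, function(m) sort(unique(m), method = "radix"))
  sizes <- vapply(comms, length, integer(1))
  ord <- order(-sizes, names(comms), method = "radix")
  comms <- comms[ord]; sizes <- sizes[ord]
  structure(list(communities = comms, sizes = sizes,
                 major = sizes > min_size, min_size = as.integer(min_size)),
            class = "cddf_communities")
}

#' @export
print.cddf_communities <- function(x, ...) {
  cat(sprintf("<cddf_communities> %d communities (%d major, > %d nodes); sizes: %s\n",
              length(x$communities), sum(x$major), x$min_size,
              paste(head(x$sizes, 10), collapse = " ")))
  invisible(x)
}

#' Select core drugs of a community by degree
#'
#' Members ranked by degree in the *full* network (not the community
#' subgraph), descending; ties broken by larger summed incident edge
#' weight, then lexicographic (C-locale) name. The top
#' `min(k, community size)` members are returned.
#'
#' @param members character vector of community member names.
#' @param network the full `igraph` drug network.
#' @param k maximum number of core drugs (default 10).
#' @return data.frame with columns `drug`, `degree`, `strength`, in rank
#'   order.
#' @export
select_core_drugs <- function(members, network, k = 10L) {
  stopifnot(length(members) >= 1)
  deg <- igraph::degree(network, v = members)
  stren <- igraph::strength(network, v = members)
  ord <- order(-deg, -stren, members, method = "radix")
  top <- head(ord, min(k, length(members)))
  data.frame(drug = members[top], degree = as.integer(deg[top]),
             strength = unname(stren[top]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Core drugs for every community
#'
#' @param communities a `cddf_communities`.
#' @param network the full `igraph` drug network.
#' @param k maximum core drugs per community.
#' @param major_only restrict to major communities (default `TRUE`).
#' @return named list of data.frames (see [select_core_drugs()]).
#' @export
core_drugs <- function(communities, network, k = 10L, major_only = TRUE) {
  stopifnot(inherits(communities, "cddf_communities"))
  keep <- if (major_only) communities$major else
    rep(TRUE, length(communities$communities))
  lapply(communities$communities[keep], select_core_drugs,
         network = network, k = k)
}
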