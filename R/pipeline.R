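#' Run the full core-drug discovery pipeline
#'
#' Convenience wrapper chaining [train_embedding()], [output_vectors()],
#' [extract_drugs()], [build_network()], [copra_run()],
#' [extract_communities()] and [network_report()].
#'
#' @param corpus a `cddf_corpus` of segmented sentences.
#' @param thesaurus a `cddf_thesaurus` of standard drug names.
#' @param table a `cddf_feature_table` (needed for `ssp2vec` mode).
#' @param config a [training_config()].
#' @param s similarity threshold for the drug network.
#' @param target_edges optional edge budget overriding `s`
#'   (see [tune_threshold()]).
#' @param r COPRA retention threshold.
#' @param copra_seed seed for the label-propagation sweep order.
#' @param min_size major-community size threshold (major means more than
#'   `min_size` members).
#' @param k core drugs per community.
#' @return a `cddf_result`: list with `model`, `drugs` (drug vector
#'   matrix), `network`, `labelstate`, `communities`, `core` (per-community
#'   core-drug tables) and `report`.
#' @export
discover_core_drugs <- function(corpus, thesaurus, table = NULL,
                                config = training_config(),
                                s = 0.5, target_edges = NULL,
                                r = 2L, copra_seed = 1L,
                                min_size = 3L, k = 10L) {
  model <- train_embedding(corpus, table, config)
  vectors <- output_vectors(model)
  drugs <- extract_drugs(vectors, thesaurus)
  network <- build_network(drugs, s = s, target_edges = target_edges)
  labelstate <- copra_run(network, r = r, seed = copra_seed)
  communities <- extract_communities(labelstate, min_size = min_size)
  report <- network_report(network, communities, k = k)
  structure(list(model = model, drugs = drugs, network = network,
                 labelstate = labelstate, communities = communities,
                 core = core_drugs(communities, network, k = k),
                 report = report),
            class = "cddf_result")
}

#' @export
print.cddf_result <- function(x, ...) {
  cat("<cddf_result>\n")
  print(x$model)
  cat(sprintf("  drug network: %d drugs, %d edges (threshold %.4f)\n",
              igraph::vcount(x$network), igraph::ecount(x$network),
              igraph::graph_attr(x$network, "threshold")))
  print(x$communities)
  print(x$report)
  invisible(x)
}
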