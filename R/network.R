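#' Assemble a direct interaction network over regulated genes
#'
#' Induced subgraph of a curated edge table: an edge is kept iff both of its
#' endpoints belong to the member set (regulated genes) or the declared seed
#' nodes (e.g. the metal-ion node and Mtf1). Members without any retained
#' edge stay in the node table, flagged isolated. Duplicate
#' (source, target, type) triples are collapsed; malformed rows are skipped
#' with a warning.
#'
#' @param members character vector of regulated gene/protein ids.
#' @param seed_nodes character vector of additional seed nodes.
#' @param edge_table data frame with columns `source`, `target`, `type` and
#'   optionally `directed` (logical, defaults to `FALSE`).
#' @return object of class `interaction_network`: list with `nodes` (data
#'   frame `id`, `is_seed`, `isolated`, `component`) and `edges`.
#' @export
build_direct_interaction_network <- function(members, seed_nodes = character(),
                                             edge_table) {
  nodes <- unique(c(members, seed_nodes))
  if (!length(nodes)) stopf("members and seed nodes are all empty")
  if (!all(c("source", "target", "type") %in% names(edge_table)))
    stopf("edge table needs columns source, target, type")
  if (is.null(edge_table$directed))
    edge_table$directed <- rep(FALSE, nrow(edge_table))

  bad <- !stats::complete.cases(edge_table[, c("source", "target", "type")]) |
    edge_table$source == "" | edge_table$target == ""
  if (any(bad))
    warning(sprintf("skipped %d malformed edge row(s)", sum(bad)), call. = FALSE)
  edges <- edge_table[!bad, , drop = FALSE]

  edges <- edges[edges$source %in% nodes & edges$target %in% nodes, ,
                 drop = FALSE]
  dup <- duplicated(edges[, c("source", "target", "type")])
  n_dup <- sum(dup)
  if (n_dup > 0)
    message(sprintf("collapsed %d duplicate edge(s)", n_dup))
  edges <- edges[!dup, , drop = FALSE]
  rownames(edges) <- NULL

  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = nodes))
  comp <- igraph::components(g)$membership
  deg <- igraph::degree(g)
  node_tab <- data.frame(id = nodes,
                         is_seed = nodes %in% seed_nodes,
                         isolated = deg[nodes] == 0,
                         component = unname(comp[nodes]),
                         row.names = NULL)
  structure(list(nodes = node_tab, edges = edges, n_duplicates = n_dup),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges,", max(x$nodes$component), "component(s),",
      sum(x$nodes$isolated), "isolated\n")
  invisible(x)
}

#' Rank network hubs by degree
#'
#' Degree counts unique neighbours, collapsing edge types and direction (two
#' edges of different types to the same partner contribute 1). Descending
#' order, ties broken by node id.
#'
#' @param network an [build_direct_interaction_network()] result.
#' @return data frame `id`, `degree`.
#' @export
rank_hubs <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  if (!nrow(network$nodes))
    return(data.frame(id = character(), degree = integer()))
  nbrs <- lapply(setNames(network$nodes$id, network$nodes$id), function(v) {
    unique(c(network$edges$target[network$edges$source == v],
             network$edges$source[network$edges$target == v]))
  })
  # a self-loop contributes the node itself as a neighbour; drop it
  deg <- vapply(names(nbrs), function(v) length(setdiff(nbrs[[v]], v)),
                integer(1))
  out <- data.frame(id = names(deg), degree = unname(deg), row.names = NULL)
  out[order(-out$degree, out$id), , drop = FALSE]
}
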