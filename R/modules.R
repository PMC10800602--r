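# single-FC degree of every node (count of incident single-class edges)
single_degree <- function(graph, edge_classes) {
  deg <- setNames(integer(length(graph$nodes)), graph$nodes)
  se <- edge_classes[edge_classes$class == "single", , drop = FALSE]
  if (nrow(se) > 0) {
    tab <- table(c(se$label_i, se$label_j))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Rank candidate hub nodes by single-FC degree
#'
#' Nodes are ranked by their count of incident single-class dysfunctional
#' edges; ties are broken by total dysfunctional degree, then by atlas
#' label order. The top-ranked node(s) are the natural hub seeds (the
#' thalamus role in the motivating analysis).
#'
#' @param graph a [dysfunction_graph()].
#' @param edge_classes output of [classify_edges()].
#' @return data.frame `label`, `single_fc_degree`, `total_degree`, ranked;
#'   empty when the graph has no single-class edges.
#' @export
find_hub_nodes <- function(graph, edge_classes = classify_edges(graph)) {
  sdeg <- single_degree(graph, edge_classes)
  if (all(sdeg == 0)) {
    return(data.frame(label = character(), single_fc_degree = integer(),
                      total_degree = integer(), stringsAsFactors = FALSE))
  }
  tdeg <- degree_profile(graph)$degree
  keep <- sdeg > 0
  out <- data.frame(label = names(sdeg)[keep],
                    single_fc_degree = as.integer(sdeg[keep]),
                    total_degree = as.integer(tdeg[keep]),
                    stringsAsFactors = FALSE)
  ord <- order(-out$single_fc_degree, -out$total_degree,
               match(out$label, graph$nodes))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify hub-node FCs among single-class edges
#'
#' A single-class edge is a **hub-node FC** when one of its endpoints is a
#' shared node of several regions' single-FC dysfunctions, i.e. carries at
#' least two incident single-class edges. In the motif
#' "Region 1--Region 7, Region 6--Region 7", node 7 is shared and both
#' edges are hub-node FCs; an isolated pendant single edge is not.
#'
#' @inheritParams find_hub_nodes
#' @return data.frame of qualifying edges (`label_i`, `label_j`).
#' @export
identify_hub_node_fcs <- function(graph, edge_classes = classify_edges(graph)) {
  se <- edge_classes[edge_classes$class == "single", , drop = FALSE]
  if (nrow(se) == 0) {
    return(data.frame(label_i = character(), label_j = character(),
                      stringsAsFactors = FALSE))
  }
  sdeg <- single_degree(graph, edge_classes)
  hub <- sdeg[se$label_i] >= 2 | sdeg[se$label_j] >= 2
  out <- se[hub, c("label_i", "label_j"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hierarchical level assignment from hub seeds
#'
#' Breadth-first distance from the seed set over the subgraph of
#' single-class edges (hub-node FCs are single-class edges, so the layering
#' spans both): seeds sit at level 0, their single-FC partners at level 1,
#' and so on. Nodes unreachable from any seed through single-class edges
#' are left unassigned.
#'
#' @inheritParams find_hub_nodes
#' @param seeds character vector of seed labels; defaults to the node(s)
#'   with maximal single-FC degree.
#' @return named integer vector of levels for reachable nodes.
#' @export
assign_levels <- function(graph, edge_classes = classify_edges(graph),
                          seeds = NULL) {
  if (is.null(seeds)) {
    rk <- find_hub_nodes(graph, edge_classes)
    assert_that(nrow(rk) > 0, "graph has no single-class edges to layer")
    seeds <- rk$label[rk$single_fc_degree == rk$single_fc_degree[1]]
  }
  assert_that(length(seeds) > 0, "seeds must be nonempty")
  known <- seeds %in% graph$nodes
  if (!all(known)) {
    warning("ignoring seed(s) not in atlas: ",
            paste(seeds[!known], collapse = ", "), call. = FALSE)
    seeds <- seeds[known]
  }
  assert_that(length(seeds) > 0, "no valid seeds remain")
  se <- edge_classes[edge_classes$class == "single", , drop = FALSE]
  g <- as_igraph(graph, se)
  d <- igraph::distances(g, v = seeds)
  lev <- apply(d, 2, min)
  lev <- lev[is.finite(lev)]
  setNames(as.integer(lev), names(lev))
}

#' Dysfunctional modules formed by network-FC edges
#'
#' Connected components of the subgraph induced by network-class edges,
#' ordered by decreasing size. Since every network-class edge lies on a
#' triangle, each module has at least three regions.
#'
#' @inheritParams find_hub_nodes
#' @return list of character vectors (region labels per module).
#' @export
network_fc_modules <- function(graph, edge_classes = classify_edges(graph)) {
  ne <- edge_classes[edge_classes$class == "network", , drop = FALSE]
  if (nrow(ne) == 0) return(list())
  g <- igraph::graph_from_data_frame(
    ne[, c("label_i", "label_j")], directed = FALSE)
  comp <- igraph::components(g)
  mods <- split(names(comp$membership), comp$membership)
  mods <- lapply(mods, function(m) m[order(match(m, graph$nodes))])
  mods[order(-vapply(mods, length, integer(1)))]
}

#' Full node-based module analysis
#'
#' Convenience wrapper returning hub ranking, hub-node FCs, hierarchical
#' levels from the top hub seed(s) and the network-FC modules in one call.
#'
#' @param graph a [dysfunction_graph()].
#' @param seeds optional seed override for [assign_levels()].
#' @return list of class `module_result`: `hub_ranking`, `hub_seeds`,
#'   `hub_node_fcs`, `levels`, `network_modules`, `edge_classes`.
#' @export
detect_modules <- function(graph, seeds = NULL) {
  ec <- classify_edges(graph)
  rk <- find_hub_nodes(graph, ec)
  if (is.null(seeds) && nrow(rk) > 0) {
    seeds <- rk$label[rk$single_fc_degree == rk$single_fc_degree[1]]
  }
  levels <- if (!is.null(seeds)) assign_levels(graph, ec, seeds) else
    setNames(integer(0), character(0))
  structure(list(hub_ranking = rk,
                 hub_seeds = seeds %||% character(0),
                 hub_node_fcs = identify_hub_node_fcs(graph, ec),
                 levels = levels,
                 network_modules = network_fc_modules(graph, ec),
                 edge_classes = ec),
            class = "module_result")
}
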