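#' Signed dysfunction graph
#'
#' Container for the binarized group-difference connectome: an undirected
#' simple graph over the atlas regions whose edges are the FC differences
#' surviving multiple-comparison correction, each signed as increased or
#' decreased in patients.
#'
#' @param nodes character vector of atlas region labels (the full node
#'   set, including isolated regions).
#' @param edges data.frame with columns `label_i`, `label_j`, `sign`
#'   (`"increased"`/`"decreased"`), optionally `t_stat`, `p_value`.
#' @param alpha family-wise level used to build the graph.
#' @param m number of comparisons used in the correction.
#' @return an object of class `dysfunction_graph`.
#' @export
dysfunction_graph <- function(nodes, edges = NULL, alpha = NA_real_,
                              m = NA_real_) {
  nodes <- as.character(nodes)
  assert_that(!anyDuplicated(nodes), "node labels must be unique")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(label_i = character(), label_j = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges)
  assert_that(all(c("label_i", "label_j", "sign") %in% names(edges)),
              "edges need label_i, label_j and sign columns")
  edges$label_i <- as.character(edges$label_i)
  edges$label_j <- as.character(edges$label_j)
  assert_that(all(c(edges$label_i, edges$label_j) %in% nodes),
              "edge endpoints must be graph nodes")
  assert_that(all(edges$label_i != edges$label_j), "self-loops not allowed")
  assert_that(all(edges$sign %in% c("increased", "decreased")),
              "edge sign must be 'increased' or 'decreased'")
  # canonical endpoint order, no duplicate edges
  swap <- match(edges$label_i, nodes) > match(edges$label_j, nodes)
  tmp <- edges$label_i[swap]
  edges$label_i[swap] <- edges$label_j[swap]
  edges$label_j[swap] <- tmp
  assert_that(!anyDuplicated(paste(edges$label_i, edges$label_j, sep = "|")),
              "duplicate edges not allowed")
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, alpha = alpha, m = m),
            class = "dysfunction_graph")
}

#' @export
print.dysfunction_graph <- function(x, ...) {
  cat("dysfunction graph:", length(x$nodes), "regions,",
      nrow(x$edges), "edges",
      sprintf("(%d increased, %d decreased)\n",
              sum(x$edges$sign == "increased"),
              sum(x$edges$sign == "decreased")))
  if (!is.na(x$alpha)) {
    cat(sprintf("  Bonferroni alpha = %g over m = %g comparisons\n",
                x$alpha, x$m))
  }
  invisible(x)
}

# adjacency matrix over all atlas nodes (0/1, symmetric)
graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0L, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0) {
    i <- match(graph$edges$label_i, graph$nodes)
    j <- match(graph$edges$label_j, graph$nodes)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  A
}

# igraph view (non-isolated handling preserved by passing all vertices)
as_igraph <- function(graph, edges = graph$edges) {
  igraph::graph_from_data_frame(
    edges[, c("label_i", "label_j"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes))
}

#' Classify dysfunctional edges as single-FC or network-FC
#'
#' An edge (R, X) is **network-FC** iff some third region is dysfunctionally
#' connected to both R and X — i.e. the edge lies on at least one triangle
#' of the dysfunction graph, forming a closed chain such as
#' R1--R4--R5--R1. Every other edge is **single-FC**: the partner region is
#' solitary within the index region's dysfunctional neighbourhood. The rule
#' is symmetric in the two endpoints.
#'
#' @param graph a [dysfunction_graph()].
#' @return data.frame with `label_i`, `label_j`, `class`
#'   (`"single"`/`"network"`).
#' @export
classify_edges <- function(graph) {
  edges <- graph$edges
  if (nrow(edges) == 0) {
    return(data.frame(label_i = character(), label_j = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  A <- graph_adjacency(graph)
  common <- A %*% A  # (i,j): number of shared neighbours
  i <- match(edges$label_i, graph$nodes)
  j <- match(edges$label_j, graph$nodes)
  in_triangle <- common[cbind(i, j)] > 0
  data.frame(label_i = edges$label_i, label_j = edges$label_j,
             class = ifelse(in_triangle, "network", "single"),
             stringsAsFactors = FALSE)
}

#' Single-FC / network-FC profile of one region
#'
#' Partitions the region's incident dysfunctional edges into single-FC and
#' network-FC partners and reports both counts and percentage ratios
#' (count divided by the region's total dysfunctional edges, rounded
#' half-up to one decimal). Following the reporting convention, ratios are
#' flagged as undefined (`NA`) for regions with fewer than two
#' dysfunctional edges.
#'
#' @param graph a [dysfunction_graph()].
#' @param region region label.
#' @param edge_classes optional precomputed [classify_edges()] output.
#' @return list of class `region_classification`: `region`,
#'   `single_partners`, `network_partners`, `n_single`, `n_network`,
#'   `degree`, `single_ratio`, `network_ratio`.
#' @export
classify_region <- function(graph, region, edge_classes = classify_edges(graph)) {
  assert_that(region %in% graph$nodes,
              paste0("region '", region, "' not in atlas"))
  inc <- edge_classes$label_i == region | edge_classes$label_j == region
  ec <- edge_classes[inc, , drop = FALSE]
  partner <- ifelse(ec$label_i == region, ec$label_j, ec$label_i)
  n_single <- sum(ec$class == "single")
  n_network <- sum(ec$class == "network")
  degree <- n_single + n_network
  if (degree > 1) {
    sr <- round_half_up(100 * n_single / degree, 1)
    nr <- round_half_up(100 * n_network / degree, 1)
  } else {
    sr <- nr <- NA_real_
  }
  structure(list(region = region,
                 single_partners = partner[ec$class == "single"],
                 network_partners = partner[ec$class == "network"],
                 n_single = n_single, n_network = n_network,
                 degree = degree,
                 single_ratio = sr, network_ratio = nr),
            class = "region_classification")
}

#' Classify every atlas region
#'
#' @param graph a [dysfunction_graph()].
#' @return named list of [classify_region()] results, one per atlas node.
#' @export
classify_all_regions <- function(graph) {
  ec <- classify_edges(graph)
  setNames(lapply(graph$nodes, classify_region, graph = graph,
                  edge_classes = ec),
           graph$nodes)
}

#' Whole-brain summary of dysfunction ratios
#'
#' Buckets the regions with more than one dysfunctional edge into
#' absolute single-FC (100% single), majority single (> 50%), equal
#' (50/50) and majority network (> 50% network), and reports the
#' favour-single / favour-network percentages over the **full atlas**
#' (isolated and degree-1 regions stay in the denominator), matching the
#' whole-brain reporting convention.
#'
#' @param classifications list of `region_classification` objects (one per
#'   atlas region), e.g. from [classify_all_regions()].
#' @param n_atlas atlas size; defaults to `length(classifications)`.
#' @return list: `n_zero_degree`, `n_one_degree`, `n_multi_degree`,
#'   `n_absolute_single`, `n_majority_single`, `n_equal`,
#'   `n_majority_network`, `pct_favor_single`, `pct_favor_network`.
#' @export
whole_brain_summary <- function(classifications,
                                n_atlas = length(classifications)) {
  deg <- vapply(classifications, function(x) x$degree, numeric(1))
  multi <- classifications[deg > 1]
  ns <- vapply(multi, function(x) x$n_single, numeric(1))
  nn <- vapply(multi, function(x) x$n_network, numeric(1))
  n_abs <- sum(nn == 0)
  n_maj_s <- sum(nn > 0 & ns > nn)
  n_eq <- sum(ns == nn)
  n_maj_n <- sum(nn > ns)
  list(n_zero_degree = sum(deg == 0),
       n_one_degree = sum(deg == 1),
       n_multi_degree = sum(deg > 1),
       n_absolute_single = n_abs,
       n_majority_single = n_maj_s,
       n_equal = n_eq,
       n_majority_network = n_maj_n,
       pct_favor_single = round_half_up(100 * (n_abs + n_maj_s) / n_atlas, 1),
       pct_favor_network = round_half_up(100 * n_maj_n / n_atlas, 1))
}

#' Network-dysfunction ratio map for atlas visualization
#'
#' Returns each region's network-FC ratio (0-100) for colour mapping onto
#' a brain atlas; regions with fewer than two dysfunctional edges are
#' omitted (their ratio is undefined).
#'
#' @param classifications list of `region_classification` objects.
#' @return named numeric vector, values in \[0, 100\].
#' @export
ratio_map <- function(classifications) {
  vals <- vapply(classifications, function(x) x$network_ratio, numeric(1))
  vals[!is.na(vals)]
}
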