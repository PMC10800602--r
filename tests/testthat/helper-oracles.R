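# shared fixtures and independent oracles used across test files

# build a dysfunction graph from an edge matrix/list of index pairs over
# nodes "N1".."Nk" (or explicit labels), all edges signed "increased"
toy_graph <- function(n_nodes, edges, labels = paste0("N", seq_len(n_nodes)),
                      signs = NULL) {
  e <- if (length(edges) == 0) {
    data.frame(label_i = character(), label_j = character(),
               sign = character())
  } else {
    em <- do.call(rbind, edges)
    data.frame(label_i = labels[em[, 1]], label_j = labels[em[, 2]],
               sign = signs %||% rep("increased", nrow(em)),
               stringsAsFactors = FALSE)
  }
  dysfunction_graph(labels, e)
}

# Erdos-Renyi style random edge set on n nodes
random_edges <- function(n, p) {
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  on <- runif(nrow(pairs)) < p
  lapply(which(on), function(k) c(pairs[k, 1], pairs[k, 2]))
}

# O(n^3) triangle oracle: class of every edge by exhaustive enumeration of
# all third nodes
oracle_edge_classes <- function(graph) {
  A <- matrix(0L, length(graph$nodes), length(graph$nodes),
              dimnames = list(graph$nodes, graph$nodes))
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges$label_i[r]; j <- graph$edges$label_j[r]
    A[i, j] <- A[j, i] <- 1L
  }
  cls <- character(nrow(graph$edges))
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges$label_i[r]; j <- graph$edges$label_j[r]
    tri <- FALSE
    for (k in graph$nodes) {
      if (k != i && k != j && A[i, k] == 1L && A[j, k] == 1L) tri <- TRUE
    }
    cls[r] <- if (tri) "network" else "single"
  }
  data.frame(label_i = graph$edges$label_i, label_j = graph$edges$label_j,
             class = cls, stringsAsFactors = FALSE)
}

# Floyd-Warshall shortest paths on a 0/1 adjacency matrix
oracle_shortest_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# local efficiency by brute force: Floyd-Warshall on the neighbour-induced
# subgraph
oracle_local_efficiency <- function(A, node) {
  idx <- which(colnames(A) == node)
  nb <- which(A[idx, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  D <- oracle_shortest_paths(A[nb, nb, drop = FALSE])
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (k * (k - 1))
}

# textbook first-order partial correlation recursion
oracle_partial_r <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# AR(1)-structured correlation matrix (Toeplitz rho^|i-j|), always PD
ar1_correlation <- function(n, rho) {
  outer(seq_len(n), seq_len(n), function(i, j) rho^abs(i - j))
}

# fabricate a region classification record with given single/network counts
# (only the count fields feed whole_brain_summary)
fake_classification <- function(n_single, n_network, region = "X") {
  degree <- n_single + n_network
  structure(list(region = region, single_partners = character(),
                 network_partners = character(),
                 n_single = n_single, n_network = n_network,
                 degree = degree,
                 single_ratio = if (degree > 1)
                   round_half_up(100 * n_single / degree, 1) else NA_real_,
                 network_ratio = if (degree > 1)
                   round_half_up(100 * n_network / degree, 1) else NA_real_),
            class = "region_classification")
}

# a compact cohort with strong implanted effects that the full pipeline
# should recover exactly: effect edges sit on a well-connected base
# (population |r| = 0.5 in controls) so they pass the per-subject screen
recovery_config <- function(seed, n_per_group = 100, delta = 0.3) {
  n <- 20
  base <- diag(n)
  pairs <- cbind(seq(1, n, by = 2), seq(2, n, by = 2))
  base[pairs] <- 0.5
  base[pairs[, c(2, 1)]] <- 0.5
  cohort_config(
    n_per_group = n_per_group, n_regions = n, n_timepoints = 195,
    base_matrix = base,
    effect_edges = data.frame(i = c(1, 5), j = c(2, 6),
                              delta = c(delta, delta)),
    seed = seed)
}

# a dysfunction graph in which one index region has 14 solitary partners
# and 8 partners interconnected in pairs (four triangles through the hub)
hub_22_graph <- function() {
  labels <- c("HUB", paste0("P", 1:22))
  edges <- lapply(1:22, function(k) c(1, k + 1))
  edges <- c(edges, list(c(16, 17), c(18, 19), c(20, 21), c(22, 23)))
  toy_graph(23, edges, labels)
}
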