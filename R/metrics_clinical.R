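#' Nodal local efficiency
#'
#' For node i with degree k >= 2, the average inverse shortest-path length
#' between all ordered pairs of its neighbours, with paths restricted to
#' the subgraph induced by the neighbour set:
#' `E_loc(i) = 1 / (k (k - 1)) * sum_{j != h in N(i)} 1 / d(j, h)`.
#' Unreachable pairs contribute 0, so the value lies in \[0, 1\]: 1 when
#' the neighbourhood is a complete graph, 0 when it carries no edges or
#' the node has fewer than two neighbours. Higher values indicate more
#' efficient information transfer among the node's local network.
#'
#' @param graph a [dysfunction_graph()] or a symmetric 0/1 adjacency
#'   matrix with region labels as dimnames.
#' @param node region label.
#' @return local efficiency in \[0, 1\].
#' @export
local_efficiency <- function(graph, node) {
  A <- if (inherits(graph, "dysfunction_graph")) graph_adjacency(graph)
       else as.matrix(graph)
  assert_that(node %in% colnames(A),
              paste0("node '", node, "' not in graph"))
  nb <- colnames(A)[A[node, ] > 0]
  k <- length(nb)
  if (k < 2) return(0)
  sub <- A[nb, nb, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  d <- igraph::distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (k * (k - 1))
}

#' Subject-level local efficiency from an FC matrix
#'
#' Binarizes one subject's FC matrix at `|r| > threshold` (default 0.23,
#' the cohort screening value) and computes [local_efficiency()] at the
#' requested node. This supplies the per-subject metric that clinical
#' scores are correlated against.
#'
#' @param fc an `fc_matrix`.
#' @param node region label.
#' @param threshold binarization threshold on `|r|`.
#' @return local efficiency in \[0, 1\].
#' @export
subject_local_efficiency <- function(fc, node, threshold = 0.23) {
  A <- (abs(unclass(fc)) > threshold) * 1L
  A[is.na(A)] <- 0L
  diag(A) <- 0L
  local_efficiency(A, node)
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with p from the t transform,
#' `t = r sqrt((n - 2) / (1 - r^2))`, on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3, finite).
#' @return one-row data.frame: `r`, `p`, `n`, `df`, `covariates` ("").
#' @export
pearson_with_p <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 3, "need at least 3 complete observations")
  assert_that(sd(x) > 0 && sd(y) > 0,
              "degenerate input: zero variance in x or y")
  r <- cor(x, y)
  df <- n - 2
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df)
  }
  data.frame(r = r, p = p, n = n, df = df, covariates = "",
             stringsAsFactors = FALSE)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' projection on the covariates (plus intercept); the p-value uses the t
#' transform with `n - n_covariates - 2` degrees of freedom. With no
#' covariates this reduces exactly to [pearson_with_p()].
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix or data.frame (n rows), or `NULL`.
#' @return one-row data.frame: `r`, `p`, `n`, `df`, `covariates`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(pearson_with_p(x, y))
  }
  Z <- as.matrix(as.data.frame(covariates))
  assert_that(nrow(Z) == length(x) && length(x) == length(y),
              "x, y and covariates must agree in length")
  ok <- complete.cases(x, y, Z)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  X <- cbind(1, Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- setdiff(seq_len(ncol(X)), keep) - 1
    warning("dropping collinear covariate column(s): ",
            paste(colnames(Z)[dropped] %||% dropped, collapse = ", "),
            call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  k <- ncol(X) - 1
  n <- length(x)
  assert_that(n > k + 2, "need n > number of covariates + 2")
  rx <- qr.resid(qr(X), x)
  ry <- qr.resid(qr(X), y)
  if (sd(rx) <= 1e-10 * max(sd(x), 1e-300) ||
      sd(ry) <= 1e-10 * max(sd(y), 1e-300)) {
    stop_dc("degenerate: x or y fully explained by the covariates")
  }
  r <- cor(rx, ry)
  df <- n - k - 2
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df)
  }
  data.frame(r = r, p = p, n = n, df = df,
             covariates = paste(colnames(Z), collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Correlate a nodal metric with clinical scores across patients
#'
#' For each requested clinical score, reports the plain Pearson
#' correlation between the per-patient metric (e.g. subject-level local
#' efficiency of a hub node) and the score, and — when covariates are
#' given — the partial correlation controlling for them. Patients with a
#' missing score or covariate are dropped per row, with a message.
#'
#' @param metric_values named numeric vector (names = patient subject
#'   ids).
#' @param meta metadata data.frame.
#' @param score_names character vector of score columns in `meta`.
#' @param covariate_names character vector of covariate columns (e.g.
#'   `c("cpz_equivalent", "age", "sex")`), or `NULL` for plain Pearson
#'   only. A `sex` covariate is coded as a male indicator.
#' @param node label of the metric's node, recorded in the output.
#' @return data.frame: `node`, `score`, `covariates`, `r`, `p`, `n`.
#' @export
clinical_correlation_table <- function(metric_values, meta, score_names,
                                       covariate_names = NULL,
                                       node = NA_character_) {
  pats <- meta[meta$group == "patient", , drop = FALSE]
  assert_that(all(pats$subject_id %in% names(metric_values)),
              "metric values required for every patient")
  m <- metric_values[pats$subject_id]
  rows <- list()
  for (sc in score_names) {
    assert_that(sc %in% names(pats),
                paste0("metadata has no score column '", sc, "'"))
    y <- pats[[sc]]
    ok <- !is.na(y)
    if (any(!ok)) {
      message(sum(!ok), " patient(s) without '", sc, "' dropped")
    }
    res <- pearson_with_p(m[ok], y[ok])
    rows[[length(rows) + 1]] <- data.frame(
      node = node, score = sc, covariates = "",
      r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE)
    if (!is.null(covariate_names)) {
      Z <- pats[, covariate_names, drop = FALSE]
      if ("sex" %in% names(Z)) Z$sex <- as.numeric(Z$sex == "male")
      Z <- as.data.frame(lapply(Z, as.numeric))
      okz <- ok & complete.cases(Z)
      resp <- partial_corr(m[okz], y[okz], Z[okz, , drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        node = node, score = sc,
        covariates = paste(covariate_names, collapse = "+"),
        r = resp$r, p = resp$p, n = resp$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
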