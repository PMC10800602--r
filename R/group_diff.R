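# design matrix for the edge-wise group model: intercept, group indicator
# (patient = 1, so positive effects mean FC increased in patients), age,
# and a male indicator. Collinear covariates are dropped with a warning.
build_group_design <- function(meta) {
  assert_that(all(c("group", "age", "sex") %in% names(meta)),
              "metadata needs group, age and sex columns")
  g <- unique(meta$group)
  assert_that(length(g) == 2, "both groups must be represented")
  X <- cbind(intercept = 1,
             group = as.numeric(meta$group == "patient"),
             age = meta$age,
             sex = as.numeric(meta$sex == "male"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    assert_that(!"group" %in% dropped,
                "group indicator is collinear with the covariates")
    warning("dropping collinear covariate(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  X
}

# OLS of each column of y on X; returns group coefficient, its t and
# two-sided p (df = n - ncol(X)), vectorized across columns
ols_group_stats <- function(X, y) {
  y <- as.matrix(y)
  n <- nrow(X)
  p <- ncol(X)
  assert_that(n >= p + 1, "need more subjects than model parameters")
  XtX_inv <- chol2inv(chol(crossprod(X)))
  B <- XtX_inv %*% crossprod(X, y)
  resid <- y - X %*% B
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  gi <- which(colnames(X) == "group")
  se <- sqrt(sigma2 * XtX_inv[gi, gi])
  beta <- B[gi, ]
  # a numerically perfect fit (e.g. identical values in both groups) has
  # zero residual variance up to rounding; report t = 0, p = 1 there
  yscale <- pmax(colMeans(y^2), .Machine$double.xmin)
  zero_resid <- sigma2 <= 1e-20 * yscale
  zero_beta <- abs(beta) <= 1e-8 * sqrt(yscale)
  t_stat <- ifelse(!zero_resid, beta / se,
                   ifelse(zero_beta, 0, sign(beta) * Inf))
  p_val <- ifelse(!zero_resid, 2 * pt(-abs(t_stat), df),
                  ifelse(zero_beta, 1, 0))
  data.frame(beta_group = as.numeric(beta), t_stat = as.numeric(t_stat),
             p_value = as.numeric(p_val), n_used = n)
}

#' Covariate-adjusted group test for one edge
#'
#' Ordinary least squares of the per-subject FC value on a patient/control
#' indicator, age and sex; reports the group coefficient with its t
#' statistic and two-sided p-value (t distribution, n minus number of model
#' parameters degrees of freedom). If the two groups carry identical FC
#' values the test degenerates to t = 0, p = 1.
#'
#' @param fc_values numeric vector, one FC value per subject (same order as
#'   `meta`).
#' @param meta metadata data.frame with `group`, `age`, `sex`.
#' @return one-row data.frame: `beta_group`, `t_stat`, `p_value`, `n_used`.
#' @export
edge_regression <- function(fc_values, meta) {
  assert_that(length(fc_values) == nrow(meta),
              "one FC value per subject required")
  ok <- !is.na(fc_values)
  X <- build_group_design(meta[ok, , drop = FALSE])
  ols_group_stats(X, fc_values[ok])
}

#' Test every screened edge for a group difference
#'
#' Runs [edge_regression()] on each edge retained by the screening mask.
#' Subjects with a missing FC value on an edge are dropped for that edge
#' only.
#'
#' @param fcs list of `fc_matrix` objects (one per subject, same order as
#'   `meta`).
#' @param meta metadata data.frame.
#' @param mask an `edge_mask` from [consensus_screen()].
#' @return data.frame with one row per masked edge: `label_i`, `label_j`,
#'   `beta_group`, `t_stat`, `p_value`, `n_used`.
#' @export
test_all_edges <- function(fcs, meta, mask) {
  labs <- colnames(mask)
  assert_that(length(fcs) == nrow(meta),
              "one FC matrix per metadata row required")
  for (fc in fcs) {
    assert_that(identical(colnames(fc), labs),
                "FC matrices and mask must share label order")
  }
  idx <- which(upper.tri(mask) & mask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(label_i = character(), label_j = character(),
                      beta_group = numeric(), t_stat = numeric(),
                      p_value = numeric(), n_used = integer()))
  }
  Y <- vapply(fcs, function(fc) unclass(fc)[idx], numeric(nrow(idx)))
  Y <- t(Y)  # subjects x edges
  if (anyNA(Y)) {
    res <- do.call(rbind, lapply(seq_len(ncol(Y)), function(k) {
      edge_regression(Y[, k], meta)
    }))
  } else {
    X <- build_group_design(meta)
    res <- ols_group_stats(X, Y)
  }
  cbind(data.frame(label_i = labs[idx[, 1]], label_j = labs[idx[, 2]],
                   stringsAsFactors = FALSE), res)
}

#' Binarize edge tests into a signed dysfunction graph
#'
#' An edge enters the graph iff its two-sided p-value is strictly below
#' `alpha / m` (Bonferroni). `m` defaults to the number of unique region
#' pairs of the full atlas, `N (N - 1) / 2` — 4,005 for the 90-region
#' atlas — regardless of how many edges survived screening. The edge sign
#' records whether patient FC is increased (positive group t) or decreased.
#'
#' @param results data.frame from [test_all_edges()].
#' @param nodes character vector of all atlas region labels (defines the
#'   node set and the default `m`).
#' @param alpha family-wise significance level (default 0.05).
#' @param m number of comparisons; `NULL` (default) uses
#'   `choose(length(nodes), 2)`.
#' @return a [dysfunction_graph()].
#' @export
bonferroni_binarize <- function(results, nodes, alpha = 0.05, m = NULL) {
  m <- m %||% choose(length(nodes), 2)
  assert_that(m >= 1, "m must be >= 1")
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  keep <- results$p_value < alpha / m
  edges <- results[keep, , drop = FALSE]
  dysfunction_graph(
    nodes = nodes,
    edges = data.frame(
      label_i = edges$label_i, label_j = edges$label_j,
      sign = ifelse(edges$t_stat > 0, "increased", "decreased"),
      t_stat = edges$t_stat, p_value = edges$p_value,
      stringsAsFactors = FALSE),
    alpha = alpha, m = m)
}

#' Per-region count of dysfunctional edges
#'
#' @param graph a [dysfunction_graph()].
#' @return list with `degree` (named integer vector over all atlas nodes)
#'   and `breakdown` (counts of degree-0, degree-1 and degree->1 nodes).
#' @export
degree_profile <- function(graph) {
  deg <- setNames(integer(length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges) > 0) {
    tab <- table(c(graph$edges$label_i, graph$edges$label_j))
    deg[names(tab)] <- as.integer(tab)
  }
  list(degree = deg,
       breakdown = c(n_zero = sum(deg == 0),
                     n_one = sum(deg == 1),
                     n_multi = sum(deg > 1)))
}

#' Leave-one-subject-out sensitivity of the edge model
#'
#' For each masked edge and each subject, the group model is refitted on
#' the remaining subjects and the held-out subject's FC predicted from its
#' covariates; the squared prediction errors are averaged per edge.
#' Computed exactly through the leave-one-out identity
#' `e_(-i) = e_i / (1 - h_ii)` for linear least squares, which equals the
#' fold-by-fold refit.
#'
#' @inheritParams test_all_edges
#' @return list with `per_edge` (data.frame: labels, `mean_sq_error`) and
#'   `range` (min and max of the per-edge means).
#' @export
loso_sensitivity <- function(fcs, meta, mask) {
  assert_that(nrow(meta) >= 5, "need at least 5 subjects")
  labs <- colnames(mask)
  idx <- which(upper.tri(mask) & mask, arr.ind = TRUE)
  assert_that(nrow(idx) > 0, "mask retains no edges")
  Y <- t(vapply(fcs, function(fc) unclass(fc)[idx], numeric(nrow(idx))))
  X <- build_group_design(meta)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  H <- rowSums((X %*% XtX_inv) * X)  # leverages
  B <- XtX_inv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  loo <- resid / (1 - H)
  mse <- colMeans(loo^2)
  list(per_edge = data.frame(label_i = labs[idx[, 1]],
                             label_j = labs[idx[, 2]],
                             mean_sq_error = as.numeric(mse),
                             stringsAsFactors = FALSE),
       range = c(min = min(mse), max = max(mse)))
}

#' Head-motion QC comparison between groups
#'
#' Welch two-sample t-test of mean framewise displacement (patients minus
#' controls) with a 95% confidence interval for the mean difference.
#'
#' @param meta metadata data.frame with `group` and `fd_power`.
#' @return list: `t`, `df`, `p`, `ci` (length-2), `mean_diff`.
#' @export
compare_motion <- function(meta) {
  bad <- meta$subject_id[is.na(meta$fd_power)]
  if (length(bad) > 0) {
    stop_dc("fd_power missing for subject(s): ", paste(bad, collapse = ", "))
  }
  pat <- meta$fd_power[meta$group == "patient"]
  ctl <- meta$fd_power[meta$group == "control"]
  compare_motion_summary(mean(pat), sd(pat), length(pat),
                         mean(ctl), sd(ctl), length(ctl))
}

#' Head-motion comparison from printed summary statistics
#'
#' Same Welch test as [compare_motion()] but starting from group means,
#' standard deviations and sizes, as reported in a demographics table.
#'
#' @param mean_patient,sd_patient,n_patient patient-group summaries.
#' @param mean_control,sd_control,n_control control-group summaries.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list: `t`, `df`, `p`, `ci`, `mean_diff` (patient minus control).
#' @export
compare_motion_summary <- function(mean_patient, sd_patient, n_patient,
                                   mean_control, sd_control, n_control,
                                   conf_level = 0.95) {
  v1 <- sd_patient^2 / n_patient
  v2 <- sd_control^2 / n_control
  se <- sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n_patient - 1) + v2^2 / (n_control - 1))
  diff <- mean_patient - mean_control
  t_stat <- if (se > 0) diff / se else 0
  p <- if (se > 0) 2 * pt(-abs(t_stat), df) else 1
  half <- qt(1 - (1 - conf_level) / 2, df) * se
  list(t = t_stat, df = df, p = p,
       ci = c(diff - half, diff + half), mean_diff = diff)
}
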