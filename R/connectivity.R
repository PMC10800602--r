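#' Construct a subject's ROI time-series object
#'
#' @param data numeric matrix, T timepoints x N regions (BOLD, arbitrary
#'   units). Column names, if present, must agree with `region_labels`.
#' @param subject_id subject identifier.
#' @param region_labels ordered atlas labels for the columns; defaults to
#'   existing column names.
#' @return an object of class `roi_ts` (the data matrix with labelled
#'   columns and a `subject_id` attribute).
#' @export
roi_timeseries <- function(data, subject_id, region_labels = colnames(data)) {
  data <- as.matrix(data)
  assert_that(is.numeric(data), "time-series data must be numeric")
  assert_that(!anyNA(data),
              paste0("time series for subject ", subject_id,
                     " contains missing values"))
  assert_that(nrow(data) >= 3, "need at least 3 timepoints")
  assert_that(!is.null(region_labels) && length(region_labels) == ncol(data),
              "region_labels must name every column")
  colnames(data) <- region_labels
  structure(data, subject_id = as.character(subject_id), class = c("roi_ts", "matrix"))
}

#' Subject-level functional connectivity matrix
#'
#' Computes the N x N Pearson correlation matrix of the regional BOLD time
#' series: entry (i, j) is the correlation of region i's and region j's
#' signals over time. Zero-variance regions (flat signal) yield NA rows and
#' columns with a warning; such edges are excluded from downstream screens.
#'
#' @param ts a `roi_ts` object (or plain T x N matrix with column labels).
#' @param subject_id identifier; defaults to the one carried by `ts`.
#' @return an `fc_matrix`: symmetric N x N matrix, unit diagonal,
#'   `subject_id` attribute.
#' @export
compute_fc <- function(ts, subject_id = attr(ts, "subject_id")) {
  m <- unclass(ts)
  assert_that(is.matrix(m) && is.numeric(m), "ts must be a numeric matrix")
  assert_that(!anyNA(m), "time series contains missing values")
  assert_that(nrow(m) >= 3, "need at least 3 timepoints")
  vars <- apply(m, 2, stats::var)
  flat <- vars == 0
  fc <- suppressWarnings(cor(m))
  if (any(flat)) {
    warning("zero-variance region(s) excluded from FC: ",
            paste(colnames(m)[flat], collapse = ", "), call. = FALSE)
    fc[flat, ] <- NA_real_
    fc[, flat] <- NA_real_
  }
  diag(fc) <- 1
  structure(fc, subject_id = as.character(subject_id %||% NA_character_),
            class = c("fc_matrix", "matrix"))
}

#' Cohort-wide edge screening by correlation magnitude
#'
#' Keeps candidate edges whose FC magnitude exceeds `r_threshold` according
#' to the selected policy:
#' \describe{
#'   \item{`"all"`}{(default) `|r| > r_threshold` in every subject — the
#'     strictest reading of a per-subject magnitude criterion.}
#'   \item{`"fraction"`}{`|r| > r_threshold` in at least a proportion `q`
#'     of subjects.}
#'   \item{`"mean"`}{the cohort mean of `|r|` exceeds `r_threshold`.}
#' }
#' Edges touching a region with NA correlations in any subject are dropped.
#'
#' @param fcs list of `fc_matrix` objects with identical region labels.
#' @param r_threshold magnitude threshold on Pearson r (default 0.23, the
#'   two-sided p < 0.001 critical value at ~193 residual df; see
#'   [critical_r()]).
#' @param policy one of `"all"`, `"fraction"`, `"mean"`.
#' @param q fraction of subjects required under `policy = "fraction"`.
#' @return an `edge_mask`: logical symmetric N x N matrix (diagonal FALSE)
#'   with attributes `r_threshold` and `policy`.
#' @export
consensus_screen <- function(fcs, r_threshold = 0.23,
                             policy = c("all", "fraction", "mean"),
                             q = 0.9) {
  policy <- match.arg(policy)
  assert_that(length(fcs) >= 1, "need at least one FC matrix")
  labs <- colnames(fcs[[1]])
  for (fc in fcs) {
    assert_that(identical(colnames(fc), labs),
                "all FC matrices must share the same region label order")
  }
  n <- length(labs)
  absr <- vapply(fcs, function(fc) abs(unclass(fc)), matrix(0, n, n))
  pass <- absr > r_threshold
  keep <- switch(policy,
    all      = apply(pass, c(1, 2), all),
    fraction = apply(pass, c(1, 2), mean) >= q,
    mean     = apply(absr, c(1, 2), mean) > r_threshold)
  keep[is.na(keep)] <- FALSE
  diag(keep) <- FALSE
  keep <- keep & t(keep)
  dimnames(keep) <- list(labs, labs)
  structure(keep, r_threshold = r_threshold, policy = policy,
            q = if (policy == "fraction") q else NULL,
            class = c("edge_mask", "matrix"))
}

#' Critical Pearson correlation for a two-sided test
#'
#' The smallest |r| significant at level `alpha` (two-sided) with `df`
#' residual degrees of freedom, via the t transform:
#' `r* = t* / sqrt(t*^2 + df)` with `t*` the upper `alpha/2` t quantile.
#' At alpha = 0.001 and df = 193 (195 usable timepoints) this is 0.234,
#' i.e. the |r| > 0.23 screening threshold.
#'
#' @param alpha two-sided significance level in (0, 1).
#' @param df residual degrees of freedom (n - 2 for a plain correlation).
#' @return the critical correlation magnitude.
#' @export
critical_r <- function(alpha, df) {
  assert_that(is.numeric(alpha) && length(alpha) == 1 &&
                alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  assert_that(is.numeric(df) && length(df) == 1 && df >= 1,
              "df must be >= 1")
  tstar <- qt(1 - alpha / 2, df)
  tstar / sqrt(tstar^2 + df)
}
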