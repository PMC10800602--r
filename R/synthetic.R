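#' Configuration for a synthetic two-group fMRI cohort
#'
#' Bundles and validates every knob of the cohort generator. Defaults mirror
#' a 200 + 200 schizophrenia/control resting-state cohort parcellated into
#' 90 regions with 195 usable volumes per subject: demographic summaries
#' (age ~43.6 years, balanced sex, ~96% right-handed), head motion
#' (mean FD ~0.15-0.16 mm), and patient-only PANSS/CPZ score distributions.
#'
#' @param n_per_group subjects per group (patients = controls).
#' @param n_regions number of atlas regions (>= 3; 90 uses the bundled
#'   AAL-90 abbreviations as labels).
#' @param n_timepoints usable volumes per subject (>= 10).
#' @param base_connectivity list with `density` (expected fraction of region
#'   pairs given a non-zero population correlation) and `strength` (the
#'   correlation magnitude placed on those pairs before projection to the
#'   nearest positive-definite correlation matrix).
#' @param effect_edges data.frame with columns `i`, `j`, `delta`: region
#'   index pairs whose population correlation is shifted by `delta` in the
#'   patient group. Pairs must be distinct and within 1..n_regions.
#' @param age_range two-element numeric, uniform age range in years.
#' @param sex_ratio proportion of males.
#' @param covariate_confounding coefficient coupling standardized age and
#'   sex to the effect-edge correlations of every subject (0 = none).
#' @param clinical_model list with `target_node` (label or index), `slope`,
#'   `noise_sd`, and optionally `score` (default `"panss_p3"`) and
#'   `intercept` (default 4): the linear model tying a patient clinical
#'   score to that node's local efficiency via
#'   [generate_clinical_scores()].
#' @param ar1 lag-1 autocorrelation of the latent signal (0 = i.i.d.
#'   timepoints, the default; the stationary cross-correlation structure is
#'   preserved for any value in (-1, 1)).
#' @param base_matrix optional explicit population correlation matrix for
#'   the control group, overriding the random construction (must be a valid
#'   correlation matrix of size `n_regions`).
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group,
                          n_regions = 90,
                          n_timepoints = 195,
                          base_connectivity = list(density = 0.05, strength = 0.5),
                          effect_edges = NULL,
                          age_range = c(20, 65),
                          sex_ratio = 0.5,
                          covariate_confounding = 0,
                          clinical_model = NULL,
                          ar1 = 0,
                          base_matrix = NULL,
                          seed = 1) {
  assert_that(n_per_group >= 1, "n_per_group must be >= 1")
  assert_that(n_regions >= 3, "n_regions must be >= 3")
  assert_that(n_timepoints >= 10, "n_timepoints must be >= 10")
  assert_that(is.list(base_connectivity) &&
                all(c("density", "strength") %in% names(base_connectivity)),
              "base_connectivity needs 'density' and 'strength'")
  assert_that(base_connectivity$density > 0 && base_connectivity$density < 1,
              "base_connectivity$density must be in (0, 1)")
  assert_that(base_connectivity$strength > 0 && base_connectivity$strength < 1,
              "base_connectivity$strength must be in (0, 1)")
  assert_that(abs(ar1) < 1, "ar1 must be in (-1, 1)")
  if (!is.null(effect_edges)) {
    effect_edges <- as.data.frame(effect_edges)
    assert_that(all(c("i", "j", "delta") %in% names(effect_edges)),
                "effect_edges needs columns i, j, delta")
    assert_that(all(effect_edges$i != effect_edges$j),
                "effect_edges must reference distinct regions")
    assert_that(all(c(effect_edges$i, effect_edges$j) >= 1) &&
                  all(c(effect_edges$i, effect_edges$j) <= n_regions),
                "effect_edges reference regions outside 1..n_regions")
    key <- edge_key(effect_edges$i, effect_edges$j)
    assert_that(!anyDuplicated(key), "effect_edges contains duplicate pairs")
  } else {
    effect_edges <- data.frame(i = integer(), j = integer(), delta = numeric())
  }
  if (!is.null(base_matrix)) {
    base_matrix <- as.matrix(base_matrix)
    assert_that(nrow(base_matrix) == n_regions &&
                  ncol(base_matrix) == n_regions,
                "base_matrix must be n_regions x n_regions")
    assert_that(isTRUE(all.equal(base_matrix, t(base_matrix))) &&
                  all(abs(diag(base_matrix) - 1) < 1e-12),
                "base_matrix must be a symmetric correlation matrix")
    assert_that(min(eigen(base_matrix, symmetric = TRUE,
                          only.values = TRUE)$values) > 0,
                "base_matrix must be positive definite")
  }
  if (!is.null(clinical_model)) {
    assert_that(all(c("target_node", "slope", "noise_sd") %in%
                      names(clinical_model)),
                "clinical_model needs target_node, slope, noise_sd")
    clinical_model$score <- clinical_model$score %||% "panss_p3"
    clinical_model$intercept <- clinical_model$intercept %||% 4
    assert_that(clinical_model$noise_sd >= 0, "noise_sd must be >= 0")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints),
                 base_connectivity = base_connectivity,
                 effect_edges = effect_edges,
                 age_range = age_range,
                 sex_ratio = sex_ratio,
                 covariate_confounding = covariate_confounding,
                 clinical_model = clinical_model,
                 ar1 = ar1,
                 base_matrix = base_matrix,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# random sparse symmetric signal structure projected to the nearest
# positive-definite correlation matrix (Matrix::nearPD); seeded by caller
make_base_correlation <- function(n, density, strength) {
  sigma <- diag(n)
  pairs <- which(upper.tri(sigma), arr.ind = TRUE)
  on <- runif(nrow(pairs)) < density
  vals <- strength * sample(c(-1, 1), sum(on), replace = TRUE)
  sigma[pairs[on, , drop = FALSE]] <- vals
  sigma[lower.tri(sigma)] <- t(sigma)[lower.tri(sigma)]
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-8) {
    sigma <- as.matrix(Matrix::nearPD(sigma, corr = TRUE,
                                      posd.tol = 1e-6)$mat)
  }
  sigma
}

# add patient deltas to the control matrix; fail loudly if any delta breaks
# the correlation bounds or positive definiteness
apply_effect_edges <- function(sigma, effect_edges) {
  if (nrow(effect_edges) == 0) return(sigma)
  out <- sigma
  for (k in seq_len(nrow(effect_edges))) {
    i <- effect_edges$i[k]; j <- effect_edges$j[k]; d <- effect_edges$delta[k]
    v <- out[i, j] + d
    if (abs(v) >= 1) {
      stop_dc(sprintf(
        "delta %.3f on edge (%d, %d) drives the population correlation to %.3f (outside (-1, 1))",
        d, i, j, v))
    }
    out[i, j] <- out[j, i] <- v
  }
  ev <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) {
    # identify which single delta (if any) already breaks PD to aid debugging
    for (k in seq_len(nrow(effect_edges))) {
      one <- sigma
      i <- effect_edges$i[k]; j <- effect_edges$j[k]
      one[i, j] <- one[j, i] <- one[i, j] + effect_edges$delta[k]
      if (min(eigen(one, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
        stop_dc(sprintf(
          "delta %.3f on edge (%d, %d) makes the patient correlation matrix non-positive-definite",
          effect_edges$delta[k], i, j))
      }
    }
    stop_dc("combined effect deltas make the patient correlation matrix non-positive-definite")
  }
  out
}

# T x N multivariate normal sample with marginal covariance sigma_chol'%*%
# sigma_chol; optional AR(1) temporal structure preserving the marginals
sample_timeseries <- function(n_t, chol_sigma, ar1 = 0) {
  n <- ncol(chol_sigma)
  z <- matrix(rnorm(n_t * n), n_t, n)
  if (ar1 != 0) {
    s <- sqrt(1 - ar1^2)
    for (t in 2:n_t) z[t, ] <- ar1 * z[t - 1, ] + s * z[t, ]
  }
  z %*% chol_sigma
}

#' Generate a synthetic two-group cohort of ROI time series
#'
#' Draws per-subject regional BOLD time series as stationary multivariate
#' Gaussian samples from group-specific population correlation matrices:
#' the control matrix is either supplied (`base_matrix`) or built as a
#' random sparse signal structure projected to the nearest
#' positive-definite correlation matrix; the patient matrix adds the
#' configured `delta` on each effect edge (validated to stay positive
#' definite). Subject metadata (age, sex, handedness, head motion,
#' patient-only PANSS/CPZ scores) are drawn to match the default cohort
#' profile, and the implanted effects are returned as ground truth so that
#' downstream detection can be scored.
#'
#' @param config a [cohort_config()].
#' @return a list of class `cohort` with elements
#'   \describe{
#'     \item{`timeseries`}{list of `roi_ts` matrices, one per subject;}
#'     \item{`meta`}{data.frame of subject metadata (one row per subject);}
#'     \item{`truth`}{list with `effect_edges` (i, j, delta and region
#'       labels), `sigma_control`, `sigma_patient`, and the
#'       `clinical_model` (if configured).}
#'   }
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"),
              "config must be built with cohort_config()")
  set.seed(config$seed)
  n <- config$n_regions
  labels <- default_region_labels(n)

  sigma_c <- config$base_matrix %||%
    make_base_correlation(n, config$base_connectivity$density,
                          config$base_connectivity$strength)
  dimnames(sigma_c) <- list(labels, labels)
  sigma_p <- apply_effect_edges(sigma_c, config$effect_edges)

  n_sub <- 2L * config$n_per_group
  group <- rep(c("patient", "control"), each = config$n_per_group)
  ids <- sprintf("S%04d", seq_len(n_sub))
  age <- runif(n_sub, config$age_range[1], config$age_range[2])
  sex <- ifelse(rbinom(n_sub, 1, config$sex_ratio) == 1, "male", "female")
  hand <- ifelse(runif(n_sub) < 0.96, "right", "left")
  # head motion: gamma with group means 0.16 (patients) / 0.15 (controls),
  # SDs 0.11 / 0.10, matching the cohort QC profile
  fd_mean <- ifelse(group == "patient", 0.16, 0.15)
  fd_sd <- ifelse(group == "patient", 0.11, 0.10)
  fd <- rgamma(n_sub, shape = (fd_mean / fd_sd)^2, rate = fd_mean / fd_sd^2)

  is_pat <- group == "patient"
  np <- sum(is_pat)
  trunc_norm <- function(n, mean, sd, lo) pmax(rnorm(n, mean, sd), lo)
  meta <- data.frame(
    subject_id = ids, group = group, age = age, sex = sex,
    handedness = hand, fd_power = fd,
    panss_total = NA_real_, panss_positive = NA_real_,
    panss_negative = NA_real_, panss_general = NA_real_,
    panss_p3 = NA_real_, panss_p6 = NA_real_,
    cpz_equivalent = NA_real_,
    stringsAsFactors = FALSE)
  meta$panss_positive[is_pat] <- trunc_norm(np, 9.6, 3.6, 7)
  meta$panss_negative[is_pat] <- trunc_norm(np, 9.8, 3.8, 7)
  meta$panss_general[is_pat] <- trunc_norm(np, 21.1, 6.1, 16)
  meta$panss_total[is_pat] <- meta$panss_positive[is_pat] +
    meta$panss_negative[is_pat] + meta$panss_general[is_pat]
  meta$panss_p3[is_pat] <- pmin(pmax(round(rnorm(np, 2, 1)), 1), 7)
  meta$panss_p6[is_pat] <- pmin(pmax(round(rnorm(np, 2, 1)), 1), 7)
  # CPZ-equivalent dose: lognormal matched to mean 403.2, SD 325.4 mg/day
  sdlog <- sqrt(log(1 + (325.4 / 403.2)^2))
  meta$cpz_equivalent[is_pat] <- rlnorm(np, log(403.2) - sdlog^2 / 2, sdlog)

  chol_c <- chol(sigma_c)
  chol_p <- chol(sigma_p)
  conf <- config$covariate_confounding
  age_z <- as.numeric(scale(age))
  sex_i <- as.numeric(sex == "male")

  ts <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    ch <- if (is_pat[s]) chol_p else chol_c
    if (conf != 0 && nrow(config$effect_edges) > 0) {
      sig <- if (is_pat[s]) sigma_p else sigma_c
      shift <- conf * (age_z[s] + (sex_i[s] - 0.5))
      for (k in seq_len(nrow(config$effect_edges))) {
        i <- config$effect_edges$i[k]; j <- config$effect_edges$j[k]
        v <- max(min(sig[i, j] + shift, 0.99), -0.99)
        sig[i, j] <- sig[j, i] <- v
      }
      # keep the per-subject matrix positive definite: shrink the
      # perturbation towards the group matrix until Cholesky succeeds
      base <- if (is_pat[s]) sigma_p else sigma_c
      w <- 1
      repeat {
        cand <- w * sig + (1 - w) * base
        ch_try <- tryCatch(chol(cand), error = function(e) NULL)
        if (!is.null(ch_try)) { ch <- ch_try; break }
        w <- w / 2
        if (w < 1e-3) { ch <- if (is_pat[s]) chol_p else chol_c; break }
      }
    }
    x <- sample_timeseries(config$n_timepoints, ch, config$ar1)
    ts[[s]] <- roi_timeseries(x, ids[s], labels)
  }

  truth_edges <- config$effect_edges
  if (nrow(truth_edges) > 0) {
    truth_edges$label_i <- labels[truth_edges$i]
    truth_edges$label_j <- labels[truth_edges$j]
  } else {
    truth_edges$label_i <- character()
    truth_edges$label_j <- character()
  }
  structure(list(timeseries = ts, meta = meta,
                 truth = list(effect_edges = truth_edges,
                              sigma_control = sigma_c,
                              sigma_patient = sigma_p,
                              clinical_model = config$clinical_model),
                 config = config),
            class = "cohort")
}

#' Couple a patient clinical score to a nodal graph metric
#'
#' Overwrites the configured clinical score for every patient with
#' `intercept + slope * metric + N(0, noise_sd)`; controls are untouched.
#' With `noise_sd = 0` the resulting score is an exact affine function of
#' the metric, so its Pearson correlation with the metric is +/-1 by the
#' sign of `slope`.
#'
#' @param meta subject metadata data.frame (see [generate_cohort()]).
#' @param metric_values named numeric vector, one value per patient
#'   subject_id (typically a nodal local efficiency).
#' @param model list with `score` (metadata column), `intercept`, `slope`,
#'   `noise_sd`.
#' @param seed integer seed for the noise draw.
#' @return `meta` with the score column replaced for patients.
#' @export
generate_clinical_scores <- function(meta, metric_values, model, seed = 1) {
  assert_that(all(c("slope", "noise_sd") %in% names(model)),
              "model needs slope and noise_sd")
  score <- model$score %||% "panss_p3"
  intercept <- model$intercept %||% 4
  assert_that(score %in% names(meta),
              paste0("metadata has no column '", score, "'"))
  pats <- meta$subject_id[meta$group == "patient"]
  missing <- setdiff(pats, names(metric_values))
  if (length(missing) > 0) {
    stop_dc("metric values missing for subject(s): ",
            paste(missing, collapse = ", "))
  }
  set.seed(seed)
  m <- metric_values[pats]
  noise <- if (model$noise_sd > 0) rnorm(length(m), 0, model$noise_sd) else 0
  meta[[score]][match(pats, meta$subject_id)] <-
    intercept + model$slope * m + noise
  meta
}
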