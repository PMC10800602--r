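test_that("cohort generation is deterministic for a fixed config", {
  cfg <- cohort_config(n_per_group = 5, n_regions = 8, n_timepoints = 30,
                       effect_edges = data.frame(i = 1, j = 2, delta = 0.3),
                       seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$meta, b$meta)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$truth$effect_edges, b$truth$effect_edges)
})

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(n_per_group = 5, n_regions = 2),
               "n_regions")
  expect_error(cohort_config(n_per_group = 5, n_regions = 8,
                             n_timepoints = 5), "n_timepoints")
  expect_error(cohort_config(n_per_group = 5, n_regions = 8,
                             effect_edges = data.frame(i = 3, j = 3,
                                                       delta = 0.2)),
               "distinct")
  expect_error(cohort_config(n_per_group = 5, n_regions = 8,
                             effect_edges = data.frame(i = 1, j = 9,
                                                       delta = 0.2)),
               "outside")
})

test_that("deltas breaking correlation bounds or positive definiteness fail loudly", {
  cfg <- cohort_config(n_per_group = 3, n_regions = 4, n_timepoints = 20,
                       base_matrix = diag(4),
                       effect_edges = data.frame(i = 1, j = 2, delta = 1.2),
                       seed = 1)
  expect_error(generate_cohort(cfg), "outside \\(-1, 1\\)")
  # each delta is fine alone but jointly the matrix loses definiteness
  cfg2 <- cohort_config(n_per_group = 3, n_regions = 3, n_timepoints = 20,
                        base_matrix = diag(3),
                        effect_edges = data.frame(i = c(1, 1, 2),
                                                  j = c(2, 3, 3),
                                                  delta = c(0.8, 0.8, -0.8)),
                        seed = 1)
  expect_error(generate_cohort(cfg2), "positive-definite")
})

test_that("metadata respects the two-group clinical structure", {
  cfg <- cohort_config(n_per_group = 30, n_regions = 5, n_timepoints = 20,
                       seed = 3)
  meta <- generate_cohort(cfg)$meta
  expect_setequal(unique(meta$group), c("patient", "control"))
  expect_true(all(meta$age > 0))
  expect_true(all(meta$fd_power >= 0))
  pat <- meta$group == "patient"
  expect_true(all(!is.na(meta$panss_total[pat])))
  expect_true(all(is.na(meta$panss_total[!pat])))
  expect_true(all(is.na(meta$cpz_equivalent[!pat])))
  expect_true(all(meta$panss_p3[pat] >= 1 & meta$panss_p3[pat] <= 7))
})

test_that("empty effect set yields empty ground truth", {
  cfg <- cohort_config(n_per_group = 4, n_regions = 6, n_timepoints = 20,
                       seed = 5)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$truth$effect_edges), 0)
  expect_equal(co$truth$sigma_control, co$truth$sigma_patient)
})

test_that("subject FC estimates are valid correlation matrices", {
  cfg <- cohort_config(n_per_group = 3, n_regions = 12, n_timepoints = 40,
                       base_connectivity = list(density = 0.3,
                                                strength = 0.4),
                       seed = 9)
  co <- generate_cohort(cfg)
  for (ts in co$timeseries) {
    fc <- compute_fc(ts)
    expect_equal(unclass(fc), t(unclass(fc)))
    expect_equal(unname(diag(fc)), rep(1, 12))
    expect_true(all(abs(fc) <= 1 + 1e-12))
  }
})

test_that("implanted deltas are recovered by the sample mean of subject FC", {
  # population shift of 0.4 on edge (77, 78); group means of subject-level
  # Pearson r must converge to it across seeds
  base <- diag(90)
  base[77, 78] <- base[78, 77] <- 0.1
  diffs <- vapply(1:20, function(s) {
    cfg <- cohort_config(n_per_group = 100, n_regions = 90,
                         n_timepoints = 195, base_matrix = base,
                         effect_edges = data.frame(i = 77, j = 78,
                                                   delta = 0.4),
                         seed = 100 + s)
    co <- generate_cohort(cfg)
    r <- vapply(co$timeseries, function(ts) cor(ts[, 77], ts[, 78]),
                numeric(1))
    pat <- co$meta$group == "patient"
    mean(r[pat]) - mean(r[!pat])
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 0.4), 0.02)
})

test_that("AR(1) temporal structure preserves the cross-correlation target", {
  base <- diag(6); base[1, 2] <- base[2, 1] <- 0.5
  cfg <- cohort_config(n_per_group = 60, n_regions = 6,
                       n_timepoints = 300, base_matrix = base, ar1 = 0.4,
                       seed = 21)
  co <- generate_cohort(cfg)
  r <- vapply(co$timeseries, function(ts) cor(ts[, 1], ts[, 2]), numeric(1))
  expect_equal(mean(r), 0.5, tolerance = 0.05)
  # and lag-1 autocorrelation is close to the knob
  ac <- vapply(co$timeseries, function(ts) {
    x <- ts[, 3]; cor(x[-1], x[-length(x)])
  }, numeric(1))
  expect_equal(mean(ac), 0.4, tolerance = 0.1)
})

test_that("clinical scores follow the configured linear model", {
  cfg <- cohort_config(n_per_group = 200, n_regions = 5, n_timepoints = 20,
                       seed = 13)
  meta <- generate_cohort(cfg)$meta
  pats <- meta$subject_id[meta$group == "patient"]
  set.seed(42)
  metric <- setNames(runif(length(pats)), pats)

  # zero noise, negative slope: exact affine relation, r = -1
  m0 <- generate_clinical_scores(meta, metric,
                                 list(score = "panss_p3", intercept = 4,
                                      slope = -3, noise_sd = 0), seed = 2)
  pp <- m0$panss_p3[m0$group == "patient"]
  expect_equal(cor(pp, metric[pats]), -1)
  expect_true(all(is.na(m0$panss_p3[m0$group == "control"])))

  # slope recovered by least squares under noise (closed-form OLS oracle)
  m1 <- generate_clinical_scores(meta, metric,
                                 list(score = "panss_p6", intercept = 10,
                                      slope = -2, noise_sd = 1), seed = 3)
  y <- m1$panss_p6[m1$group == "patient"]
  x <- metric[pats]
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(beta[2], -2, tolerance = 0.35)

  # slope 0: correlation is small at n = 200
  m2 <- generate_clinical_scores(meta, metric,
                                 list(score = "panss_p3", intercept = 4,
                                      slope = 0, noise_sd = 1), seed = 4)
  expect_lt(abs(cor(m2$panss_p3[m2$group == "patient"], x)), 0.2)

  # missing metric values are reported by subject
  expect_error(generate_clinical_scores(meta, metric[-1],
                                        list(slope = 1, noise_sd = 0)),
               pats[1])
})
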