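eight_subject_meta <- function() {
  data.frame(
    subject_id = paste0("s", 1:8),
    group = rep(c("patient", "control"), each = 4),
    age = c(30, 45, 52, 38, 29, 47, 51, 40),
    sex = c("male", "female", "male", "female",
            "male", "female", "male", "female"),
    stringsAsFactors = FALSE)
}

test_that("edge regression equals the normal-equations solution", {
  meta <- eight_subject_meta()
  y <- c(0.61, 0.55, 0.49, 0.58, 0.32, 0.28, 0.41, 0.30)
  res <- edge_regression(y, meta)

  X <- cbind(1, as.numeric(meta$group == "patient"), meta$age,
             as.numeric(meta$sex == "male"))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  e <- y - X %*% beta
  s2 <- sum(e^2) / (8 - 4)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(res$beta_group, beta[2], tolerance = 1e-10)
  expect_equal(res$t_stat, beta[2] / se, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-abs(beta[2] / se), 4), tolerance = 1e-10)
  expect_equal(res$n_used, 8)

  # independent cross-check against lm()
  fit <- summary(lm(y ~ group + age + sex,
                    data = transform(meta,
                                     group = factor(group,
                                                    c("control", "patient")))))
  expect_equal(res$t_stat, fit$coefficients["grouppatient", "t value"],
               tolerance = 1e-10)
  expect_equal(res$p_value, fit$coefficients["grouppatient", "Pr(>|t|)"],
               tolerance = 1e-10)
})

test_that("degenerate designs are handled", {
  meta <- eight_subject_meta()
  # identical FC values in both groups: no effect, p = 1
  res <- edge_regression(rep(0.4, 8), meta)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  # single-sex cohort: sex indicator collinear with intercept, dropped
  meta$sex <- "male"
  expect_warning(res2 <- edge_regression(c(1, 2, 1, 2, 3, 4, 3, 4), meta),
                 "collinear")
  expect_true(is.finite(res2$t_stat))
  # single-group cohort is an error
  meta2 <- eight_subject_meta()
  meta2$group <- "patient"
  expect_error(edge_regression(rnorm(8), meta2), "both groups")
})

test_that("sign convention: positive beta means FC increased in patients", {
  meta <- eight_subject_meta()
  y <- ifelse(meta$group == "patient", 0.8, 0.1) + seq(0, 0.007, length = 8)
  res <- edge_regression(y, meta)
  expect_gt(res$beta_group, 0)
  expect_equal(sign(res$t_stat), sign(res$beta_group))
})

test_that("test_all_edges covers exactly the masked edges", {
  set.seed(31)
  labs <- paste0("R", 1:5)
  meta <- data.frame(subject_id = paste0("s", 1:20),
                     group = rep(c("patient", "control"), 10),
                     age = runif(20, 20, 60),
                     sex = sample(c("male", "female"), 20, TRUE),
                     stringsAsFactors = FALSE)
  fcs <- lapply(1:20, function(s) {
    compute_fc(roi_timeseries(matrix(rnorm(150), 30, 5,
                                     dimnames = list(NULL, labs)),
                              paste0("s", s)))
  })
  empty <- consensus_screen(fcs, 0.999)
  expect_equal(nrow(test_all_edges(fcs, meta, empty)), 0)
  full <- consensus_screen(fcs, 0)
  res <- test_all_edges(fcs, meta, full)
  expect_equal(nrow(res), choose(5, 2))
  # vectorized fit agrees with the single-edge path
  one <- edge_regression(vapply(fcs, function(fc) fc["R1", "R3"],
                                numeric(1)), meta)
  row <- res[res$label_i == "R1" & res$label_j == "R3", ]
  expect_equal(row$t_stat, one$t_stat, tolerance = 1e-12)
})

test_that("an implanted group effect yields the smallest p-value", {
  hits <- vapply(1:10, function(s) {
    cfg <- cohort_config(n_per_group = 50, n_regions = 8, n_timepoints = 100,
                         base_matrix = diag(8),
                         effect_edges = data.frame(i = 1, j = 2,
                                                   delta = 0.5),
                         seed = 300 + s)
    co <- generate_cohort(cfg)
    fcs <- lapply(co$timeseries, compute_fc)
    mask <- consensus_screen(fcs, 0)  # test every edge
    res <- test_all_edges(fcs, co$meta, mask)
    top <- res[which.min(res$p_value), ]
    top$label_i == "R001" && top$label_j == "R002"
  }, logical(1))
  expect_true(all(hits))
})

test_that("Bonferroni binarization uses strict inequality and default m", {
  nodes <- paste0("R", 1:90)
  res <- data.frame(label_i = c("R1", "R2", "R3"),
                    label_j = c("R2", "R3", "R4"),
                    beta_group = c(0.5, -0.2, 0.1),
                    t_stat = c(9, -3.5, 1.2),
                    p_value = c(1e-9, 1e-3, 0.2),
                    n_used = 400)
  g <- bonferroni_binarize(res, nodes)
  expect_equal(g$m, 4005)           # 90 * 89 / 2
  expect_equal(nrow(g$edges), 1)    # only 1e-9 < 0.05/4005
  expect_equal(g$edges$sign, "increased")

  # boundary: p exactly alpha/m is excluded
  res$p_value[1] <- 0.05 / 4005
  g2 <- bonferroni_binarize(res, nodes)
  expect_equal(nrow(g2$edges), 0)
})

test_that("lowering alpha never adds edges", {
  set.seed(77)
  res <- data.frame(label_i = paste0("R", 1:30), label_j = paste0("R", 31:60),
                    beta_group = rnorm(30), t_stat = rnorm(30),
                    p_value = 10^runif(30, -8, 0), n_used = 100)
  nodes <- paste0("R", 1:60)
  alphas <- c(0.2, 0.05, 0.01, 0.001)
  sizes <- vapply(alphas, function(a)
    nrow(bonferroni_binarize(res, nodes, alpha = a)$edges), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("degree profile matches a brute-force incidence tally", {
  g_empty <- toy_graph(90, list(), labels = paste0("R", 1:90))
  expect_equal(unname(degree_profile(g_empty)$breakdown), c(90, 0, 0))

  g1 <- toy_graph(5, list(c(1, 2)))
  expect_equal(unname(degree_profile(g1)$breakdown), c(3, 2, 0))

  set.seed(19)
  g <- toy_graph(12, random_edges(12, 0.3))
  deg <- degree_profile(g)$degree
  for (v in g$nodes) {
    expect_equal(unname(deg[v]),
                 sum(g$edges$label_i == v) + sum(g$edges$label_j == v))
  }
})

test_that("leave-one-subject-out errors equal the fold-by-fold oracle", {
  set.seed(23)
  labs <- c("A", "B", "C")
  n <- 6
  meta <- data.frame(subject_id = paste0("s", 1:n),
                     group = rep(c("patient", "control"), 3),
                     age = c(25, 33, 41, 52, 38, 46),
                     sex = c("male", "male", "female", "female",
                             "male", "female"),
                     stringsAsFactors = FALSE)
  fcs <- lapply(1:n, function(s) {
    compute_fc(roi_timeseries(matrix(rnorm(30), 10, 3,
                                     dimnames = list(NULL, labs)),
                              paste0("s", s)))
  })
  mask <- consensus_screen(fcs, 0)
  out <- loso_sensitivity(fcs, meta, mask)

  X <- cbind(1, as.numeric(meta$group == "patient"), meta$age,
             as.numeric(meta$sex == "male"))
  for (r in seq_len(nrow(out$per_edge))) {
    y <- vapply(fcs, function(fc) fc[out$per_edge$label_i[r],
                                     out$per_edge$label_j[r]], numeric(1))
    errs <- vapply(seq_len(n), function(i) {
      b <- solve(t(X[-i, ]) %*% X[-i, ], t(X[-i, ]) %*% y[-i])
      (y[i] - X[i, ] %*% b)^2
    }, numeric(1))
    expect_equal(out$per_edge$mean_sq_error[r], mean(errs),
                 tolerance = 1e-10)
  }
  expect_equal(unname(out$range["min"]), min(out$per_edge$mean_sq_error))
  expect_equal(unname(out$range["max"]), max(out$per_edge$mean_sq_error))
})

test_that("motion QC reproduces the Welch test", {
  # identical groups: no difference, symmetric CI
  meta <- data.frame(subject_id = paste0("s", 1:10),
                     group = rep(c("patient", "control"), each = 5),
                     fd_power = rep(c(0.1, 0.2, 0.15, 0.12, 0.18), 2))
  qc <- compare_motion(meta)
  expect_equal(qc$t, 0)
  expect_equal(qc$ci[1], -qc$ci[2])

  # unequal-variance fixture against stats::t.test
  meta2 <- data.frame(subject_id = paste0("s", 1:12),
                      group = rep(c("patient", "control"), each = 6),
                      fd_power = c(0.31, 0.12, 0.45, 0.22, 0.38, 0.29,
                                   0.10, 0.12, 0.11, 0.13, 0.09, 0.14))
  qc2 <- compare_motion(meta2)
  ref <- t.test(meta2$fd_power[1:6], meta2$fd_power[7:12])
  expect_equal(qc2$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(qc2$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(qc2$p, ref$p.value, tolerance = 1e-10)
  expect_equal(qc2$ci, as.numeric(ref$conf.int), tolerance = 1e-10)

  meta2$fd_power[3] <- NA
  expect_error(compare_motion(meta2), "s3")
})
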