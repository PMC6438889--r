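synthetic_metric_table <- function(values, groups_per_subject) {
  # values: subjects x clusters matrix of degree_avg
  n <- nrow(values); k <- ncol(values)
  tibble::tibble(
    subject_id = rep(sprintf("s%03d", seq_len(n)), each = k),
    group = rep(groups_per_subject, each = k),
    cluster = rep(seq_len(k), times = n),
    degree_avg = as.vector(t(values)),
    betweenness_avg = 0
  )
}

test_that("hub rule: pooled mean + 1 SD threshold and a-priori union semantics", {
  set.seed(1)
  vals <- matrix(rnorm(10 * 8, mean = 10), 10, 8)
  vals[, 2] <- vals[, 2] + 6   # an unambiguous hub for every group
  tab <- synthetic_metric_table(vals, rep(c("A", "B"), each = 5))
  rep_ <- select_hubs(tab, a_priori = c(5L))
  expect_equal(rep_$rule_mean, mean(vals))
  expect_equal(rep_$rule_sd, sd(tab$degree_avg))
  expect_true(2L %in% rep_$hub_clusters)
  expect_false(5L %in% rep_$hub_clusters)
  expect_true(all(c(2L, 5L) %in% rep_$analysis_set))
  expect_equal(rep_$analysis_set, sort(union(rep_$hub_clusters, 5L)))
})

test_that("planted hub clusters are recovered from simulated cohorts", {
  hits <- vapply(1:10, function(s) {
    cfg <- tiny_config(group_sizes = c(A = 8, B = 8), n_regions = 40,
                       n_true_clusters = 10, timepoints_per_run = 100,
                       rho_between = 0.1,
                       hub_nodes = list(A = 3L, B = integer(0)),
                       hub_boost = 0.2, hub_strength_sd = 0.03,
                       seed = 500 + s)
    co <- simulate_cohort(cfg)
    met <- cohort_node_metrics(co, true_partition(cfg))
    3L %in% select_hubs(met)$hub_clusters
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("under exchangeable clusters the hub count matches the Gaussian tail expectation", {
  set.seed(2)
  k <- 30; n_per_group <- 4; groups <- rep(c("A", "B"), each = n_per_group)
  counts <- vapply(1:300, function(i) {
    vals <- matrix(rnorm(8 * k), 8, k)
    length(select_hubs(synthetic_metric_table(vals, groups))$hub_clusters)
  }, numeric(1))
  # group mean of n iid N(0,1) exceeds mu + sigma with prob 1 - Phi(sqrt(n))
  p1 <- 1 - pnorm(sqrt(n_per_group))
  expected <- k * (1 - (1 - p1)^2)
  expect_lt(abs(mean(counts) - expected), 0.3)
})

test_that("group comparison: identical groups, t/GLM equivalence, planted power", {
  set.seed(3)
  vals <- matrix(rnorm(12 * 6, 8), 12, 6)
  tab <- synthetic_metric_table(rbind(vals[1:6, ], vals[1:6, ]),
                                rep(c("A", "B"), each = 6))
  cov <- tibble::tibble(subject_id = sprintf("s%03d", 1:12),
                        age = rnorm(12, 60))
  res <- compare_groups(tab, cov, c("A", "B"), analysis_set = 1:6)
  expect_true(all(res$effect == 0))
  expect_false(any(res$discovered))

  # equal-variance t equals the dummy-regression t on random tables
  tab2 <- synthetic_metric_table(matrix(rnorm(12 * 4, 8), 12, 4),
                                 rep(c("A", "B"), each = 6))
  res2 <- compare_groups(tab2, cov, c("A", "B"), analysis_set = 1:4)
  for (cl in 1:4) {
    d <- tab2[tab2$cluster == cl, ]
    fit <- summary(lm(degree_avg ~ I(group == "B"), data = d))$coefficients
    expect_equal(res2$t[res2$cluster == cl & res2$metric == "degree_avg"],
                 fit[2, 3], tolerance = 1e-10)
  }
})

test_that("a planted group difference in hub coupling is detected at FDR 0.05", {
  hits <- vapply(1:10, function(s) {
    cfg <- tiny_config(group_sizes = c(A = 15, B = 15), n_regions = 40,
                       n_true_clusters = 10, timepoints_per_run = 100,
                       rho_between = 0.1,
                       hub_nodes = list(A = 3L, B = integer(0)),
                       hub_boost = 0.2, hub_strength_sd = 0.03,
                       seed = 600 + s)
    co <- simulate_cohort(cfg)
    met <- cohort_node_metrics(co, true_partition(cfg))
    res <- compare_groups(met, co$covariates, c("B", "A"),
                          analysis_set = 1:10, fdr_q = 0.05)
    any(res$discovered[res$cluster == 3 & res$metric == "degree_avg"])
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("two-way ANOVA: balanced-design sums of squares match the arithmetic oracle", {
  # balanced 2x2 with 3 observations per cell
  d <- tibble::tibble(
    group = factor(rep(c("G1", "G2"), each = 6)),
    age = rep(c(60, 60, 60, 75, 75, 75), 2),
    y = c(10, 11, 12, 14, 15, 16, 20, 21, 22, 30, 31, 32)
  )
  res <- subgroup_anova(d, "y", "age", threshold = 67.6)
  # oracle: balanced two-way sums of squares from cell means
  cell <- with(d, tapply(y, list(group, age < 67.6), mean))
  grand <- mean(d$y)
  row_m <- rowMeans(cell); col_m <- colMeans(cell)
  ss_group <- 6 * sum((row_m - grand)^2)
  ss_sub <- 6 * sum((col_m - grand)^2)
  ss_int <- 3 * sum((sweep(sweep(cell, 1, row_m), 2, col_m) + grand)^2)
  ss_res <- sum((d$y - ave(d$y, d$group, d$age))^2)
  an <- res$anova
  expect_equal(an$sumsq[an$term == "group"], ss_group, tolerance = 1e-10)
  expect_equal(an$sumsq[an$term == "subgroup"], ss_sub, tolerance = 1e-10)
  expect_equal(an$sumsq[an$term == "group:subgroup"], ss_int,
               tolerance = 1e-10)
  expect_equal(an$sumsq[an$term == "residuals"], ss_res, tolerance = 1e-10)
  df_res <- an$df[an$term == "residuals"]
  expect_equal(an$statistic[an$term == "group"],
               (ss_group / 1) / (ss_res / df_res), tolerance = 1e-10)
  expect_equal(nrow(res$t_tests), 2)  # one t-test per subgroup
})

test_that("ANOVA p-values are calibrated under the null and detect a pure group effect", {
  set.seed(4)
  n_sim <- 400
  ps <- t(vapply(seq_len(n_sim), function(i) {
    d <- tibble::tibble(group = factor(rep(c("a", "b"), each = 10)),
                        bdi = rnorm(20, 7, 3), y = rnorm(20))
    res <- suppressWarnings(subgroup_anova(d, "y", "bdi", threshold = 6.9))
    if (res$degenerate) return(rep(NA_real_, 3))  # flagged empty-cell draws
    unlist(glance(res)[1:3])
  }, numeric(3)))
  ps <- ps[stats::complete.cases(ps), , drop = FALSE]
  se <- sqrt(0.05 * 0.95 / nrow(ps))
  for (j in 1:3) expect_lt(mean(ps[, j] <= 0.05), 0.05 + 3 * se)

  set.seed(5)
  ps2 <- t(vapply(1:100, function(i) {
    d <- tibble::tibble(group = factor(rep(c("a", "b"), each = 10)),
                        bdi = rnorm(20, 7, 3),
                        y = rnorm(20) + 2 * rep(c(0, 1), each = 10))
    unlist(glance(subgroup_anova(d, "y", "bdi", threshold = 6.9))[1:3])
  }, numeric(3)))
  expect_gt(mean(ps2[, 1] <= 0.05), 0.8)          # group effect found
  expect_lt(abs(mean(ps2[, 3] <= 0.05) - 0.05), 0.08)  # interaction null
})

test_that("empty subgroup cells flag the ANOVA as degenerate", {
  d <- tibble::tibble(group = factor(rep(c("a", "b"), each = 6)),
                      age = c(rep(50, 6), rep(80, 6)),
                      y = rnorm(12))
  expect_warning(res <- subgroup_anova(d, "y", "age", threshold = 65),
                 "degenerate")
  expect_true(res$degenerate)
})

test_that("degree-cognition correlation: exact linearity, nulls, and recovery near r = 0.4", {
  set.seed(6)
  vals <- matrix(rnorm(20 * 3, 10), 20, 3)
  tab <- synthetic_metric_table(vals, rep("PD", 20))
  cov <- tibble::tibble(subject_id = sprintf("s%03d", 1:20),
                        mean_z = vals[, 2], age = rnorm(20, 65))
  res <- correlate_cognition(tab, cov, clusters = 2L)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-6)

  # no coupling in the generator: rejection rate at alpha = 0.05 stays nominal
  set.seed(7)
  rej <- vapply(1:400, function(i) {
    x <- rnorm(35); z <- rnorm(35)
    cor.test(x, z)$p.value <= 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 400))

  # planted coupling at population r ~ 0.4, n = 35: the mean recovered r
  # across seeds is an accurate estimate (single-seed estimates carry the
  # irreducible Pearson sampling SE of ~0.15 at this n)
  rs <- vapply(1:10, function(s) {
    cfg <- sim_config(group_sizes = c(PD = 35), n_regions = 40,
                      n_true_clusters = 10, timepoints_per_run = 100,
                      runs_per_subject = 1, hub_nodes = list(PD = 3L),
                      covariate_spec = default_covariate_spec("PD"),
                      seed = 700 + s)
    co <- simulate_cohort(cfg)
    met <- cohort_node_metrics(co, true_partition(cfg))
    correlate_cognition(met, co$covariates, clusters = 3L)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.4), 0.15)
  expect_true(all(rs > 0))
})

test_that("zero-variance inputs are flagged undefined rather than failing", {
  tab <- synthetic_metric_table(matrix(5, 6, 2), rep("PD", 6))
  cov <- tibble::tibble(subject_id = sprintf("s%03d", 1:6),
                        mean_z = rnorm(6), age = rnorm(6, 65))
  res <- correlate_cognition(tab, cov, clusters = 1L)
  expect_true(res$undefined)
  expect_true(is.na(res$r))
})
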