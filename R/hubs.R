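# Hub selection and the statistics run on cost-averaged node metrics:
# group contrasts, two-way subgroup ANOVA, and degree-cognition correlation.

#' Cost-averaged node metrics for a whole cohort
#'
#' Builds each subject's cluster-level correlation matrix (Pearson
#' correlation of cluster mean series at the chosen partition) from the
#' requested runs and returns the degree/betweenness table averaged over the
#' cost range.
#'
#' @param cohort A `basc_cohort`.
#' @param partition Partition at the graph resolution.
#' @param costs Cost range (default 18-24% in 0.5% steps).
#' @param runs Run subset (default first run only, the usual choice when
#'   groups differ in number of runs).
#' @inheritParams preprocess_subject
#' @return Tibble with columns `subject_id`, `group`, `cluster`,
#'   `degree_avg`, `betweenness_avg`.
#' @export
cohort_node_metrics <- function(cohort, partition,
                                costs = seq(0.18, 0.24, by = 0.005),
                                runs = 1L, fd_threshold = 0.5,
                                min_volumes = 40, highpass_hz = 0.01,
                                tr_s = 2.6) {
  rows <- lapply(cohort$subjects, function(sub) {
    pre <- preprocess_subject(sub, fd_threshold, min_volumes, highpass_hz,
                              tr_s, runs = runs)
    if (pre$rejected) return(NULL)
    M <- cluster_mean_series(scale(pre$ts), partition)
    W <- cor(M)
    nm <- node_metrics_over_range(W, costs)
    mutate(nm, subject_id = sub$subject_id, group = sub$group,
           .before = 1)
  })
  bind_rows(rows)
}

#' Select hub clusters by the mean-plus-one-SD rule
#'
#' The rule mean and SD are computed over the pooled subject-by-cluster
#' `degree_avg` values of all groups; a cluster is a hub when at least one
#' group's mean `degree_avg` exceeds `rule_mean + rule_sd`. The analysis set
#' is the union of the hubs with any a-priori clusters.
#'
#' @param metrics Tibble from [cohort_node_metrics()].
#' @param a_priori Integer cluster ids always included in the analysis set
#'   (e.g. basal ganglia and hippocampal clusters).
#' @return An object of class `basc_hub_report`: list with `hub_clusters`,
#'   `a_priori`, `analysis_set`, `rule_mean`, `rule_sd`, and `group_means`
#'   (tibble cluster x group mean/SD of degree).
#' @export
select_hubs <- function(metrics, a_priori = integer(0)) {
  if (!nrow(metrics)) abort("Empty metrics table.")
  if (!all(c("group", "cluster", "degree_avg") %in% names(metrics))) {
    abort("`metrics` needs columns group, cluster, degree_avg.")
  }
  rule_mean <- mean(metrics$degree_avg)
  rule_sd <- sd(metrics$degree_avg)
  gm <- metrics |>
    group_by(.data$cluster, .data$group) |>
    summarise(mean_degree = mean(.data$degree_avg),
              sd_degree = sd(.data$degree_avg),
              mean_betweenness = mean(.data$betweenness_avg),
              .groups = "drop")
  hubs <- sort(unique(gm$cluster[gm$mean_degree > rule_mean + rule_sd]))
  structure(list(
    hub_clusters = hubs,
    a_priori = sort(unique(as.integer(a_priori))),
    analysis_set = sort(union(hubs, as.integer(a_priori))),
    rule_mean = rule_mean, rule_sd = rule_sd,
    group_means = gm
  ), class = "basc_hub_report")
}

#' @export
print.basc_hub_report <- function(x, ...) {
  cat(sprintf("<basc_hub_report> rule mean + SD = %.2f + %.2f; hubs: %s; analysis set n = %d\n",
              x$rule_mean, x$rule_sd,
              paste(x$hub_clusters, collapse = ", "),
              length(x$analysis_set)))
  invisible(x)
}

#' Group contrasts of node metrics in the analysis set
#'
#' For each cluster of the analysis set and each metric, a two-sample
#' Student t-test (equal variances) between the two groups, or an OLS model
#' with mean-centred age as covariate when `with_age = TRUE`.
#' Benjamini-Hochberg correction is applied across the analysis-set clusters
#' within each metric.
#'
#' @param metrics Tibble from [cohort_node_metrics()].
#' @param covariates Cohort covariate tibble (needs `subject_id` and `age`
#'   when `with_age = TRUE`).
#' @param contrast Two group labels `(A, B)`; effect is B minus A.
#' @param analysis_set Clusters to test (e.g. from [select_hubs()]).
#' @param with_age Covary age via a linear model.
#' @param metric_cols Metric columns to test.
#' @param fdr_q FDR level across the analysis set.
#' @return Tibble with cluster, metric, effect, t, p, q, discovered.
#' @export
compare_groups <- function(metrics, covariates, contrast, analysis_set,
                           with_age = FALSE,
                           metric_cols = c("degree_avg", "betweenness_avg"),
                           fdr_q = 0.05) {
  if (length(contrast) != 2) abort("`contrast` must name two groups.")
  d <- metrics |>
    filter(.data$group %in% contrast, .data$cluster %in% analysis_set) |>
    left_join(select(covariates, "subject_id", "age"), by = "subject_id")
  if (!nrow(d)) abort("No data for the requested contrast / analysis set.")
  for (g in contrast) {
    if (length(unique(d$subject_id[d$group == g])) < 2) {
      abort(sprintf("Group '%s' has fewer than 2 subjects.", g))
    }
  }
  rows <- list()
  for (m in metric_cols) {
    for (cl in analysis_set) {
      dc <- d[d$cluster == cl, ]
      y <- dc[[m]]
      dummy <- as.numeric(dc$group == contrast[2])
      if (with_age) {
        fit <- summary(lm(y ~ dummy + I(dc$age - mean(dc$age))))$coefficients
        rows[[length(rows) + 1L]] <- tibble(
          cluster = cl, metric = m, effect = fit["dummy", 1],
          t = fit["dummy", 3], p = fit["dummy", 4])
      } else {
        # pooled two-sample Student t, with an explicit degenerate branch so
        # constant metrics (e.g. betweenness at very small k) cannot crash
        y1 <- y[dummy == 1]; y0 <- y[dummy == 0]
        n1 <- length(y1); n0 <- length(y0)
        eff <- mean(y1) - mean(y0)
        sp2 <- ((n1 - 1) * var(y1) + (n0 - 1) * var(y0)) / (n1 + n0 - 2)
        if (sp2 < 1e-24) {
          degen <- abs(eff) < 1e-12
          rows[[length(rows) + 1L]] <- tibble(
            cluster = cl, metric = m, effect = eff,
            t = if (degen) 0 else NA_real_,
            p = if (degen) 1 else NA_real_)
        } else {
          tval <- eff / sqrt(sp2 * (1 / n1 + 1 / n0))
          rows[[length(rows) + 1L]] <- tibble(
            cluster = cl, metric = m, effect = eff, t = tval,
            p = 2 * pt(-abs(tval), n1 + n0 - 2))
        }
      }
    }
  }
  out <- bind_rows(rows) |>
    group_by(.data$metric) |>
    mutate(q = p.adjust(.data$p, method = "BH"),
           discovered = .data$q <= fdr_q) |>
    ungroup()
  out
}

#' Two-way subgroup ANOVA of an averaged degree
#'
#' Splits each group into two subgroups at `threshold` (for a numeric
#' `split_col` such as age or depression score) or by the levels of a
#' two-level factor (such as sex), fits a two-way fixed-effects model
#' `response ~ group * subgroup` with Type II sums of squares, and runs
#' per-subgroup two-sample t-tests between consecutive group pairs.
#'
#' @param data Tibble with one row per subject: the response column, `group`,
#'   and the splitting column.
#' @param response Name of the response column (e.g. the mean degree over a
#'   set of clusters).
#' @param split_col Name of the splitting column.
#' @param threshold Numeric split point (required for numeric `split_col`;
#'   values strictly below go to the low subgroup).
#' @param group_col Name of the group column.
#' @return List of class `basc_subgroup_anova` with `anova` (tibble term,
#'   df, sumsq, statistic, p.value), `t_tests` (per subgroup and group
#'   pair), `cell_counts`, `degenerate` (TRUE when a group-by-subgroup cell
#'   is empty).
#' @export
subgroup_anova <- function(data, response, split_col, threshold = NULL,
                           group_col = "group") {
  y <- data[[response]]
  grp <- factor(data[[group_col]])
  sv <- data[[split_col]]
  if (is.numeric(sv)) {
    if (is.null(threshold)) abort("Numeric `split_col` needs a `threshold`.")
    sub <- factor(ifelse(sv < threshold, "low", "high"), c("low", "high"))
  } else {
    sub <- factor(sv)
    if (nlevels(sub) != 2) abort("`split_col` must have exactly two levels.")
  }
  cells <- table(grp, sub)
  degenerate <- any(cells == 0)
  if (degenerate) {
    warn("Empty group-by-subgroup cell; ANOVA flagged unbalanced-degenerate.")
  }
  fit <- lm(y ~ grp * sub)
  an <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  if (is.null(an)) {
    # saturated / zero-residual fits (tiny cells) cannot support the F test
    warn("Two-way ANOVA inestimable (zero residual variance); flagged degenerate.")
    degenerate <- TRUE
    an <- data.frame("Sum Sq" = rep(NA_real_, 4), Df = rep(NA_real_, 4),
                     "F value" = NA_real_, "Pr(>F)" = NA_real_,
                     row.names = c("grp", "sub", "grp:sub", "Residuals"),
                     check.names = FALSE)
  }
  an_tb <- tibble(
    term = rownames(an),
    sumsq = an[["Sum Sq"]],
    df = an[["Df"]],
    statistic = an[["F value"]],
    p.value = an[["Pr(>F)"]]
  ) |>
    mutate(term = dplyr::recode(.data$term, "grp" = "group",
                                "sub" = "subgroup",
                                "grp:sub" = "group:subgroup",
                                "Residuals" = "residuals"))
  glevels <- levels(grp)
  tt_rows <- list()
  for (s in levels(sub)) {
    for (i in seq_len(length(glevels) - 1)) {
      a <- glevels[i]; b <- glevels[i + 1]
      ya <- y[grp == a & sub == s]; yb <- y[grp == b & sub == s]
      if (length(ya) < 2 || length(yb) < 2) next
      tt <- t.test(yb, ya, var.equal = TRUE)
      tt_rows[[length(tt_rows) + 1L]] <- tibble(
        subgroup = s, group_a = a, group_b = b,
        effect = unname(diff(rev(tt$estimate))),
        t = unname(tt$statistic), p = tt$p.value)
    }
  }
  structure(list(anova = an_tb, t_tests = bind_rows(tt_rows),
                 cell_counts = cells, degenerate = degenerate,
                 split_col = split_col, threshold = threshold),
            class = "basc_subgroup_anova")
}

#' @export
print.basc_subgroup_anova <- function(x, ...) {
  cat(sprintf("<basc_subgroup_anova> split on %s%s%s\n", x$split_col,
              if (!is.null(x$threshold)) sprintf(" at %.3g", x$threshold) else "",
              if (x$degenerate) " [degenerate cells]" else ""))
  print(x$anova)
  invisible(x)
}

#' Degree-cognition correlations over selected clusters
#'
#' Pearson correlation (or age-partialled correlation via residuals of both
#' variables on age) between each cluster's cost-averaged degree and the
#' subject mean cognitive z-score, with Benjamini-Hochberg correction across
#' the tested clusters.
#'
#' @param metrics Tibble from [cohort_node_metrics()].
#' @param covariates Covariate tibble with `subject_id`, `mean_z`, and `age`.
#' @param clusters Clusters to test (default: all present).
#' @param groups Optional group subset over which to correlate.
#' @param with_age Partial out age from both variables.
#' @param metric_col Metric column (default `degree_avg`).
#' @param fdr_q FDR level across the tested clusters.
#' @return Tibble with cluster, n, r, p, q, discovered, undefined (TRUE when
#'   either variable has zero variance).
#' @export
correlate_cognition <- function(metrics, covariates, clusters = NULL,
                                groups = NULL, with_age = FALSE,
                                metric_col = "degree_avg", fdr_q = 0.05) {
  d <- left_join(metrics,
                 select(covariates, "subject_id", "mean_z", dplyr::any_of("age")),
                 by = "subject_id")
  if (!is.null(groups)) d <- filter(d, .data$group %in% groups)
  clusters <- clusters %||% sort(unique(d$cluster))
  rows <- lapply(clusters, function(cl) {
    dc <- d[d$cluster == cl, ]
    if (nrow(dc) < 4) abort("Need at least 4 subjects per correlation.")
    x <- dc[[metric_col]]; z <- dc$mean_z
    if (with_age) {
      x <- stats::resid(lm(x ~ dc$age))
      z <- stats::resid(lm(z ~ dc$age))
    }
    if (var(x) < 1e-24 || var(z) < 1e-24) {
      return(tibble(cluster = cl, n = nrow(dc), r = NA_real_, p = NA_real_,
                    undefined = TRUE))
    }
    ct <- cor.test(x, z)
    tibble(cluster = cl, n = nrow(dc), r = unname(ct$estimate),
           p = ct$p.value, undefined = FALSE)
  })
  out <- bind_rows(rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$discovered <- !is.na(out$q) & out$q <= fdr_q
  out
}
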