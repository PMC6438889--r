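# End-to-end orchestration: scrub -> confound regression -> BASC ->
# connectomes -> connection-wise statistics with omnibus gate -> graph
# metrics, hubs, subgroup ANOVA, and cognition correlations.

#' Pipeline configuration
#'
#' Collects every tunable of the two-step analysis. Exactly one of `cohort`
#' (an in-memory `basc_cohort`), `cohort_dir` (a directory for
#' [load_cohort()]), or `sim` (a [sim_config()] to simulate from) must be
#' supplied.
#'
#' @param cohort,cohort_dir,sim Cohort source (see above).
#' @param grid Resolution grid for BASC (default desk-scale `c(4, 10)`; the
#'   study-scale grid is `c(4, 10, 19, 35, 63, 118, 221, 393)`).
#' @param n_boot,n_boot_group BASC replication counts.
#' @param fdr_q Connection-wise FDR level.
#' @param alpha,n_perm Omnibus family-wise level and permutation count.
#' @param contrasts List of contrasts, each a list with `groups` (two
#'   labels) and `with_age` (logical).
#' @param graph_resolution Resolution (must be in `grid`) whose consensus
#'   partition defines the Step-2 graph nodes.
#' @param cost_grid Cost grid for the efficiency scan.
#' @param cost_range Cost range over which node metrics are averaged.
#' @param omega_costs Costs at which omega is evaluated during the scan.
#' @param a_priori A-priori cluster ids always kept in the hub analysis set.
#' @param anova_clusters Clusters whose mean degree feeds the subgroup
#'   ANOVA (default: the correlation clusters).
#' @param anova_groups Groups entering the subgroup ANOVA.
#' @param correlation_clusters Clusters tested for degree-cognition
#'   correlation (default: the analysis set determined at run time).
#' @param correlation_groups Groups pooled for the correlation.
#' @param graph_runs Runs used for Step 2 (default first run only).
#' @param fd_threshold,min_volumes,highpass_hz,tr_s Preprocessing settings.
#' @param seed Master seed; per-stage seeds are fanned out deterministically.
#' @param cache_dir Optional BASC cache directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, cohort_dir = NULL, sim = NULL,
                            grid = c(4, 10),
                            n_boot = 100, n_boot_group = 100,
                            fdr_q = 0.05, alpha = 0.05, n_perm = 199,
                            contrasts = list(),
                            graph_resolution = max(grid),
                            cost_grid = seq(0.005, 0.5, by = 0.005),
                            cost_range = seq(0.18, 0.24, by = 0.005),
                            omega_costs = NULL,
                            a_priori = integer(0),
                            anova_clusters = NULL,
                            anova_groups = NULL,
                            correlation_clusters = NULL,
                            correlation_groups = NULL,
                            graph_runs = 1L,
                            fd_threshold = 0.5, min_volumes = 40,
                            highpass_hz = 0.01, tr_s = 2.6,
                            seed = 1L, cache_dir = NULL) {
  if (sum(!vapply(list(cohort, cohort_dir, sim), is.null, TRUE)) != 1) {
    abort("Supply exactly one of `cohort`, `cohort_dir`, `sim`.")
  }
  if (fdr_q <= 0 || fdr_q >= 1) abort("`fdr_q` must lie in (0, 1).")
  if (!graph_resolution %in% grid) {
    abort("`graph_resolution` must be one of `grid`.")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full two-step pipeline
#'
#' @param config A [pipeline_config()].
#' @return A `basc_report` bundle: list with `basc` (per-resolution
#'   partitions and stability), `connectomes` (per resolution), `design_data`
#'   (per-subject covariates + mean frame displacement), `step1` (per
#'   contrast: `basc_omnibus`), `metrics`, `hubs`, `group_stats`, `anova`,
#'   `correlations`, `cost_curves`, and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- config$cohort %||%
    (if (!is.null(config$cohort_dir)) load_cohort(config$cohort_dir)
     else simulate_cohort(config$sim))

  basc <- run_multiresolution(
    cohort, grid = config$grid, n_boot = config$n_boot,
    n_boot_group = config$n_boot_group,
    seed = stage_seed(config$seed, "basc"), cache_dir = config$cache_dir,
    fd_threshold = config$fd_threshold, min_volumes = config$min_volumes,
    highpass_hz = config$highpass_hz, tr_s = config$tr_s)

  # per-subject mean frame displacement over all usable runs -> GLM covariate
  pre_info <- lapply(cohort$subjects, preprocess_subject,
                     fd_threshold = config$fd_threshold,
                     min_volumes = config$min_volumes,
                     highpass_hz = config$highpass_hz, tr_s = config$tr_s)
  usable <- !vapply(pre_info, `[[`, TRUE, "rejected")
  design_data <- cohort$covariates |>
    mutate(mean_fd = vapply(pre_info, `[[`, 0, "mean_fd")) |>
    filter(usable)

  keep_subjects <- cohort$subjects[usable]
  connectomes <- lapply(basc, function(res) {
    conns <- lapply(keep_subjects, subject_connectome,
                    partition = res$partition,
                    fd_threshold = config$fd_threshold,
                    min_volumes = config$min_volumes,
                    highpass_hz = config$highpass_hz, tr_s = config$tr_s)
    conns[!vapply(conns, is.null, TRUE)]
  })

  step1 <- list()
  for (ct in config$contrasts) {
    design <- build_design(design_data, ct$groups,
                           with_age = isTRUE(ct$with_age))
    in_ct <- design_data$group %in% ct$groups
    conns_ct <- lapply(connectomes, function(cl) cl[in_ct])
    label <- sprintf("%s_vs_%s%s", ct$groups[1], ct$groups[2],
                     if (isTRUE(ct$with_age)) "_age" else "")
    step1[[label]] <- omnibus_test(
      conns_ct, design, q = config$fdr_q, n_perm = config$n_perm,
      alpha = config$alpha,
      seed = stage_seed(config$seed, paste0("omnibus_", label)))
  }

  part2 <- basc[[as.character(config$graph_resolution)]]$partition
  metrics <- cohort_node_metrics(
    cohort, part2, costs = config$cost_range, runs = config$graph_runs,
    fd_threshold = config$fd_threshold, min_volumes = config$min_volumes,
    highpass_hz = config$highpass_hz, tr_s = config$tr_s)
  hubs <- select_hubs(metrics, a_priori = config$a_priori)

  # group-wise cost-efficiency curves on the group-mean correlation matrix
  cost_curves <- list()
  for (g in unique(metrics$group)) {
    subs <- Filter(function(s) s$group == g, keep_subjects)
    Ws <- lapply(subs, function(s) {
      pre <- preprocess_subject(s, config$fd_threshold, config$min_volumes,
                                config$highpass_hz, config$tr_s,
                                runs = config$graph_runs)
      cor(cluster_mean_series(scale(pre$ts), part2))
    })
    Wbar <- Reduce(`+`, Ws) / length(Ws)
    cost_curves[[g]] <- cost_scan(Wbar, costs = config$cost_grid,
                                  omega_costs = config$omega_costs,
                                  seed = stage_seed(config$seed,
                                                    paste0("omega_", g)))
  }
  check_cost_range(cost_curves, config$cost_range)

  group_stats <- list()
  for (ct in config$contrasts) {
    label <- sprintf("%s_vs_%s%s", ct$groups[1], ct$groups[2],
                     if (isTRUE(ct$with_age)) "_age" else "")
    group_stats[[label]] <- if (length(hubs$analysis_set)) {
      compare_groups(metrics, design_data, ct$groups, hubs$analysis_set,
                     with_age = isTRUE(ct$with_age), fdr_q = config$fdr_q)
    } else {
      tibble(cluster = integer(0), metric = character(0), effect = numeric(0),
             t = numeric(0), p = numeric(0), q = numeric(0),
             discovered = logical(0))
    }
  }

  anova_clusters <- config$anova_clusters %||% config$correlation_clusters
  anova <- NULL
  if (!is.null(anova_clusters)) {
    avg <- metrics |>
      filter(.data$cluster %in% anova_clusters) |>
      group_by(.data$subject_id) |>
      summarise(avg_degree = mean(.data$degree_avg), .groups = "drop") |>
      left_join(design_data, by = "subject_id")
    if (!is.null(config$anova_groups)) {
      avg <- filter(avg, .data$group %in% config$anova_groups)
    }
    avg$group <- factor(avg$group, unique(avg$group))
    anova <- list(
      age = subgroup_anova(avg, "avg_degree", "age",
                           threshold = mean(avg$age)),
      sex = subgroup_anova(avg, "avg_degree", "sex"),
      bdi = subgroup_anova(avg, "avg_degree", "bdi",
                           threshold = mean(avg$bdi))
    )
  }

  corr_clusters <- config$correlation_clusters %||% hubs$analysis_set
  correlations <- correlate_cognition(
    metrics, design_data, clusters = corr_clusters,
    groups = config$correlation_groups, fdr_q = config$fdr_q)

  structure(list(
    basc = basc, connectomes = connectomes, design_data = design_data,
    step1 = step1, metrics = metrics, hubs = hubs,
    group_stats = group_stats, anova = anova, correlations = correlations,
    cost_curves = cost_curves, config = config,
    ground_truth = cohort$ground_truth
  ), class = "basc_report")
}

check_cost_range <- function(cost_curves, cost_range) {
  arg <- vapply(cost_curves, function(cc) attr(cc, "argmax_cost"), numeric(1))
  lo <- min(cost_range); hi <- max(cost_range)
  outside <- arg < lo | arg > hi
  if (any(outside)) {
    warn(sprintf(
      "Group cost-efficiency argmax outside the configured cost range [%.3g, %.3g]: %s",
      lo, hi,
      paste(sprintf("%s (%.3g)", names(arg)[outside], arg[outside]),
            collapse = ", ")))
  }
  invisible(arg)
}

#' Machine-readable summary of a pipeline report
#'
#' Emits the per-contrast omnibus p-values with per-resolution discovery
#' fractions, the hub table (per-cluster group means and SDs of degree), the
#' subgroup ANOVA p-values, and the degree-cognition correlation table, as a
#' plain list ready for JSON serialisation.
#'
#' @param bundle A `basc_report` from [run_pipeline()].
#' @param path Optional file; when given the summary is also written as
#'   JSON.
#' @return The summary list, invisibly when `path` is given.
#' @export
report_summary <- function(bundle, path = NULL) {
  step1 <- lapply(bundle$step1, function(om) {
    list(
      omnibus_p = om$p,
      significant = om$significant,
      percent_discovery = setNames(
        vapply(om$per_resolution, `[[`, 0, "percent_discovery"),
        names(om$per_resolution))
    )
  })
  hub_block <- bundle$hubs$group_means |>
    filter(.data$cluster %in% bundle$hubs$analysis_set)
  anova_block <- NULL
  if (!is.null(bundle$anova)) {
    anova_block <- lapply(bundle$anova, function(a) {
      stats::setNames(as.list(a$anova$p.value[a$anova$term != "residuals"]),
                      a$anova$term[a$anova$term != "residuals"])
    })
  }
  out <- list(
    step1 = step1,
    hubs = list(
      rule_mean = bundle$hubs$rule_mean,
      rule_sd = bundle$hubs$rule_sd,
      hub_clusters = bundle$hubs$hub_clusters,
      analysis_set = bundle$hubs$analysis_set,
      group_means = hub_block
    ),
    group_stats = lapply(bundle$group_stats, identity),
    anova = anova_block,
    correlations = bundle$correlations,
    argmax_cost = lapply(bundle$cost_curves,
                         function(cc) attr(cc, "argmax_cost"))
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE)
    return(invisible(out))
  }
  out
}

#' @export
print.basc_report <- function(x, ...) {
  cat(sprintf("<basc_report> %d resolutions; %d contrast(s); graph k = %d\n",
              length(x$basc), length(x$step1),
              x$config$graph_resolution))
  for (nm in names(x$step1)) {
    cat(sprintf("  %s: omnibus p = %.4g\n", nm, x$step1[[nm]]$p))
  }
  invisible(x)
}
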