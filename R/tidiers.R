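# broom-style tidiers for the fitted result objects.

#' Tidy a connection-wise test result
#'
#' @param x A `basc_edge_test`.
#' @param ... Unused.
#' @return Tibble with one row per tested connection (i, j, effect, t, p, q,
#'   discovered).
#' @method tidy basc_edge_test
#' @export
tidy.basc_edge_test <- function(x, ...) {
  mutate(x$edges, resolution = x$k, .before = 1)
}

#' @rdname tidy.basc_edge_test
#' @method glance basc_edge_test
#' @export
glance.basc_edge_test <- function(x, ...) {
  tibble(resolution = x$k, n_tested = x$n_tested,
         n_discovered = sum(x$edges$discovered),
         percent_discovery = x$percent_discovery, fdr_q = x$fdr_q)
}

#' Tidy an omnibus test result
#'
#' @param x A `basc_omnibus`.
#' @param ... Unused.
#' @return One row per resolution with its discovery fraction.
#' @method tidy basc_omnibus
#' @export
tidy.basc_omnibus <- function(x, ...) {
  bind_rows(lapply(x$per_resolution, glance))
}

#' @rdname tidy.basc_omnibus
#' @method glance basc_omnibus
#' @export
glance.basc_omnibus <- function(x, ...) {
  tibble(p.value = x$p, observed = x$observed,
         significant = x$significant, n_perm = x$n_perm, alpha = x$alpha)
}

#' Tidy a hub report
#'
#' @param x A `basc_hub_report`.
#' @param ... Unused.
#' @return Per cluster-by-group degree summary with hub flags.
#' @method tidy basc_hub_report
#' @export
tidy.basc_hub_report <- function(x, ...) {
  mutate(x$group_means,
         is_hub = .data$cluster %in% x$hub_clusters,
         in_analysis_set = .data$cluster %in% x$analysis_set)
}

#' @rdname tidy.basc_hub_report
#' @method glance basc_hub_report
#' @export
glance.basc_hub_report <- function(x, ...) {
  tibble(rule_mean = x$rule_mean, rule_sd = x$rule_sd,
         n_hubs = length(x$hub_clusters),
         n_analysis_set = length(x$analysis_set))
}

#' Tidy a subgroup ANOVA
#'
#' @param x A `basc_subgroup_anova`.
#' @param ... Unused.
#' @return The Type II ANOVA table as a tibble.
#' @method tidy basc_subgroup_anova
#' @export
tidy.basc_subgroup_anova <- function(x, ...) {
  x$anova
}

#' @rdname tidy.basc_subgroup_anova
#' @method glance basc_subgroup_anova
#' @export
glance.basc_subgroup_anova <- function(x, ...) {
  an <- x$anova
  tibble(
    p_group = an$p.value[an$term == "group"],
    p_subgroup = an$p.value[an$term == "subgroup"],
    p_interaction = an$p.value[an$term == "group:subgroup"],
    degenerate = x$degenerate
  )
}
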