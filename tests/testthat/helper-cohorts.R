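# Small cohort configurations reused across tests. Sizes are desk-scale so
# the default suite stays fast; acceptance tests build their own, larger
# cohorts.

tiny_config <- function(seed = 1L, ...) {
  args <- list(
    group_sizes = c(A = 4, B = 4), n_regions = 20, n_true_clusters = 4,
    timepoints_per_run = 80, runs_per_subject = 1,
    rho_within = 0.6, rho_between = 0.15,
    hub_nodes = list(A = integer(0), B = integer(0)),
    edge_effects = list(), seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# connectomes + design for a simulated two-group cohort at the planted
# partition (skips BASC, which has its own tests)
cohort_edge_inputs <- function(cfg, with_age = FALSE) {
  co <- simulate_cohort(cfg)
  part <- true_partition(cfg)
  conns <- lapply(co$subjects, subject_connectome, partition = part)
  pre <- lapply(co$subjects, preprocess_subject)
  dd <- co$covariates
  dd$mean_fd <- vapply(pre, `[[`, 0, "mean_fd")
  design <- build_design(dd, names(cfg$group_sizes)[1:2], with_age = with_age)
  list(cohort = co, connectomes = conns, design = design, data = dd,
       partition = part)
}
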