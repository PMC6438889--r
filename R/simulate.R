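# Synthetic multi-subject cohort generator.
#
# Region time series follow a latent-factor model: one latent signal per true
# cluster with a structured latent correlation matrix, plus independent
# region-level noise scaled so the expected within-cluster correlation equals
# rho_within. Hub boosts and group-specific edge effects act additively on the
# latent correlation matrix, so planted structure composes transparently and
# positive definiteness can be checked rather than silently repaired.

#' Simulation configuration for a synthetic resting-state cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()]. Defaults
#' describe a desk-scale cohort shaped like a typical aging/Parkinson's
#' resting-state study: four groups (younger and older healthy volunteers,
#' Parkinson's patients without and with mild cognitive impairment), three
#' runs of 150 volumes, 100 regions organised into 10 true functional
#' clusters.
#'
#' @param n_regions Number of regions (columns of each run matrix).
#' @param n_true_clusters Number of planted functional clusters.
#' @param timepoints_per_run Frames per run.
#' @param runs_per_subject Runs acquired per subject.
#' @param group_sizes Named integer vector of subjects per group. Names are
#'   the group labels; all sizes must be at least 2.
#' @param rho_within Target expected Pearson correlation between two regions
#'   of the same cluster, in `[0, 1)`.
#' @param rho_between Latent correlation between cluster factors, in
#'   `[0, rho_within)`. The realised region-level between-cluster correlation
#'   is attenuated to `rho_between * rho_within` by the region noise.
#' @param hub_nodes Named list mapping group label to integer cluster indices
#'   whose latent coupling to every other cluster is boosted for subjects of
#'   that group.
#' @param hub_boost Mean additive increment on the hub clusters' latent
#'   correlations.
#' @param hub_strength_sd Between-subject SD of the hub increment; subject
#'   hub strength is drawn once per subject (truncated at 0) and drives the
#'   cognition coupling below.
#' @param edge_effects List of planted connectivity effects, each a list with
#'   elements `pair` (two cluster indices), `group` (label), and `delta`
#'   (additive change to that latent correlation entry for that group).
#' @param fd_mean,fd_sd Mean and SD (mm) of the per-frame displacement trace,
#'   simulated i.i.d. log-normal per frame.
#' @param covariate_spec Named list (one entry per group) of lists with
#'   `age_mean`, `age_sd`, `p_male`, `bdi_mean`, `bdi_sd`, `z_baseline`
#'   (group-level mean cognitive z).
#' @param cognition_coupling Slope linking a subject's realised hub strength
#'   to their mean cognitive z-score.
#' @param z_noise_sd Residual SD of the subject mean cognitive z.
#' @param domain_noise_sd SD of the five domain scores around the subject
#'   mean (deviations are centred so the domain mean reproduces `mean_z`
#'   exactly).
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   configuration.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(group_sizes = c(A = 3, B = 2), n_regions = 20,
#'                   n_true_clusters = 4, timepoints_per_run = 60,
#'                   runs_per_subject = 1)
#' cohort <- simulate_cohort(cfg)
#' cohort$covariates
sim_config <- function(n_regions = 100,
                       n_true_clusters = 10,
                       timepoints_per_run = 150,
                       runs_per_subject = 3,
                       group_sizes = c("YHV" = 10, "OHV" = 10,
                                       "PD-non-MCI" = 10, "PD-MCI" = 10),
                       rho_within = 0.6,
                       rho_between = 0.2,
                       hub_nodes = default_hub_nodes(names(group_sizes)),
                       hub_boost = 0.15,
                       hub_strength_sd = 0.05,
                       edge_effects = list(),
                       fd_mean = 0.15,
                       fd_sd = 0.08,
                       covariate_spec = default_covariate_spec(names(group_sizes)),
                       cognition_coupling = 7,
                       z_noise_sd = 0.5,
                       domain_noise_sd = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    n_true_clusters = as.integer(n_true_clusters),
    timepoints_per_run = as.integer(timepoints_per_run),
    runs_per_subject = as.integer(runs_per_subject),
    group_sizes = group_sizes,
    rho_within = rho_within,
    rho_between = rho_between,
    hub_nodes = hub_nodes,
    hub_boost = hub_boost,
    hub_strength_sd = hub_strength_sd,
    edge_effects = edge_effects,
    fd_mean = fd_mean,
    fd_sd = fd_sd,
    covariate_spec = covariate_spec,
    cognition_coupling = cognition_coupling,
    z_noise_sd = z_noise_sd,
    domain_noise_sd = domain_noise_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (is.null(names(cfg$group_sizes)) || any(!nzchar(names(cfg$group_sizes)))) {
    abort("`group_sizes` must be a named vector of group sizes.")
  }
  if (any(cfg$group_sizes < 2)) {
    abort("All `group_sizes` must be >= 2.")
  }
  if (cfg$n_true_clusters > cfg$n_regions) {
    abort("`n_true_clusters` must not exceed `n_regions`.")
  }
  if (cfg$rho_within < 0 || cfg$rho_within >= 1) {
    abort("`rho_within` must lie in [0, 1).")
  }
  if (cfg$rho_between < 0 || cfg$rho_between >= cfg$rho_within) {
    abort("`rho_between` must lie in [0, rho_within).")
  }
  hub_idx <- unlist(cfg$hub_nodes, use.names = FALSE)
  if (length(hub_idx) && any(hub_idx < 1 | hub_idx > cfg$n_true_clusters)) {
    abort("`hub_nodes` cluster indices must lie in 1..n_true_clusters.")
  }
  bad_groups <- setdiff(names(cfg$hub_nodes), names(cfg$group_sizes))
  if (length(bad_groups)) {
    abort(sprintf("`hub_nodes` references unknown group(s): %s",
                  paste(bad_groups, collapse = ", ")))
  }
  for (eff in cfg$edge_effects) {
    if (!all(c("pair", "group", "delta") %in% names(eff))) {
      abort("Each edge effect needs `pair`, `group`, and `delta`.")
    }
    if (length(eff$pair) != 2 || any(eff$pair < 1 | eff$pair > cfg$n_true_clusters)) {
      abort("Edge-effect `pair` must be two cluster indices in range.")
    }
    if (!eff$group %in% names(cfg$group_sizes)) {
      abort(sprintf("Edge effect references unknown group '%s'.", eff$group))
    }
  }
  miss <- setdiff(names(cfg$group_sizes), names(cfg$covariate_spec))
  if (length(miss)) {
    abort(sprintf("`covariate_spec` missing group(s): %s",
                  paste(miss, collapse = ", ")))
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @param groups Character vector of group labels.
#' @export
default_hub_nodes <- function(groups) {
  known <- list("YHV" = c(1L, 2L), "OHV" = 1L,
                "PD-non-MCI" = 3L, "PD-MCI" = integer(0))
  out <- lapply(groups, function(g) known[[g]] %||% integer(0))
  names(out) <- groups
  out
}

#' @rdname sim_config
#' @export
default_covariate_spec <- function(groups) {
  # Demography emulates a typical cohort of this design: young controls in
  # their twenties, older controls ~70y, de-novo-to-moderate PD patients with
  # higher depression scores and (for the MCI subgroup) mean cognition about
  # one SD below standardised norms.
  known <- list(
    "YHV"        = list(age_mean = 23.8, age_sd = 3.2, p_male = 14 / 30,
                        bdi_mean = 3.0, bdi_sd = 2.5, z_baseline = 0.3),
    "OHV"        = list(age_mean = 70.0, age_sd = 5.4, p_male = 5 / 21,
                        bdi_mean = 4.3, bdi_sd = 4.2, z_baseline = 0.0),
    "PD-non-MCI" = list(age_mean = 63.8, age_sd = 7.4, p_male = 10 / 20,
                        bdi_mean = 7.7, bdi_sd = 5.6, z_baseline = -0.2),
    "PD-MCI"     = list(age_mean = 69.4, age_sd = 6.8, p_male = 10 / 15,
                        bdi_mean = 10.1, bdi_sd = 4.9, z_baseline = -1.0)
  )
  generic <- list(age_mean = 60, age_sd = 8, p_male = 0.5,
                  bdi_mean = 5, bdi_sd = 4, z_baseline = 0)
  out <- lapply(groups, function(g) known[[g]] %||% generic)
  names(out) <- groups
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Ground-truth region partition of a configuration
#'
#' Regions are assigned to the planted clusters in contiguous blocks of
#' near-equal size.
#'
#' @param cfg A [sim_config()] object.
#' @return Integer vector of length `n_regions` with values in
#'   `1..n_true_clusters`.
#' @export
true_partition <- function(cfg) {
  sort(rep_len(seq_len(cfg$n_true_clusters), cfg$n_regions))
}

# Latent correlation matrix for one subject: base exchangeable rho_between,
# hub rows/cols boosted by the subject's realised hub strength, planted edge
# deltas added last. Errors (rather than repairs) if the result leaves the
# valid correlation cone.
latent_correlation <- function(cfg, group, subject_boost) {
  m <- cfg$n_true_clusters
  C <- matrix(cfg$rho_between, m, m)
  diag(C) <- 1
  touched <- matrix(FALSE, m, m)
  hubs <- cfg$hub_nodes[[group]] %||% integer(0)
  for (h in hubs) {
    others <- setdiff(seq_len(m), h)
    C[h, others] <- C[h, others] + subject_boost
    C[others, h] <- C[h, others]
    touched[h, others] <- touched[others, h] <- TRUE
  }
  for (eff in cfg$edge_effects) {
    if (eff$group != group) next
    a <- eff$pair[1]; b <- eff$pair[2]
    C[a, b] <- C[a, b] + eff$delta
    C[b, a] <- C[a, b]
    touched[a, b] <- touched[b, a] <- TRUE
  }
  bad <- which(abs(C) >= 1 & row(C) != col(C), arr.ind = TRUE)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (nrow(bad) > 0 || min(ev) <= 1e-10) {
    offenders <- unique(apply(which(touched, arr.ind = TRUE), 1,
                              function(ij) paste(sort(ij), collapse = "-")))
    abort(sprintf(
      "Latent correlation matrix for group '%s' is not positive definite after boosts (min eigenvalue %.3g); modified entries: %s",
      group, min(ev),
      if (length(offenders)) paste(offenders, collapse = ", ") else "none"))
  }
  C
}

#' Simulate a multi-subject cohort of region time series
#'
#' Generates one record per subject: `runs_per_subject` time-by-region
#' matrices drawn from the latent-factor model, a per-frame displacement
#' trace per run, demographic covariates, and five cognitive-domain z-scores
#' whose mean is coupled to the subject's planted hub strength. The cohort is
#' bit-reproducible given the configuration (including its seed).
#'
#' @param cfg A [sim_config()] object.
#' @return An object of class `basc_cohort`: a list with elements
#'   \describe{
#'     \item{subjects}{list of subject records (`subject_id`, `group`,
#'       `runs`, `frame_displacement`, covariates, `domain_z`, `mean_z`).}
#'     \item{covariates}{tibble with one row per subject (subject_id, group,
#'       age, sex, bdi, the five domain z-scores, mean_z, hub_strength).}
#'     \item{ground_truth}{planted partition, hub map, edge effects, seed.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  part <- true_partition(cfg)
  noise_sd <- sqrt(1 / cfg$rho_within - 1)
  # log-normal parameters matched to the requested fd mean/sd by moments
  fd_sdlog <- sqrt(log(1 + (cfg$fd_sd / cfg$fd_mean)^2))
  fd_meanlog <- log(cfg$fd_mean) - fd_sdlog^2 / 2

  subjects <- list()
  cov_rows <- list()
  idx <- 0L
  for (g in names(cfg$group_sizes)) {
    spec <- cfg$covariate_spec[[g]]
    has_hubs <- length(cfg$hub_nodes[[g]] %||% integer(0)) > 0
    for (s in seq_len(cfg$group_sizes[[g]])) {
      idx <- idx + 1L
      sid <- sprintf("sub-%03d", idx)
      boost <- if (has_hubs) {
        # bounded subject heterogeneity: +-3 SD keeps every subject's latent
        # matrix inside the correlation cone for sane configurations
        z <- max(-3, min(3, rnorm(1)))
        max(0, cfg$hub_boost + cfg$hub_strength_sd * z)
      } else 0
      C <- latent_correlation(cfg, g, boost)
      R <- chol(C)
      runs <- vector("list", cfg$runs_per_subject)
      fds <- vector("list", cfg$runs_per_subject)
      for (r in seq_len(cfg$runs_per_subject)) {
        Z <- matrix(rnorm(cfg$timepoints_per_run * cfg$n_true_clusters),
                    cfg$timepoints_per_run, cfg$n_true_clusters)
        L <- Z %*% R
        X <- L[, part, drop = FALSE] +
          noise_sd * matrix(rnorm(cfg$timepoints_per_run * cfg$n_regions),
                            cfg$timepoints_per_run, cfg$n_regions)
        colnames(X) <- sprintf("R%03d", seq_len(cfg$n_regions))
        runs[[r]] <- X
        fds[[r]] <- rlnorm(cfg$timepoints_per_run, fd_meanlog, fd_sdlog)
      }
      age <- rnorm(1, spec$age_mean, spec$age_sd)
      sex <- if (runif(1) < spec$p_male) "M" else "F"
      bdi <- max(0, rnorm(1, spec$bdi_mean, spec$bdi_sd))
      mean_z <- spec$z_baseline + cfg$cognition_coupling * boost +
        rnorm(1, 0, cfg$z_noise_sd)
      eps <- rnorm(5, 0, cfg$domain_noise_sd)
      domain_z <- mean_z + (eps - mean(eps))
      names(domain_z) <- c("attention", "executive", "memory",
                           "visuospatial", "language")
      subjects[[idx]] <- structure(list(
        subject_id = sid, group = g, runs = runs,
        frame_displacement = fds, age = age, sex = sex, bdi = bdi,
        domain_z = domain_z, mean_z = mean(domain_z),
        hub_strength = boost
      ), class = "basc_subject")
      cov_rows[[idx]] <- tibble(
        subject_id = sid, group = g, age = age, sex = sex, bdi = bdi,
        z_attention = domain_z[["attention"]],
        z_executive = domain_z[["executive"]],
        z_memory = domain_z[["memory"]],
        z_visuospatial = domain_z[["visuospatial"]],
        z_language = domain_z[["language"]],
        mean_z = mean(domain_z), hub_strength = boost
      )
    }
  }
  structure(list(
    subjects = subjects,
    covariates = bind_rows(cov_rows),
    ground_truth = list(partition = part, hub_nodes = cfg$hub_nodes,
                        edge_effects = cfg$edge_effects, seed = cfg$seed),
    config = cfg
  ), class = "basc_cohort")
}

#' @export
print.basc_cohort <- function(x, ...) {
  sizes <- table(vapply(x$subjects, `[[`, "", "group"))
  first_run <- x$subjects[[1]]$runs[[1]]
  cat(sprintf(
    "<basc_cohort> %d subjects (%s); %d regions, %d run(s) of %d frames\n",
    length(x$subjects),
    paste(sprintf("%s:%d", names(sizes), sizes), collapse = ", "),
    ncol(first_run), length(x$subjects[[1]]$runs), nrow(first_run)))
  invisible(x)
}
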