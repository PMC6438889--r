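# Bootstrap analysis of stable clusters (BASC).
#
# Individual level: Ward clustering of regional time series is replicated
# under a circular block bootstrap of frames; the fraction of replications in
# which two regions co-cluster is their stability. Group level: subjects are
# bootstrapped, their stability matrices averaged and re-clustered, and the
# co-clustering of that consensus is accumulated into a group stability
# matrix. A final consensus clustering of the group stability matrix yields
# the partition at each resolution.

new_partition <- function(labels, k) {
  labels <- as.integer(labels)
  structure(list(labels = labels, k = as.integer(k)), class = "basc_partition")
}

#' @export
print.basc_partition <- function(x, ...) {
  cat(sprintf("<basc_partition> %d regions in %d clusters\n",
              length(x$labels), x$k))
  invisible(x)
}

new_stability <- function(values, n_replications, level) {
  structure(list(values = values, n_replications = as.integer(n_replications),
                 level = level), class = "basc_stability")
}

#' Circular block bootstrap of frame indices
#'
#' Draws blocks of `block_length` consecutive frame indices (wrapping past
#' the last frame) from uniformly random start points, concatenates them, and
#' truncates to `n_frames` indices. With `block_length = 1` this reduces to
#' i.i.d. resampling with replacement; preserving short blocks respects the
#' temporal autocorrelation of the series.
#'
#' @param n_frames Number of frames in the run.
#' @param block_length Block length; defaults to `ceiling(sqrt(n_frames))`,
#'   the standard rate-optimal order for dependent-data bootstraps.
#' @param seed Optional integer seed.
#' @return Integer vector of `n_frames` indices in `1..n_frames`.
#' @export
circular_block_bootstrap <- function(n_frames,
                                     block_length = ceiling(sqrt(n_frames)),
                                     seed = NULL) {
  if (block_length < 1) abort("`block_length` must be >= 1.")
  if (block_length > n_frames) abort("`block_length` must be <= `n_frames`.")
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- ceiling(n_frames / block_length)
  starts <- sample.int(n_frames, n_blocks, replace = TRUE)
  idx <- unlist(lapply(starts, function(s) {
    ((s - 1L + seq_len(block_length) - 1L) %% n_frames) + 1L
  }))
  idx[seq_len(n_frames)]
}

#' Ward partition of regions from their time series
#'
#' Computes the region-by-region Pearson correlation, converts it to the
#' Euclidean-equivalent distance `sqrt(2 * (1 - r))` (under which Ward's
#' variance criterion is meaningful for standardised series), runs
#' agglomerative Ward clustering, and cuts the tree at `k` clusters.
#'
#' @param ts Time-by-region numeric matrix.
#' @param k Number of clusters.
#' @return A `basc_partition`.
#' @export
ward_partition <- function(ts, k) {
  assert_ts_matrix(ts)
  if (k > ncol(ts)) abort("`k` must not exceed the number of regions.")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    abort(sprintf("Region(s) with zero variance: %s",
                  paste(colnames(ts)[bad] %||% bad, collapse = ", ")))
  }
  r <- cor(ts)
  d <- sqrt(pmax(2 * (1 - r), 0))
  hc <- hclust(as.dist(d), method = "ward.D2")
  new_partition(cutree(hc, k = k), k)
}

# Ward clustering of a stability (or any similarity in [0,1]) matrix at k.
cluster_similarity <- function(S, k) {
  d <- 1 - S
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "ward.D2")
  new_partition(cutree(hc, k = k), k)
}

co_cluster_indicator <- function(labels) {
  outer(labels, labels, "==") * 1
}

#' Individual-level stability matrix
#'
#' Replicates [ward_partition()] under the circular block bootstrap and
#' returns the region-by-region co-clustering probability.
#'
#' @param ts Time-by-region matrix (typically scrubbed, confound-regressed,
#'   runs concatenated).
#' @param k Resolution (number of clusters per replication).
#' @param n_boot Number of bootstrap replications (study-scale default 1000;
#'   pass something smaller for quick exploration).
#' @param block_length Bootstrap block length (default
#'   `ceiling(sqrt(nrow(ts)))`).
#' @param seed Optional integer seed.
#' @return A `basc_stability` object (symmetric, unit diagonal, entries are
#'   multiples of `1/n_boot`).
#' @export
individual_stability <- function(ts, k, n_boot = 1000,
                                 block_length = ceiling(sqrt(nrow(ts))),
                                 seed = NULL) {
  assert_ts_matrix(ts)
  if (n_boot < 1) abort("`n_boot` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(ts)
  acc <- matrix(0, n, n)
  for (b in seq_len(n_boot)) {
    idx <- circular_block_bootstrap(nrow(ts), block_length)
    part <- ward_partition(ts[idx, , drop = FALSE], k)
    acc <- acc + co_cluster_indicator(part$labels)
  }
  S <- acc / n_boot
  diag(S) <- 1
  dimnames(S) <- list(colnames(ts), colnames(ts))
  new_stability(S, n_boot, "individual")
}

#' Group-level stability matrix
#'
#' Bootstraps subjects with replacement; each replication averages the
#' resampled individual stability matrices, clusters the average with Ward
#' linkage on `1 - stability`, and accumulates the co-clustering indicator.
#'
#' @param individual_matrices List of `basc_stability` objects (or plain
#'   matrices) of identical dimension, one per subject.
#' @param k Resolution.
#' @param n_boot_group Number of subject-bootstrap replications (default
#'   500).
#' @param seed Optional integer seed.
#' @return A `basc_stability` object at level `"group"`.
#' @export
group_stability <- function(individual_matrices, k, n_boot_group = 500,
                            seed = NULL) {
  if (!length(individual_matrices)) abort("Need at least one subject matrix.")
  mats <- lapply(individual_matrices, function(m) {
    if (inherits(m, "basc_stability")) m$values else m
  })
  dims <- vapply(mats, nrow, 1L)
  if (length(unique(dims)) != 1) abort("All stability matrices must share dimensions.")
  if (n_boot_group < 1) abort("`n_boot_group` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(mats[[1]])
  n_sub <- length(mats)
  acc <- matrix(0, n, n)
  for (b in seq_len(n_boot_group)) {
    pick <- sample.int(n_sub, n_sub, replace = TRUE)
    avg <- Reduce(`+`, mats[pick]) / n_sub
    part <- cluster_similarity(avg, k)
    acc <- acc + co_cluster_indicator(part$labels)
  }
  S <- acc / n_boot_group
  diag(S) <- 1
  dimnames(S) <- dimnames(mats[[1]])
  new_stability(S, n_boot_group, "group")
}

#' Consensus partition of a group stability matrix
#'
#' Ward clustering on `1 - stability`, cut at `k`.
#'
#' @param group_stab A `basc_stability` object (or plain matrix).
#' @param k Resolution.
#' @return A `basc_partition`.
#' @export
consensus_partition <- function(group_stab, k) {
  S <- if (inherits(group_stab, "basc_stability")) group_stab$values else group_stab
  if (k > nrow(S)) abort("`k` must not exceed the number of regions.")
  cluster_similarity(S, k)
}

#' Full BASC chain over a resolution grid
#'
#' For each resolution in `grid`: individual stability per subject (runs
#' scrubbed, confound-regressed, and concatenated), group stability across
#' subjects, and a consensus partition. Results are cached to `cache_dir`
#' keyed by the inputs, so reruns and downstream stages are cheap.
#'
#' @param cohort A `basc_cohort` (from [simulate_cohort()] or
#'   [load_cohort()]).
#' @param grid Strictly increasing integer vector of resolutions, each at
#'   most `n_regions`. The study-scale default grid is
#'   `c(4, 10, 19, 35, 63, 118, 221, 393)`.
#' @param n_boot Individual-level replications (default 100 here; 1000 at
#'   study scale).
#' @param n_boot_group Group-level replications (default 100; 500 at study
#'   scale).
#' @param block_length Bootstrap block length; default
#'   `ceiling(sqrt(n_frames))` of the concatenated series.
#' @param seed Integer seed driving all replication streams.
#' @param cache_dir Optional directory for RDS caching.
#' @param fd_threshold,min_volumes,highpass_hz,tr_s Preprocessing settings,
#'   see [preprocess_subject()].
#' @return Named list (one element per resolution) of lists with `partition`
#'   (`basc_partition`) and `stability` (group `basc_stability`).
#' @export
run_multiresolution <- function(cohort, grid = c(4, 10, 19, 35, 63, 118, 221, 393),
                                n_boot = 100, n_boot_group = 100,
                                block_length = NULL, seed = 1L,
                                cache_dir = NULL,
                                fd_threshold = 0.5, min_volumes = 40,
                                highpass_hz = 0.01, tr_s = 2.6) {
  grid <- as.integer(grid)
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be strictly increasing.")
  }
  if (!length(cohort$subjects)) abort("Empty cohort.")
  n_regions <- ncol(cohort$subjects[[1]]$runs[[1]])
  if (any(grid > n_regions)) abort("Resolutions must not exceed n_regions.")

  pre <- lapply(cohort$subjects, preprocess_subject,
                fd_threshold = fd_threshold, min_volumes = min_volumes,
                highpass_hz = highpass_hz, tr_s = tr_s)
  keep <- !vapply(pre, `[[`, TRUE, "rejected")
  pre <- pre[keep]
  if (!length(pre)) abort("All subjects rejected during scrubbing.")

  cache_key <- NULL
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    cache_key <- rlang::hash(list(lapply(pre, `[[`, "ts"), n_boot,
                                  n_boot_group, block_length, seed))
  }
  out <- list()
  for (k in grid) {
    if (!is.null(cache_key)) {
      f <- file.path(cache_dir, sprintf("basc_%s_k%d.rds", cache_key, k))
      if (file.exists(f)) {
        out[[as.character(k)]] <- readRDS(f)
        next
      }
    }
    indiv <- vector("list", length(pre))
    for (i in seq_along(pre)) {
      ts <- pre[[i]]$ts
      bl <- block_length %||% ceiling(sqrt(nrow(ts)))
      indiv[[i]] <- individual_stability(
        ts, k, n_boot = n_boot, block_length = bl,
        seed = stage_seed(seed, sprintf("indiv_%d_%d", i, k)))
    }
    gs <- group_stability(indiv, k, n_boot_group = n_boot_group,
                          seed = stage_seed(seed, sprintf("group_%d", k)))
    res <- list(partition = consensus_partition(gs, k), stability = gs)
    out[[as.character(k)]] <- res
    if (!is.null(cache_key)) saveRDS(res, f)
  }
  out
}
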