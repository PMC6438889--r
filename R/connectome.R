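# Subject-level cluster-by-cluster Fisher-z connectomes.

#' Fisher z-transform of a correlation
#'
#' @param r Correlation value(s), each strictly inside (-1, 1).
#' @return `atanh(r)`.
#' @export
#' @examples
#' fisher_z(0.5)
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("`r` must be finite with |r| < 1; exclude degenerate pairs first.")
  }
  atanh(r)
}

#' Per-frame mean series of each cluster
#'
#' @param ts Time-by-region matrix.
#' @param partition A `basc_partition` (or integer label vector) covering all
#'   regions.
#' @return Time-by-k matrix; column `c` is the mean over regions labelled
#'   `c`.
#' @export
cluster_mean_series <- function(ts, partition) {
  assert_ts_matrix(ts)
  labels <- if (inherits(partition, "basc_partition")) partition$labels else as.integer(partition)
  if (length(labels) != ncol(ts)) {
    abort("`partition` must label every region (one label per column).")
  }
  k <- max(labels)
  out <- vapply(seq_len(k), function(c) {
    rowMeans(ts[, labels == c, drop = FALSE])
  }, numeric(nrow(ts)))
  matrix(out, nrow(ts), k, dimnames = list(NULL, sprintf("C%02d", seq_len(k))))
}

#' Build one connectome from a run and a partition
#'
#' Region series are standardised (zero mean, unit variance) before cluster
#' averaging, so each region contributes equally to its cluster mean and the
#' connectome is invariant to per-region affine rescaling. Off-diagonal
#' entry (a, b) is the Fisher z of the Pearson correlation between the two
#' clusters' mean series. Diagonal entry (a, a) is the Fisher
#' z of the average correlation over distinct region pairs inside cluster a
#' (self-correlations excluded); singleton clusters get `NaN` on the
#' diagonal.
#'
#' @param ts Time-by-region matrix (at least 3 frames).
#' @param partition A `basc_partition` or label vector.
#' @param subject_id,run_id Optional identifiers carried in the result.
#' @return An object of class `basc_connectome` with fields `values` (k-by-k
#'   symmetric z matrix), `k`, `subject_id`, `run_ids`.
#' @export
build_connectome <- function(ts, partition, subject_id = NA_character_,
                             run_id = NA_integer_) {
  assert_ts_matrix(ts)
  if (nrow(ts) < 3) abort("Need at least 3 frames to estimate correlations.")
  labels <- if (inherits(partition, "basc_partition")) partition$labels else as.integer(partition)
  reg_sds <- apply(ts, 2, sd)
  if (any(reg_sds == 0)) {
    abort(sprintf("Region(s) with zero variance: %s",
                  paste(which(reg_sds == 0), collapse = ", ")))
  }
  # regions are standardised before averaging so every region contributes
  # equally to its cluster mean and the connectome is invariant to
  # per-region affine rescaling
  M <- cluster_mean_series(scale(ts), labels)
  k <- ncol(M)
  sds <- apply(M, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("Cluster(s) with zero-variance mean series: %s",
                  paste(which(sds == 0), collapse = ", ")))
  }
  R <- cor(M)
  off <- abs(R) >= 1 & row(R) != col(R)
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)
    abort(sprintf("Degenerate cluster pair(s) with |r| = 1: %s",
                  paste(apply(bad, 1, paste, collapse = "-"), collapse = ", ")))
  }
  Z <- matrix(NA_real_, k, k)
  Z[row(Z) != col(Z)] <- atanh(R[row(R) != col(R)])
  r_full <- cor(ts)
  for (c in seq_len(k)) {
    members <- which(labels == c)
    if (length(members) < 2) {
      Z[c, c] <- NaN
    } else {
      sub <- r_full[members, members]
      mean_r <- mean(sub[upper.tri(sub)])
      Z[c, c] <- fisher_z(mean_r)
    }
  }
  dimnames(Z) <- list(colnames(M), colnames(M))
  structure(list(values = Z, k = k, subject_id = subject_id,
                 run_ids = run_id), class = "basc_connectome")
}

#' Average connectomes over runs (entrywise, in z-space)
#'
#' @param runs List of `basc_connectome` objects at the same resolution.
#' @return A `basc_connectome` whose entries are the entrywise means;
#'   diagonal `NaN`s propagate.
#' @export
average_connectomes <- function(runs) {
  if (!length(runs)) abort("Need at least one connectome.")
  ks <- vapply(runs, function(r) as.numeric(r$k), numeric(1))
  if (length(unique(ks)) != 1) abort("All connectomes must share resolution k.")
  vals <- Reduce(`+`, lapply(runs, `[[`, "values")) / length(runs)
  structure(list(values = vals, k = runs[[1]]$k,
                 subject_id = runs[[1]]$subject_id,
                 run_ids = unlist(lapply(runs, `[[`, "run_ids"))),
            class = "basc_connectome")
}

#' Per-subject connectome from preprocessed runs
#'
#' Builds one connectome per surviving run of a subject and averages them in
#' z-space. Preprocessing (scrubbing, confound regression) matches
#' [preprocess_subject()] but runs are kept separate so each run contributes
#' its own correlation estimate.
#'
#' @param subject A subject record.
#' @param partition Partition at the chosen resolution.
#' @param runs Optional run subset.
#' @inheritParams preprocess_subject
#' @return A `basc_connectome`, or `NULL` if every run was rejected.
#' @export
subject_connectome <- function(subject, partition, runs = NULL,
                               fd_threshold = 0.5, min_volumes = 40,
                               highpass_hz = 0.01, tr_s = 2.6) {
  run_ids <- runs %||% seq_along(subject$runs)
  conns <- list()
  for (r in run_ids) {
    sc <- scrub_frames(subject$runs[[r]], subject$frame_displacement[[r]],
                       fd_threshold, min_volumes)
    if (sc$rejected) next
    res <- regress_confounds(sc$ts, highpass_hz = highpass_hz, tr_s = tr_s)
    conns[[length(conns) + 1L]] <-
      build_connectome(res, partition, subject$subject_id, r)
  }
  if (!length(conns)) return(NULL)
  average_connectomes(conns)
}

#' @export
print.basc_connectome <- function(x, ...) {
  cat(sprintf("<basc_connectome> subject %s, k = %d, runs %s\n",
              x$subject_id, x$k, paste(x$run_ids, collapse = ",")))
  invisible(x)
}
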