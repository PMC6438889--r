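# Motion scrubbing and confound regression, applied per run before any
# clustering or connectivity step.

#' Remove high-motion frames from a run
#'
#' Frames whose displacement exceeds `fd_threshold` (strictly) are dropped.
#' A run retaining fewer than `min_volumes` frames is flagged rejected and
#' must be excluded downstream.
#'
#' @param ts Time-by-region numeric matrix.
#' @param fd Numeric vector of per-frame displacement (mm), same length as
#'   `nrow(ts)`.
#' @param fd_threshold Scrubbing threshold in mm (default 0.5).
#' @param min_volumes Minimum retained frames for a usable run (default 40).
#' @return A list with `ts` (retained rows), `kept` (retained frame indices),
#'   `rejected` (logical), and `n_retained`.
#' @export
#' @examples
#' ts <- matrix(rnorm(30), 10, 3)
#' scrub_frames(ts, fd = rep(0.1, 10))$rejected
scrub_frames <- function(ts, fd, fd_threshold = 0.5, min_volumes = 40) {
  assert_ts_matrix(ts)
  if (length(fd) != nrow(ts)) {
    abort(sprintf("`fd` has length %d but `ts` has %d rows.",
                  length(fd), nrow(ts)))
  }
  if (fd_threshold <= 0) abort("`fd_threshold` must be positive.")
  kept <- which(fd <= fd_threshold)
  list(
    ts = ts[kept, , drop = FALSE],
    kept = kept,
    rejected = length(kept) < min_volumes,
    n_retained = length(kept)
  )
}

# Discrete cosine drift basis: unit-norm cosines whose frequencies
# j / (2 * T * tr_s) lie strictly below the high-pass cut-off, i.e. the slow
# components a high-pass filter at that cut-off would remove.
cosine_drift_basis <- function(n_frames, tr_s, highpass_hz) {
  if (is.null(highpass_hz) || highpass_hz <= 0) {
    return(matrix(numeric(0), n_frames, 0))
  }
  n_comp <- floor(2 * n_frames * tr_s * highpass_hz)
  n_comp <- min(n_comp, n_frames - 1)
  if (n_comp < 1) return(matrix(numeric(0), n_frames, 0))
  t_idx <- seq_len(n_frames) - 0.5
  B <- vapply(seq_len(n_comp),
              function(j) cos(pi * t_idx * j / n_frames),
              numeric(n_frames))
  B <- matrix(B, n_frames, n_comp)
  sweep(B, 2, sqrt(colSums(B^2)), "/")
}

#' Regress slow drifts and confounds out of a run
#'
#' Fits, by ordinary least squares, a regressor set made of an intercept, a
#' discrete-cosine drift basis up to the high-pass cut-off, and any supplied
#' confound columns, and returns the residuals per region. Collinear
#' regressors are dropped with a warning.
#'
#' @param ts Time-by-region numeric matrix.
#' @param confounds Optional time-by-q numeric matrix of nuisance regressors
#'   (e.g. motion parameter components).
#' @param highpass_hz High-pass cut-off in Hz for the cosine drift basis
#'   (default 0.01); `NULL` or 0 disables the drift basis.
#' @param tr_s Repetition time in seconds (default 2.6).
#' @return Residual matrix with the same dimensions as `ts`.
#' @export
regress_confounds <- function(ts, confounds = NULL, highpass_hz = 0.01,
                              tr_s = 2.6) {
  assert_ts_matrix(ts)
  n <- nrow(ts)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n) {
      abort(sprintf("`confounds` has %d rows but `ts` has %d.",
                    nrow(confounds), n))
    }
  } else {
    confounds <- matrix(numeric(0), n, 0)
  }
  X <- cbind(intercept = rep(1, n), cosine_drift_basis(n, tr_s, highpass_hz),
             confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1, ncol(X))]
    warn(sprintf("Dropping %d collinear confound column(s): %s",
                 length(drop_idx),
                 paste(drop_idx, collapse = ", ")))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  ts - X %*% qr.coef(qrX, ts)
}

#' Scrub, denoise, and concatenate a subject's runs
#'
#' Applies [scrub_frames()] then [regress_confounds()] to each run and
#' concatenates the surviving runs row-wise. Rejected runs (too few retained
#' frames) are dropped; if every run is rejected the subject is flagged.
#'
#' @param subject A subject record from [simulate_cohort()] or
#'   [load_cohort()].
#' @param fd_threshold,min_volumes See [scrub_frames()].
#' @param highpass_hz,tr_s See [regress_confounds()].
#' @param runs Optional integer subset of runs to use (default all).
#' @return A list with `ts` (concatenated residual matrix), `runs_used`,
#'   `frames_retained` (per used run), `mean_fd` (mean displacement over the
#'   used runs, the motion covariate carried into group models), and
#'   `rejected` (TRUE when no run survives).
#' @export
preprocess_subject <- function(subject, fd_threshold = 0.5, min_volumes = 40,
                               highpass_hz = 0.01, tr_s = 2.6, runs = NULL) {
  run_ids <- runs %||% seq_along(subject$runs)
  kept_ts <- list()
  used <- integer(0)
  frames <- integer(0)
  fd_all <- numeric(0)
  for (r in run_ids) {
    sc <- scrub_frames(subject$runs[[r]], subject$frame_displacement[[r]],
                       fd_threshold, min_volumes)
    if (sc$rejected) next
    res <- regress_confounds(sc$ts, highpass_hz = highpass_hz, tr_s = tr_s)
    kept_ts[[length(kept_ts) + 1L]] <- res
    used <- c(used, r)
    frames <- c(frames, sc$n_retained)
    fd_all <- c(fd_all, subject$frame_displacement[[r]])
  }
  if (!length(used)) {
    return(list(ts = NULL, runs_used = integer(0), frames_retained = integer(0),
                mean_fd = NA_real_, rejected = TRUE))
  }
  list(ts = do.call(rbind, kept_ts), runs_used = used,
       frames_retained = frames, mean_fd = mean(fd_all), rejected = FALSE)
}
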