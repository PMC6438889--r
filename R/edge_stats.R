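# Step-1 statistics: connection-wise group contrasts on Fisher-z
# connectomes, FDR control per resolution, and a label-permutation omnibus
# test pooling discoveries across resolutions.

#' Build a two-group design matrix
#'
#' Rows are the subjects belonging to the two contrasted groups, in the
#' order of `data`. Columns: intercept, `group_dummy` (1 for the second
#' group of `contrast`), mean frame displacement, and optionally
#' mean-centred age.
#'
#' @param data Tibble/data frame with columns `subject_id`, `group`, a motion
#'   column (`mean_fd` by default), and `age` when `with_age = TRUE`.
#' @param contrast Character vector of two group labels `(A, B)`; the tested
#'   effect is B minus A.
#' @param with_age Include mean-centred age as a covariate.
#' @param fd_col Name of the motion covariate column; set `NULL` to omit.
#' @return List with `X` (numeric design matrix), `contrast` (tested column
#'   name), `subject_id`, `group`.
#' @export
build_design <- function(data, contrast, with_age = FALSE, fd_col = "mean_fd") {
  if (length(contrast) != 2) abort("`contrast` must name exactly two groups.")
  missing_groups <- setdiff(contrast, unique(data$group))
  if (length(missing_groups)) {
    abort(sprintf("Group(s) not present in data: %s",
                  paste(missing_groups, collapse = ", ")))
  }
  d <- data[data$group %in% contrast, , drop = FALSE]
  X <- cbind(intercept = rep(1, nrow(d)),
             group_dummy = as.numeric(d$group == contrast[2]))
  if (!is.null(fd_col)) {
    if (!fd_col %in% names(d)) abort(sprintf("Column '%s' not found.", fd_col))
    X <- cbind(X, mean_fd = d[[fd_col]])
  }
  if (with_age) {
    if (!"age" %in% names(d)) abort("Column 'age' not found.")
    X <- cbind(X, age = d$age - mean(d$age))
  }
  if (qr(X)$rank < ncol(X)) {
    abort("Design matrix is rank deficient (collinear covariates).")
  }
  list(X = X, contrast = "group_dummy",
       subject_id = d$subject_id, group = d$group)
}

#' Ordinary-least-squares contrast for one connection
#'
#' @param y Numeric response, one value per design row.
#' @param design A design from [build_design()].
#' @return List with `effect` (contrast coefficient), `t`, `p` (two-sided,
#'   Student t on residual df), `df`, and `degenerate` (TRUE when the
#'   residual variance is numerically zero; then `p = 1` by convention).
#' @export
glm_contrast <- function(y, design) {
  X <- design$X
  if (length(y) != nrow(X)) abort("`y` length must match design rows.")
  if (nrow(X) <= ncol(X) + 1) abort("Need more subjects than covariates + 1.")
  fit <- ols_edges(X, matrix(y, ncol = 1), which(colnames(X) == design$contrast))
  list(effect = fit$effect[1], t = fit$t[1], p = fit$p[1],
       df = fit$df, degenerate = fit$degenerate[1])
}

# Shared vectorised OLS over many connections: Y is n x E, one column per
# connection; returns the contrast coefficient, t, and p per column.
ols_edges <- function(X, Y, contrast_idx) {
  n <- nrow(X); p <- ncol(X)
  XtX_inv <- solve(crossprod(X))
  B <- XtX_inv %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtX_inv[contrast_idx, contrast_idx])
  effect <- B[contrast_idx, ]
  degenerate <- sigma2 < 1e-24
  tval <- ifelse(degenerate & abs(effect) < 1e-12, 0, effect / se)
  pval <- ifelse(degenerate & abs(effect) < 1e-12, 1,
                 2 * pt(-abs(tval), df))
  list(effect = as.numeric(effect), t = as.numeric(tval),
       p = as.numeric(pval), df = df, degenerate = degenerate)
}

#' Benjamini-Hochberg discovery mask
#'
#' Step-up FDR control at level `q`.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q Target false-discovery rate, in (0, 1).
#' @return Logical vector: TRUE where the hypothesis is discovered.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (q <= 0 || q >= 1) abort("`q` must lie in (0, 1).")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) abort("p-values outside [0, 1].")
  p.adjust(pvals, method = "BH") <= q
}

#' Connection-wise GLM at one resolution
#'
#' Fits [glm_contrast()] to every unique connection (upper triangle
#' including within-cluster diagonal entries; connections with `NaN` in any
#' subject, i.e. singleton-cluster diagonals, are skipped), applies
#' Benjamini-Hochberg across all tested connections, and summarises
#' discovery rates overall and per cluster.
#'
#' @param connectomes List of `basc_connectome` objects at a common `k`,
#'   aligned with the design rows.
#' @param design A design from [build_design()].
#' @param q FDR level (default 0.05).
#' @return An object of class `basc_edge_test`: list with `edges` (tibble
#'   i, j, effect, t, p, q, discovered), `k`, `n_tested`,
#'   `percent_discovery`, `per_cluster_discovery`, `fdr_q`.
#' @export
resolution_glm <- function(connectomes, design, q = 0.05) {
  ks <- vapply(connectomes, `[[`, 1L, "k")
  if (length(unique(ks)) != 1) abort("All connectomes must share resolution k.")
  if (length(connectomes) != nrow(design$X)) {
    abort("Connectome list must align with design rows.")
  }
  k <- ks[1]
  Y_full <- t(vapply(connectomes, function(cn) {
    v <- cn$values
    v[upper.tri(v, diag = TRUE)]
  }, numeric(k * (k + 1) / 2)))
  ij <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  usable <- colSums(!is.finite(Y_full)) == 0
  fit <- ols_edges(design$X, Y_full[, usable, drop = FALSE],
                   which(colnames(design$X) == design$contrast))
  disc <- fdr_bh(fit$p, q)
  edges <- tibble(
    i = ij[usable, 1], j = ij[usable, 2],
    effect = fit$effect, t = fit$t, p = fit$p,
    q = p.adjust(fit$p, method = "BH"),
    discovered = disc
  )
  per_cluster <- vapply(seq_len(k), function(c) {
    inc <- edges$i == c | edges$j == c
    if (!any(inc)) return(NA_real_)
    mean(edges$discovered[inc])
  }, numeric(1))
  structure(list(
    edges = edges, k = k, n_tested = nrow(edges),
    percent_discovery = mean(edges$discovered),
    per_cluster_discovery = per_cluster,
    fdr_q = q, contrast = design$contrast
  ), class = "basc_edge_test")
}

#' @export
print.basc_edge_test <- function(x, ...) {
  cat(sprintf("<basc_edge_test> k = %d: %d/%d connections discovered (q <= %.2g)\n",
              x$k, sum(x$edges$discovered), x$n_tested, x$fdr_q))
  invisible(x)
}

#' Omnibus permutation test pooling discoveries across resolutions
#'
#' The observed statistic is the total number of FDR discoveries summed over
#' all resolutions. The null distribution permutes the group labels among
#' the contrasted subjects (all other covariates stay with their subjects)
#' and recomputes the connection-wise GLM and FDR at every resolution. A
#' family-wise gate: per-resolution results should only be interpreted when
#' the omnibus p-value passes `alpha`.
#'
#' @param connectomes_by_k Named list (resolution -> list of
#'   `basc_connectome` aligned with the design rows).
#' @param design A design from [build_design()].
#' @param q FDR level within each resolution.
#' @param n_perm Number of permutations (>= 99).
#' @param alpha Family-wise level for the gate (default 0.05).
#' @param seed Optional integer seed.
#' @return An object of class `basc_omnibus`: list with `p`, `observed`
#'   (total discoveries), `significant` (`p <= alpha`), `per_resolution`
#'   (list of `basc_edge_test`), `perm_stats`, `alpha`.
#' @export
omnibus_test <- function(connectomes_by_k, design, q = 0.05, n_perm = 199,
                         alpha = 0.05, seed = NULL) {
  if (n_perm < 99) abort("`n_perm` must be >= 99.")
  if (!is.null(seed)) set.seed(seed)
  per_res <- lapply(connectomes_by_k, resolution_glm, design = design, q = q)
  observed <- sum(vapply(per_res, function(r) sum(r$edges$discovered), 1L))

  # pre-extract response matrices once; permutations only change the dummy
  c_idx <- which(colnames(design$X) == design$contrast)
  Ys <- lapply(connectomes_by_k, function(conns) {
    k <- conns[[1]]$k
    Y <- t(vapply(conns, function(cn) {
      v <- cn$values
      v[upper.tri(v, diag = TRUE)]
    }, numeric(k * (k + 1) / 2)))
    Y[, colSums(!is.finite(Y)) == 0, drop = FALSE]
  })
  n <- nrow(design$X)
  perm_stats <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    Xp <- design$X
    Xp[, c_idx] <- design$X[sample.int(n), c_idx]
    if (qr(Xp)$rank < ncol(Xp)) {
      # pathological permutation (e.g. dummy collinear with a covariate);
      # count zero discoveries for it
      perm_stats[b] <- 0L
      next
    }
    perm_stats[b] <- sum(vapply(Ys, function(Y) {
      fit <- ols_edges(Xp, Y, c_idx)
      sum(fdr_bh(fit$p, q))
    }, 1L))
  }
  p <- (1 + sum(perm_stats >= observed)) / (1 + n_perm)
  structure(list(p = p, observed = observed, significant = p <= alpha,
                 per_resolution = per_res, perm_stats = perm_stats,
                 alpha = alpha, n_perm = n_perm),
            class = "basc_omnibus")
}

#' @export
print.basc_omnibus <- function(x, ...) {
  cat(sprintf("<basc_omnibus> %d pooled discoveries, p = %.4g (%ssignificant at %.2g)\n",
              x$observed, x$p, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}
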