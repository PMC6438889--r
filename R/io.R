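# Plain-text cohort layout: one TSV time-series matrix and one TSV frame
# displacement file per subject-run, a cohort covariate table, and a JSON
# ground-truth sidecar when the cohort is synthetic.

#' Write a cohort to a directory of TSV files
#'
#' Layout: `covariates.tsv` (one row per subject),
#' `<subject>_run-<r>_ts.tsv` (frames x regions, region ids as header),
#' `<subject>_run-<r>_fd.tsv` (single `fd` column), and
#' `ground_truth.json` (planted partition, hubs, edge effects, seed) when
#' present.
#'
#' @param cohort A `basc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  for (sub in cohort$subjects) {
    for (r in seq_along(sub$runs)) {
      ts_path <- file.path(dir, sprintf("%s_run-%d_ts.tsv", sub$subject_id, r))
      readr::write_tsv(as_tibble(as.data.frame(sub$runs[[r]])), ts_path)
      fd_path <- file.path(dir, sprintf("%s_run-%d_fd.tsv", sub$subject_id, r))
      readr::write_tsv(tibble(fd = sub$frame_displacement[[r]]), fd_path)
    }
  }
  if (!is.null(cohort$ground_truth)) {
    jsonlite::write_json(cohort$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

read_numeric_tsv <- function(path) {
  df <- suppressWarnings(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(sprintf("Non-numeric cell in %s at row %d, column %d.",
                  basename(path), probs$row[1], probs$col[1]))
  }
  as.matrix(df)
}

#' Load a cohort from a directory written by [write_cohort()]
#'
#' Validates the layout: every run file must have a covariate row, frame
#' displacement length must match the run's frame count, and all cells must
#' be numeric (errors name the offending file and location).
#'
#' @param dir Cohort directory.
#' @return A `basc_cohort` (with `ground_truth` when the sidecar exists;
#'   `config` is `NULL` for loaded cohorts).
#' @export
load_cohort <- function(dir) {
  cov_path <- file.path(dir, "covariates.tsv")
  if (!file.exists(cov_path)) abort(sprintf("Missing %s.", cov_path))
  covariates <- readr::read_tsv(cov_path, show_col_types = FALSE,
                                progress = FALSE)
  ts_files <- sort(list.files(dir, pattern = "_run-[0-9]+_ts\\.tsv$"))
  if (!length(ts_files)) abort("No run files (*_run-*_ts.tsv) found.")
  sids <- unique(sub("_run-[0-9]+_ts\\.tsv$", "", ts_files))
  missing <- setdiff(sids, covariates$subject_id)
  if (length(missing)) {
    abort(sprintf("Covariate table missing subject(s): %s",
                  paste(missing, collapse = ", ")))
  }
  subjects <- lapply(sids, function(sid) {
    runs_f <- sort(list.files(dir, pattern = paste0("^", sid, "_run-[0-9]+_ts\\.tsv$")))
    runs <- list(); fds <- list()
    for (f in runs_f) {
      r <- as.integer(sub(".*_run-([0-9]+)_ts\\.tsv$", "\\1", f))
      ts <- read_numeric_tsv(file.path(dir, f))
      fd_path <- file.path(dir, sprintf("%s_run-%d_fd.tsv", sid, r))
      if (!file.exists(fd_path)) abort(sprintf("Missing %s.", fd_path))
      fd <- as.numeric(read_numeric_tsv(fd_path))
      if (length(fd) != nrow(ts)) {
        abort(sprintf("%s: %d displacement values for %d frames.",
                      basename(fd_path), length(fd), nrow(ts)))
      }
      runs[[r]] <- ts
      fds[[r]] <- fd
    }
    cv <- covariates[covariates$subject_id == sid, ]
    dz <- unlist(cv[paste0("z_", c("attention", "executive", "memory",
                                   "visuospatial", "language"))])
    names(dz) <- sub("^z_", "", names(dz))
    structure(list(
      subject_id = sid, group = cv$group, runs = runs,
      frame_displacement = fds, age = cv$age, sex = cv$sex, bdi = cv$bdi,
      domain_z = dz, mean_z = cv$mean_z,
      hub_strength = if ("hub_strength" %in% names(cv)) cv$hub_strength else NA_real_
    ), class = "basc_subject")
  })
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  structure(list(subjects = subjects, covariates = covariates,
                 ground_truth = gt, config = NULL),
            class = "basc_cohort")
}

#' Write a partition as a two-column TSV
#'
#' @param partition A `basc_partition`.
#' @param path Output file.
#' @param region_ids Optional region identifiers.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path, region_ids = NULL) {
  ids <- region_ids %||% sprintf("R%03d", seq_along(partition$labels))
  readr::write_tsv(tibble(region_id = ids, cluster_id = partition$labels), path)
  invisible(path)
}

#' Write a stability (or connectome) matrix as TSV with id header
#'
#' @param m A `basc_stability`, `basc_connectome`, or plain matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  v <- if (inherits(m, c("basc_stability", "basc_connectome"))) m$values else m
  readr::write_tsv(as_tibble(as.data.frame(v)), path)
  invisible(path)
}
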