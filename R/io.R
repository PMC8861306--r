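# Readers and writers for the pipeline's plain-text interchange formats:
# per-subject ROI series TSVs, the cohort manifest TSV, and JSON model /
# partition files.

MANIFEST_COLUMNS <- c("subject_id", "group", "site", "age", "fiq",
                      "mean_fd", "path")

#' Read a cohort manifest
#'
#' Validates the required columns (`subject_id`, `group`, `site`, `age`,
#' `fiq`, `mean_fd`, `path`), uniqueness of subject ids and numeric
#' covariates.
#'
#' @param path manifest TSV path.
#' @return data.frame with the manifest rows (series paths resolved
#'   relative to the manifest's directory).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  man <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(man))
  if (length(missing_cols))
    stopf("manifest %s: missing column(s) %s", path,
          paste(missing_cols, collapse = ", "))
  dup <- man$subject_id[duplicated(man$subject_id)]
  if (length(dup))
    stopf("manifest %s: duplicate subject_id %s", path,
          paste(unique(dup), collapse = ", "))
  for (col in c("age", "fiq", "mean_fd")) {
    if (!is.numeric(man[[col]]))
      stopf("manifest %s: column %s must be numeric", path, col)
    if (anyNA(man[[col]]))
      stopf("manifest %s: missing values in column %s", path, col)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man
}

#' Read one subject's ROI time-series TSV
#'
#' Expects a header row of ROI labels and `T` numeric rows.
#'
#' @param path series TSV path.
#' @return numeric `T x R` matrix with ROI column names.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stopf("series file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  bad <- names(df)[!vapply(df, is.numeric, TRUE)]
  if (length(bad))
    stopf("series %s: non-numeric column(s) %s", path,
          paste(bad, collapse = ", "))
  if (anyNA(df)) stopf("series %s: missing values", path)
  if (nrow(df) < 2L) stopf("series %s: need at least 2 timepoints", path)
  as.matrix(df)
}

#' Write a subject series TSV
#' @param x numeric `T x R` matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("ROI", seq_len(ncol(x)))
  df <- as.data.frame(x)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a cohort from a manifest
#'
#' Reads every subject series named in the manifest and assembles a
#' `cohort` object (without ground truth).
#'
#' @param manifest_path manifest TSV path.
#' @return a `cohort` object.
#' @export
load_cohort <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    X <- read_series(man$path[i])
    list(subject_id = man$subject_id[i], group = man$group[i],
         site = man$site[i], age = man$age[i], fiq = man$fiq[i],
         mean_fd = man$mean_fd[i], data = X, true_path = NULL)
  })
  R <- unique(vapply(subjects, function(s) ncol(s$data), 0L))
  if (length(R) != 1L)
    stopf("subjects disagree on region count: %s", paste(R, collapse = ", "))
  structure(list(subjects = subjects, manifest = man, truth = NULL,
                 config = NULL), class = "cohort")
}

write_hmm_json <- function(fit, path) {
  jsonlite::write_json(
    list(K = fit$K, P = fit$P, means = fit$means,
         covariances = fit$covariances, transition = fit$transition,
         initial = fit$initial, free_energy_trace = fit$free_energy_trace,
         seed = fit$seed),
    path, digits = NA, matrix = "rowmajor", auto_unbox = TRUE)
  invisible(path)
}
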