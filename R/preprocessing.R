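# Per-subject standardization, cohort concatenation and PCA reduction.
# The PCA is fit once on the group-concatenated matrix so that HMM state
# means live in a single shared low-dimensional space.

#' Standardize a subject's ROI time courses
#'
#' Each channel (column) is demeaned and divided by its sample standard
#' deviation (denominator `n - 1`), so every ROI has mean 0 and SD 1.
#'
#' @param x numeric `T x R` matrix, or a cohort subject list with a `data`
#'   element.
#' @param subject_id used in error messages.
#' @return the standardized object (same shape as the input).
#' @export
standardize_series <- function(x, subject_id = NULL) {
  if (is.list(x) && !is.null(x$data)) {
    x$data <- standardize_series(x$data, subject_id = x$subject_id)
    return(x)
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) stopf("subject %s: missing values in series",
                      subject_id %||% "<unnamed>")
  sds <- apply(x, 2, sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad))
    stopf("subject %s: zero-variance channel(s) %s",
          subject_id %||% "<unnamed>",
          paste(colnames(x)[bad] %||% bad, collapse = ", "))
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Concatenate standardized subjects into one stacked matrix
#'
#' Rows follow manifest order; the returned span index partitions the rows
#' exactly (1-based inclusive `start`/`end` per subject).
#'
#' @param cohort a `cohort` object or a list of `T x R` matrices.
#' @return list with `data` (`sum(T) x R`), `spans` (data.frame
#'   `subject_id`, `start`, `end`) .
#' @export
concatenate_cohort <- function(cohort) {
  mats <- if (inherits(cohort, "cohort"))
    lapply(cohort$subjects, `[[`, "data") else cohort
  if (length(mats) == 0L) stopf("empty cohort")
  ids <- if (inherits(cohort, "cohort"))
    vapply(cohort$subjects, `[[`, "", "subject_id")
  else names(mats) %||% sprintf("sub-%03d", seq_along(mats))
  R <- ncol(mats[[1]])
  if (!all(vapply(mats, ncol, 0L) == R))
    stopf("all subjects must have the same number of regions")
  Ts <- vapply(mats, nrow, 0L)
  ends <- cumsum(Ts)
  spans <- data.frame(subject_id = ids, start = c(1L, head(ends, -1) + 1L),
                      end = ends, stringsAsFactors = FALSE)
  list(data = do.call(rbind, mats), spans = spans)
}

#' Fit a PCA transform on the stacked cohort matrix
#'
#' Retains either a fixed number of components or the smallest number whose
#' cumulative explained-variance ratio reaches `variance_target`.  When
#' both are supplied `n_components` wins and the achieved variance is
#' reported via a message.  Loadings follow a deterministic sign
#' convention: each column's largest-magnitude entry is positive.
#'
#' @param stacked `(sum T) x R` matrix (rows = timepoints).
#' @param n_components optional fixed component count.
#' @param variance_target cumulative explained-variance target in (0, 1].
#' @return object of class `pca_transform`: `center` (length `R`),
#'   `loadings` (`R x P`, orthonormal columns), `explained_variance_ratio`,
#'   `P`.
#' @export
fit_pca <- function(stacked, n_components = NULL, variance_target = 0.90) {
  stopifnot(is.matrix(stacked))
  if (nrow(stacked) < ncol(stacked))
    warnf("fewer rows (%d) than columns (%d); PCA is rank-deficient",
          nrow(stacked), ncol(stacked))
  if (is.null(n_components)) {
    if (!is.numeric(variance_target) || variance_target <= 0 || variance_target > 1)
      stopf("variance_target must be in (0, 1]")
  }
  pc <- prcomp(stacked, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  # drop numerically null directions so rank-deficient input gives rank P
  rank <- max(1L, sum(evr > 1e-12))
  if (!is.null(n_components)) {
    if (!is_count(n_components) || n_components > ncol(stacked))
      stopf("n_components must be a count <= R")
    P <- as.integer(min(n_components, rank))
    message(sprintf("PCA: P = %d retains %.1f%% of variance",
                    P, 100 * sum(evr[seq_len(P)])))
  } else {
    P <- as.integer(min(which(cumsum(evr) >= variance_target - 1e-12)))
  }
  L <- pc$rotation[, seq_len(P), drop = FALSE]
  flip <- apply(L, 2, function(v) sign(v[which.max(abs(v))]))
  L <- sweep(L, 2, flip, `*`)
  structure(list(center = pc$center, loadings = L,
                 explained_variance_ratio = evr[seq_len(P)], P = P),
            class = "pca_transform")
}

#' Project data into PCA space
#' @param x `n x R` matrix or length-`R` vector.
#' @param transform a [fit_pca()] result.
#' @return `n x P` matrix (or length-`P` vector for vector input).
#' @export
pca_project <- function(x, transform) {
  stopifnot(inherits(transform, "pca_transform"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1L)
  if (ncol(x) != length(transform$center))
    stopf("dimension mismatch: data has %d columns, transform expects %d",
          ncol(x), length(transform$center))
  out <- sweep(x, 2, transform$center) %*% transform$loadings
  if (vec) drop(out) else out
}

#' Map PCA-space coordinates back to ROI space
#' @param y `n x P` matrix or length-`P` vector of component scores.
#' @param transform a [fit_pca()] result.
#' @return `n x R` matrix (or length-`R` vector); `pca_backproject(0)` is
#'   the center vector.
#' @export
pca_backproject <- function(y, transform) {
  stopifnot(inherits(transform, "pca_transform"))
  vec <- is.null(dim(y))
  if (vec) y <- matrix(y, 1L)
  if (ncol(y) != transform$P)
    stopf("dimension mismatch: scores have %d columns, transform has P = %d",
          ncol(y), transform$P)
  out <- sweep(y %*% t(transform$loadings), 2, transform$center, `+`)
  if (vec) drop(out) else out
}

#' Serialize / read a PCA transform as JSON
#' @param transform a `pca_transform`.
#' @param path file path.
#' @return `path` (write) or a `pca_transform` (read).
#' @export
write_pca <- function(transform, path) {
  stopifnot(inherits(transform, "pca_transform"))
  jsonlite::write_json(unclass(transform), path, digits = NA,
                       matrix = "rowmajor", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca
#' @export
read_pca <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = as.numeric(x$center),
                 loadings = matrix(as.numeric(x$loadings), ncol = x$P),
                 explained_variance_ratio = as.numeric(x$explained_variance_ratio),
                 P = as.integer(x$P)),
            class = "pca_transform")
}

#' Standardize, concatenate and project a cohort in one step
#'
#' Convenience wrapper running the full preprocessing chain:
#' per-subject standardization, concatenation in manifest order, PCA fit
#' on the stacked matrix and projection onto the retained components.
#'
#' @param cohort a `cohort` object.
#' @param n_components,variance_target passed to [fit_pca()].
#' @return list with `projected` (`sum(T) x P`), `spans`, `transform`,
#'   `stacked` (standardized `sum(T) x R`).
#' @export
preprocess_cohort <- function(cohort, n_components = NULL,
                              variance_target = 0.90) {
  std <- lapply(cohort$subjects, standardize_series)
  st <- concatenate_cohort(structure(list(subjects = std), class = "cohort"))
  transform <- fit_pca(st$data, n_components = n_components,
                       variance_target = variance_target)
  list(projected = pca_project(st$data, transform), spans = st$spans,
       transform = transform, stacked = st$data)
}
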