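# Model-order scan: fit the HMM over a range of K, record the best free
# energy per K and a median fractional-occupancy summary of the winning
# restart.  The summary is the median over states of each state's median
# FO across subjects: once K exceeds the number of states the data
# support, surplus states go (near-)empty, their per-state medians hit
# zero, and the summary stops decreasing -- giving the elbow the
# selection rule needs.  (The naive median over all pooled subject x
# state FO values keeps creeping down by ~1/K even with perfectly empty
# surplus states, because the zeros push the median into the lower tail
# of the real states' cross-subject FO spread; it has no elbow.)
# Free energy typically decreases monotonically with K and is therefore
# reported but not used for selection.

#' Scan the number of HMM states
#'
#' Fits one HMM per value of `K` (with restarts) and records, for each, the
#' best final free energy and the median-FO summary of the winning fit
#' (median over states of the per-state median fractional occupancy
#' across subjects).  Failed fits are recorded and skipped.
#'
#' @inheritParams fit_hmm
#' @param K_range ascending vector of state counts (study default `4:45`).
#' @param keep_fits keep the fitted models in the result (memory heavy).
#' @return object of class `hmm_scan`: data.frame `records` with columns
#'   `K`, `free_energy`, `median_fo`, `seed`, `ok`, plus `fits` when
#'   requested.
#' @export
scan_states <- function(X, spans = NULL, K_range = 4:45, n_restarts = 5L,
                        max_iter = 500L, tol = 1e-6, seed = 1L,
                        keep_fits = FALSE) {
  if (length(K_range) == 0L || is.unsorted(K_range, strictly = TRUE))
    stopf("K_range must be non-empty and strictly ascending")
  records <- data.frame(K = as.integer(K_range), free_energy = NA_real_,
                        median_fo = NA_real_, seed = NA_integer_, ok = FALSE)
  fits <- if (keep_fits) vector("list", length(K_range)) else NULL
  for (i in seq_along(K_range)) {
    fit <- tryCatch(
      fit_hmm(X, spans, K = K_range[i], n_restarts = n_restarts,
              max_iter = max_iter, tol = tol, seed = seed),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warnf("K = %d failed: %s", K_range[i], conditionMessage(fit))
      next
    }
    fo <- vapply(fit$posterior, function(p)
      fractional_occupancy(p$path, fit$K), numeric(fit$K))
    fo <- matrix(fo, nrow = fit$K)          # K x subjects
    records$free_energy[i] <- tail(fit$free_energy_trace, 1)
    records$median_fo[i] <- median(apply(fo, 1, median))
    records$seed[i] <- fit$seed
    records$ok[i] <- TRUE
    if (keep_fits) fits[[i]] <- fit
  }
  structure(list(records = records, fits = fits), class = "hmm_scan")
}

#' Select the number of states from a scan
#'
#' Returns the smallest scanned `K` at which the relative decrease of
#' median fractional occupancy to the next scanned `K` falls below
#' `epsilon` (the FO curve "ceases" to drop).  Free energy is reported for
#' reference; when it is monotone decreasing over the scan it carries no
#' selection information and this is flagged.  When no plateau exists the
#' largest scanned `K` is returned with `warning = TRUE`.
#'
#' @param scan an [scan_states()] result (>= 3 successful K values).
#' @param epsilon relative-decrease threshold (default 0.05).
#' @return list with `K` (the selection), `warning` (no plateau found),
#'   `free_energy_monotone`, and the scan `records`.
#' @export
select_n_states <- function(scan, epsilon = 0.05) {
  stopifnot(inherits(scan, "hmm_scan"))
  rec <- scan$records[scan$records$ok, , drop = FALSE]
  if (nrow(rec) < 3L) stopf("need at least 3 successful scanned K values")
  fo <- rec$median_fo
  rel_drop <- (fo[-length(fo)] - fo[-1]) / pmax(fo[-length(fo)], 1e-300)
  hit <- which(rel_drop < epsilon)
  fe <- rec$free_energy
  fe_monotone <- all(diff(fe) <= abs(fe[-length(fe)]) * 1e-8)
  if (length(hit) == 0L) {
    warnf("no median-FO plateau found; returning largest scanned K = %d",
          rec$K[nrow(rec)])
    list(K = rec$K[nrow(rec)], warning = TRUE,
         free_energy_monotone = fe_monotone, records = rec)
  } else {
    list(K = rec$K[min(hit)], warning = FALSE,
         free_energy_monotone = fe_monotone, records = rec)
  }
}

#' ROI-space mean activation maps of the HMM states
#'
#' Back-projects each state's posterior mean vector from PCA space to ROI
#' space, giving one mean activation map per state in standardized (z)
#' ROI units.
#'
#' @param fit an [fit_hmm()] result with `P`-dimensional means.
#' @param transform the [fit_pca()] transform used before fitting.
#' @return `K x R` matrix; row `k` is state `k`'s activation map.
#' @export
state_maps <- function(fit, transform) {
  stopifnot(inherits(fit, "hmm_fit"), inherits(transform, "pca_transform"))
  if (fit$P != transform$P)
    stopf("fit has P = %d but transform has P = %d", fit$P, transform$P)
  maps <- pca_backproject(fit$means, transform)
  rownames(maps) <- paste0("state", seq_len(fit$K))
  maps
}
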