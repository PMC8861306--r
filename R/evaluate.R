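# Scoring a fitted model against a simulated cohort's stored ground
# truth.  Because the pipeline standardizes each channel, the planted
# state means are compared in standardized units: (mu_k - mbar) / s per
# channel, with mbar and s the pooled mean and SD of the raw cohort data.

#' Score state recovery against a synthetic cohort's ground truth
#'
#' Matches estimated states to planted states by exhaustive Hungarian-style
#' assignment on the ROI-space activation maps, then reports the per-state
#' Pearson correlation between matched mean maps, the hard-path accuracy
#' (fraction of timepoints whose relabeled hard state equals the true
#' state), and the mean absolute error of per-subject fractional
#' occupancies.
#'
#' @param fit an [fit_hmm()] result (fit on the standardized, projected
#'   cohort), with `fit$K` equal to the planted `K`.
#' @param cohort the [simulate_cohort()] result the fit was run on.
#' @param transform the [fit_pca()] transform used before fitting.
#' @return list with `perm` (planted state k matches estimated state
#'   `perm[k]`), `mean_correlations` (length `K`), `path_accuracy`,
#'   `fo_mae`, `true_means_std` (`K x R`).
#' @export
score_recovery <- function(fit, cohort, transform) {
  stopifnot(inherits(fit, "hmm_fit"), inherits(cohort, "cohort"))
  truth <- cohort$truth
  if (is.null(truth)) stopf("cohort carries no ground truth")
  K <- fit$K
  if (K != truth$n_states)
    stopf("fit has K = %d but truth has %d states", K, truth$n_states)
  raw <- do.call(rbind, lapply(cohort$subjects, `[[`, "data"))
  mu_std <- sweep(sweep(truth$roi_means, 2, colMeans(raw)), 2,
                  apply(raw, 2, sd), "/")
  maps <- state_maps(fit, transform)
  perm <- match_states(mu_std, maps)
  cors <- vapply(seq_len(K), function(k)
    cor(mu_std[k, ], maps[perm[k], ]), 0)

  acc <- vapply(seq_along(cohort$subjects), function(s) {
    true <- cohort$subjects[[s]]$true_path
    est <- fit$posterior[[s]]$path
    mean(match(est, perm) == true)
  }, 0)

  fo_err <- vapply(seq_along(cohort$subjects), function(s) {
    fo_true <- fractional_occupancy(cohort$subjects[[s]]$true_path, K)
    fo_est <- fractional_occupancy(fit$posterior[[s]]$path, K)[perm]
    mean(abs(fo_true - fo_est))
  }, 0)

  list(perm = perm, mean_correlations = cors,
       path_accuracy = mean(acc), fo_mae = mean(fo_err),
       true_means_std = mu_std)
}
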