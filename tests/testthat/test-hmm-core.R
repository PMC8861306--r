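test_that("a single-state model reduces to its closed form", {
  set.seed(6)
  X <- matrix(rnorm(200 * 4, mean = 2), 200, 4)
  spans <- data.frame(subject_id = c("a", "b"), start = c(1L, 101L),
                      end = c(100L, 200L))
  fit <- fit_hmm(X, spans, K = 1, n_restarts = 1, seed = 1)
  expect_equal(fit$transition, matrix(1, 1, 1), ignore_attr = TRUE)
  expect_true(all(fit$posterior$a$probs == 1))
  expect_lt(max(abs(fit$means[1, ] - colMeans(X))), 1e-6)
})

test_that("states, paths and occupancies are recovered on separated data", {
  cc <- small_cohort(seed = 51, n_per_group = 10, T_len = 200, R = 10,
                     K = 3, state_separation = 3)
  pr <- preprocess_cohort(cc$cohort)
  fit <- fit_hmm(pr$projected, pr$spans, K = 3, n_restarts = 3, seed = 2)
  sc <- score_recovery(fit, cc$cohort, pr$transform)
  expect_gte(mean(sc$mean_correlations), 0.95)
  expect_gte(sc$path_accuracy, 0.90)
  expect_lte(sc$fo_mae, 0.03)
})

test_that("free energy is non-increasing across iterations and seeds", {
  for (seed in 1:10) {
    cc <- small_cohort(seed = 60 + seed, n_per_group = 3, T_len = 60,
                       R = 6, K = 2)
    pr <- preprocess_cohort(cc$cohort)
    fit <- fit_hmm(pr$projected, pr$spans, K = 2, n_restarts = 1,
                   seed = seed)
    fe <- fit$free_energy_trace
    expect_true(all(diff(fe) <= 1e-8 * pmax(1, abs(fe[-length(fe)]))))
  }
})

test_that("near-zero-noise two-state data is decoded almost perfectly", {
  cc <- small_cohort(seed = 71, n_per_group = 4, T_len = 150, R = 6,
                     K = 2, state_separation = 20)
  pr <- preprocess_cohort(cc$cohort)
  fit <- fit_hmm(pr$projected, pr$spans, K = 2, n_restarts = 2, seed = 3)
  sc <- score_recovery(fit, cc$cohort, pr$transform)
  expect_gte(sc$path_accuracy, 0.99)
})

test_that("posterior rows and transition rows are simplex vectors", {
  cc <- small_cohort(seed = 81, n_per_group = 3, T_len = 50, R = 6, K = 3)
  pr <- preprocess_cohort(cc$cohort)
  fit <- fit_hmm(pr$projected, pr$spans, K = 3, n_restarts = 1, seed = 4)
  expect_equal(rowSums(fit$transition), rep(1, 3), tolerance = 1e-10)
  expect_true(all(fit$transition >= 0))
  for (p in fit$posterior) {
    expect_equal(rowSums(p$probs), rep(1, nrow(p$probs)), tolerance = 1e-10)
    expect_true(all(p$probs >= 0))
    expect_true(all(p$path >= 1 & p$path <= 3))
  }
})

test_that("free energy is invariant to permuting state labels", {
  cc <- small_cohort(seed = 91, n_per_group = 3, T_len = 60, R = 6, K = 3)
  pr <- preprocess_cohort(cc$cohort)
  fit <- fit_hmm(pr$projected, pr$spans, K = 3, n_restarts = 1, seed = 5)
  p <- fit$vb
  prior <- fit$prior
  fb <- brainstates:::vb_e_step(pr$projected, pr$spans, p)
  fe <- brainstates:::vb_free_energy(fb, p, prior)
  perm <- c(3L, 1L, 2L)
  pp <- p
  pp$alpha_init <- p$alpha_init[perm]
  pp$alpha_trans <- p$alpha_trans[perm, perm]
  pp$beta <- p$beta[perm]; pp$nu <- p$nu[perm]
  pp$m <- p$m[perm, , drop = FALSE]; pp$W <- p$W[perm]
  fbp <- brainstates:::vb_e_step(pr$projected, pr$spans, pp)
  fep <- brainstates:::vb_free_energy(fbp, pp, prior)
  expect_equal(fep, fe, tolerance = 1e-8)
})

test_that("hard assignment is the row-wise argmax with low-index ties", {
  expect_equal(hard_assign(matrix(c(0.2, 0.5, 0.3), 1)), 2L)
  expect_equal(hard_assign(matrix(c(0.5, 0.5), 1)), 1L)
  set.seed(14)
  P <- matrix(rexp(300 * 5), 300, 5)
  P <- P / rowSums(P)
  oracle <- apply(P, 1, function(r) which(r == max(r))[1])
  expect_equal(hard_assign(P), oracle, ignore_attr = TRUE)
  expect_error(hard_assign(matrix(c(0.3, 0.3), 1)), "sum to 1")
})

test_that("VB posterior means agree with an independent EM implementation", {
  # shared tiny dataset; reference is hmmlearn's maximum-likelihood EM
  cc <- small_cohort(seed = 23, n_per_group = 4, T_len = 150, R = 6,
                     K = 2, state_separation = 4)
  pr <- preprocess_cohort(cc$cohort, variance_target = 1)
  fit <- fit_hmm(pr$projected, pr$spans, K = 2, n_restarts = 3, seed = 6)
  dat <- tempfile(fileext = ".csv")
  write.table(pr$projected, dat, sep = ",", row.names = FALSE,
              col.names = FALSE)
  lens <- paste(pr$spans$end - pr$spans$start + 1L, collapse = ",")
  out <- tempfile(fileext = ".csv")
  script <- sprintf('
import numpy as np
from hmmlearn import hmm
X = np.loadtxt("%s", delimiter=",")
lengths = [%s]
m = hmm.GaussianHMM(n_components=2, covariance_type="full", n_iter=200,
                    random_state=0, tol=1e-6)
m.fit(X, lengths)
np.savetxt("%s", m.means_, delimiter=",")
', dat, lens, out)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  ref_means <- as.matrix(read.csv(out, header = FALSE))
  perm <- match_states(ref_means, fit$means)
  for (k in 1:2)
    expect_lt(sqrt(sum((ref_means[k, ] - fit$means[perm[k], ])^2)), 0.1)
})

test_that("state maps back-project exactly through an identity transform", {
  means <- matrix(rnorm(12), 3, 4)
  fit <- structure(list(K = 3L, P = 4L, means = means), class = "hmm_fit")
  id_tr <- structure(list(center = rep(0, 4), loadings = diag(4),
                          explained_variance_ratio = rep(0.25, 4), P = 4L),
                     class = "pca_transform")
  expect_equal(state_maps(fit, id_tr), means, ignore_attr = TRUE)
  fit0 <- structure(list(K = 1L, P = 4L, means = matrix(0, 1, 4)),
                    class = "hmm_fit")
  ctr_tr <- id_tr; ctr_tr$center <- c(1, 2, 3, 4)
  expect_equal(drop(state_maps(fit0, ctr_tr)), c(1, 2, 3, 4),
               ignore_attr = TRUE)
  expect_error(state_maps(structure(list(K = 1L, P = 3L), class = "hmm_fit"),
                          id_tr), "P = 3")
})

test_that("recovered maps match the planted sign pattern on strong loadings", {
  cc <- small_cohort(seed = 52, n_per_group = 8, T_len = 150, R = 10,
                     K = 3, state_separation = 4)
  pr <- preprocess_cohort(cc$cohort)
  fit <- fit_hmm(pr$projected, pr$spans, K = 3, n_restarts = 3, seed = 7)
  scr <- score_recovery(fit, cc$cohort, pr$transform)
  maps <- state_maps(fit, pr$transform)[scr$perm, , drop = FALSE]
  strong <- abs(scr$true_means_std) > 0.5
  agree <- sign(maps[strong]) == sign(scr$true_means_std[strong])
  expect_gte(mean(agree), 0.9)
})

test_that("scan records one row per K and the degenerate scan works", {
  cc <- small_cohort(seed = 53, n_per_group = 2, T_len = 60, R = 6, K = 2)
  pr <- preprocess_cohort(cc$cohort)
  sc <- scan_states(pr$projected, pr$spans, K_range = 1:3, n_restarts = 1,
                    seed = 8)
  expect_equal(sc$records$K, 1:3)
  expect_true(all(sc$records$ok))
  expect_equal(sc$records$median_fo[1], 1.0)
  expect_error(scan_states(pr$projected, pr$spans, K_range = c(3, 2)),
               "ascending")
})

test_that("the elbow rule follows its definition on synthetic scan curves", {
  mk <- function(K, fo) structure(
    list(records = data.frame(K = K, free_energy = -seq_along(K),
                              median_fo = fo, seed = 1L, ok = TRUE)),
    class = "hmm_scan")
  sel <- select_n_states(mk(2:6, c(0.30, 0.15, 0.10, 0.099, 0.098)))
  expect_equal(sel$K, 4L)
  expect_false(sel$warning)
  expect_true(sel$free_energy_monotone)
  # strict geometric decay: no plateau anywhere
  expect_warning(sel2 <- select_n_states(mk(2:8, 0.5 * 0.5^(0:6))),
                 "no median-FO plateau")
  expect_equal(sel2$K, 8L)
  expect_true(sel2$warning)
  expect_error(select_n_states(mk(2:3, c(0.5, 0.3))), "at least 3")
})
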