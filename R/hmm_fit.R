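# Variational Bayes inference for a Gaussian hidden Markov model on
# concatenated multi-subject data.  Conjugate priors: symmetric
# Dirichlet(alpha0) on the initial distribution and on each transition
# row, Normal-Wishart on each state's (mean, precision).  The "free
# energy" reported is the negative evidence lower bound (ELBO) of the
# structured variational posterior; VB-EM increases the ELBO at every
# sweep, so the trace is non-increasing.
#
# Forward-backward runs per subject (no transition bridges subject
# boundaries; each subject's chain restarts from the initial
# distribution); transition counts are pooled across subjects, giving a
# group-level model.

ln_b_wishart <- function(W, nu) {
  P <- nrow(W)
  -(nu / 2) * determinant(W, logarithm = TRUE)$modulus[1] -
    (nu * P / 2) * log(2) - (P * (P - 1) / 4) * log(pi) -
    sum(lgamma((nu + 1 - seq_len(P)) / 2))
}

e_logdet_lambda <- function(W, nu) {
  P <- nrow(W)
  sum(digamma((nu + 1 - seq_len(P)) / 2)) + P * log(2) +
    determinant(W, logarithm = TRUE)$modulus[1]
}

kl_dirichlet <- function(a, a0) {
  # KL( Dir(a) || Dir(a0) ), a0 scalar or vector
  a0 <- rep_len(a0, length(a))
  sum(lgamma(a0)) - lgamma(sum(a0)) - sum(lgamma(a)) + lgamma(sum(a)) +
    sum((a - a0) * (digamma(a) - digamma(sum(a))))
}

kl_normal_wishart <- function(m, beta, W, nu, m0, beta0, W0inv, lnB0, nu0) {
  P <- length(m)
  eld <- e_logdet_lambda(W, nu)
  dm <- m - m0
  e_q_mu <- 0.5 * (P * log(beta / (2 * pi)) + eld - P)
  e_p_mu <- 0.5 * (P * log(beta0 / (2 * pi)) + eld - P * beta0 / beta -
                     beta0 * nu * drop(t(dm) %*% W %*% dm))
  e_q_lam <- ln_b_wishart(W, nu) + 0.5 * (nu - P - 1) * eld - 0.5 * nu * P
  e_p_lam <- lnB0 + 0.5 * (nu0 - P - 1) * eld - 0.5 * nu * sum(W0inv * W)
  (e_q_mu + e_q_lam) - (e_p_mu + e_p_lam)
}

# Expected log Gaussian density rows under q(mu_k, Lambda_k).
expected_log_lik <- function(X, m, beta, W, nu) {
  P <- ncol(X)
  ch <- chol(W)                       # W = t(ch) %*% ch
  Y <- sweep(X, 2, m) %*% t(ch)
  maha <- rowSums(Y * Y)
  0.5 * (e_logdet_lambda(W, nu) - P * log(2 * pi) - P / beta - nu * maha)
}

safe_chol_inv <- function(M) {
  # inverse via Cholesky with escalating diagonal regularization
  P <- nrow(M)
  jit <- 0
  for (i in 0:8) {
    ch <- tryCatch(chol(M + diag(jit, P)), error = function(e) NULL)
    if (!is.null(ch)) return(chol2inv(ch))
    jit <- if (jit == 0) 1e-6 * sum(diag(M)) / P else jit * 10
  }
  stopf("covariance collapse: matrix not positive definite after regularization")
}

vb_m_step <- function(X, gamma, xi, first_gamma, prior) {
  K <- ncol(gamma); P <- ncol(X)
  Nk <- colSums(gamma)
  Nk_safe <- pmax(Nk, 1e-10)
  xbar <- t(gamma) %*% X / Nk_safe
  params <- list(
    alpha_init = prior$alpha0 + first_gamma,
    alpha_trans = prior$alpha0 + xi,
    beta = prior$beta0 + Nk,
    nu = prior$nu0 + Nk,
    m = matrix(0, K, P), W = vector("list", K), Nk = Nk)
  for (k in seq_len(K)) {
    d <- sweep(X, 2, xbar[k, ])
    Sk <- t(d * gamma[, k]) %*% d            # Nk * scatter about xbar
    dm <- xbar[k, ] - prior$m0
    Winv <- prior$W0inv + Sk +
      (prior$beta0 * Nk[k] / (prior$beta0 + Nk[k])) * tcrossprod(dm)
    Winv <- (Winv + t(Winv)) / 2
    params$W[[k]] <- safe_chol_inv(Winv)
    params$m[k, ] <- (prior$beta0 * prior$m0 + Nk[k] * xbar[k, ]) / params$beta[k]
  }
  params
}

vb_e_step <- function(X, spans, params) {
  K <- nrow(params$m)
  elog_init <- digamma(params$alpha_init) - digamma(sum(params$alpha_init))
  elog_trans <- digamma(params$alpha_trans) -
    matrix(digamma(rowSums(params$alpha_trans)), K, K)
  logB <- vapply(seq_len(K), function(k)
    expected_log_lik(X, params$m[k, ], params$beta[k], params$W[[k]],
                     params$nu[k]), numeric(nrow(X)))
  if (K == 1L) logB <- matrix(logB, ncol = 1L)
  .fb_cpp(logB, matrix(elog_trans, K, K), elog_init,
          as.integer(spans$start), as.integer(spans$end))
}

vb_free_energy <- function(fb, params, prior) {
  K <- nrow(params$m)
  kl <- kl_dirichlet(params$alpha_init, prior$alpha0)
  for (k in seq_len(K)) {
    kl <- kl + kl_dirichlet(params$alpha_trans[k, ], prior$alpha0)
    kl <- kl + kl_normal_wishart(params$m[k, ], params$beta[k], params$W[[k]],
                                 params$nu[k], prior$m0, prior$beta0,
                                 prior$W0inv, prior$lnB0, prior$nu0)
  }
  -(fb$logZ - kl)                      # free energy = -ELBO
}

vb_init_gamma <- function(X, spans, K, seed) {
  # soft-ish responsibilities from k-means on a random subsample
  n <- nrow(X)
  if (K == 1L) return(matrix(1, n, 1L))
  with_seed(seed, {
    idx <- sample.int(n, min(n, max(20L * K, 2000L)))
    km <- suppressWarnings(
      kmeans(X[idx, , drop = FALSE], centers = K, nstart = 3, iter.max = 50))
    d2 <- vapply(seq_len(K), function(k)
      rowSums(sweep(X, 2, km$centers[k, ])^2), numeric(n))
    g <- exp(-0.5 * (d2 - apply(d2, 1, min)))
    g <- g / rowSums(g)
    0.9 * g + 0.1 / K
  })
}

gamma_to_counts <- function(gamma, spans) {
  # plug-in sufficient statistics for initializing the first M-step:
  # product approximation for xi, exact first-timepoint gamma
  K <- ncol(gamma)
  first <- colSums(gamma[spans$start, , drop = FALSE])
  xi <- matrix(0, K, K)
  for (s in seq_len(nrow(spans))) {
    rows <- spans$start[s]:spans$end[s]
    if (length(rows) > 1) {
      g <- gamma[rows, , drop = FALSE]
      xi <- xi + t(g[-nrow(g), , drop = FALSE]) %*% g[-1, , drop = FALSE]
    }
  }
  list(first = first, xi = xi)
}

vb_run_once <- function(X, spans, K, max_iter, tol, seed, prior) {
  gamma0 <- vb_init_gamma(X, spans, K, seed)
  cnt <- gamma_to_counts(gamma0, spans)
  params <- vb_m_step(X, gamma0, cnt$xi, cnt$first, prior)
  trace <- numeric(0)
  fb <- NULL
  for (it in seq_len(max_iter)) {
    fb <- vb_e_step(X, spans, params)
    fe <- vb_free_energy(fb, params, prior)
    trace <- c(trace, fe)
    if (it > 1) {
      rel <- abs(trace[it] - trace[it - 1]) / max(1, abs(trace[it - 1]))
      if (rel < tol) break
    }
    params <- vb_m_step(X, fb$gamma, fb$xi, fb$first_gamma, prior)
  }
  list(params = params, fb = fb, trace = trace)
}

#' Fit a variational Bayes Gaussian HMM
#'
#' Infers a `K`-state HMM with multivariate Gaussian emissions on stacked
#' (typically PCA-projected) cohort data.  Multiple random restarts are
#' run and the one with the lowest final free energy (highest evidence
#' bound) is returned.  The chain never bridges subject boundaries: the
#' forward-backward recursions restart from the initial distribution at
#' each subject's first timepoint, while transition pseudo-counts are
#' pooled across subjects (group-level model).
#'
#' @param X `(sum T) x P` numeric matrix of stacked observations.
#' @param spans data.frame with `subject_id`, `start`, `end` (1-based,
#'   inclusive) partitioning the rows of `X`; a single span covering all
#'   rows is assumed when omitted.
#' @param K number of states (>= 1).
#' @param n_restarts random restarts (k-means initialization each).
#' @param max_iter maximum VB sweeps per restart.
#' @param tol relative free-energy change declaring convergence.
#' @param seed integer seed; restart `r` uses stream `seed + 131 * (r-1)`.
#' @param prior optional overrides: `alpha0` (Dirichlet weight, default 1),
#'   `beta0` (mean shrinkage, default 1e-3), `nu0` (Wishart dof, default
#'   `P + 2`), `m0`, `W0inv`.
#' @return object of class `hmm_fit` with elements `K`, `means` (`K x P`
#'   posterior mean vectors), `covariances` (list of `K` posterior-mean
#'   covariance matrices `W^{-1}/(nu-P-1)` fallback `W^{-1}/nu`),
#'   `transition` (posterior-mean row-stochastic matrix), `initial`,
#'   `free_energy_trace`, `seed` (of the winning restart), `posterior`
#'   (list per subject: `probs` `T x K`, `path`), `spans`, `log_evidence`,
#'   `restart_traces` (free-energy trace of every successful restart),
#'   `vb`/`prior` (the variational posterior and prior hyperparameters).
#' @export
fit_hmm <- function(X, spans = NULL, K, n_restarts = 5L, max_iter = 500L,
                    tol = 1e-6, seed = 1L, prior = list()) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (!all(is.finite(X))) stopf("X must be finite")
  if (!is_count(K)) stopf("K must be a positive integer")
  if (is.null(spans))
    spans <- data.frame(subject_id = "all", start = 1L, end = nrow(X))
  if (spans$start[1] != 1L || spans$end[nrow(spans)] != nrow(X) ||
      (nrow(spans) > 1 && any(spans$start[-1] != head(spans$end, -1) + 1L)))
    stopf("spans must partition the rows of X")
  P <- ncol(X)

  defaults <- list(alpha0 = 1, beta0 = 1e-3, nu0 = P + 2,
                   m0 = colMeans(X),
                   W0inv = diag(pmax(apply(X, 2, var), 1e-12) * (P + 2), P))
  prior <- modify_list(defaults, prior)
  prior$lnB0 <- ln_b_wishart(safe_chol_inv(prior$W0inv), prior$nu0)

  best <- NULL
  errors <- character(0)
  restart_traces <- list()
  for (r in seq_len(n_restarts)) {
    run <- tryCatch(
      vb_run_once(X, spans, K, max_iter, tol, seed + 131L * (r - 1L), prior),
      error = function(e) e)
    if (inherits(run, "error")) {
      errors <- c(errors, conditionMessage(run))
      next
    }
    run$seed <- seed + 131L * (r - 1L)
    restart_traces[[length(restart_traces) + 1L]] <- run$trace
    if (is.null(best) || tail(run$trace, 1) < tail(best$trace, 1)) best <- run
  }
  if (is.null(best))
    stopf("all %d restarts failed: %s", n_restarts, errors[1])

  p <- best$params
  trans <- p$alpha_trans / rowSums(p$alpha_trans)
  init <- p$alpha_init / sum(p$alpha_init)
  covs <- lapply(seq_len(K), function(k) {
    denom <- p$nu[k] - P - 1
    if (denom <= 0) denom <- p$nu[k]
    S <- safe_chol_inv(p$W[[k]]) / denom
    (S + t(S)) / 2
  })

  posterior <- lapply(seq_len(nrow(spans)), function(s) {
    rows <- spans$start[s]:spans$end[s]
    probs <- best$fb$gamma[rows, , drop = FALSE]
    list(subject_id = spans$subject_id[s], probs = probs,
         path = hard_assign(probs))
  })
  names(posterior) <- spans$subject_id

  structure(list(K = as.integer(K), means = p$m,
                 covariances = covs, transition = trans, initial = init,
                 free_energy_trace = best$trace, seed = best$seed,
                 posterior = posterior, spans = spans,
                 log_evidence = -tail(best$trace, 1), P = P,
                 vb = p, prior = prior, restart_traces = restart_traces),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("Variational Bayes Gaussian HMM: K = %d states, P = %d dims\n",
              x$K, x$P))
  cat(sprintf("  %d subjects, final free energy %.2f (%d iterations)\n",
              length(x$posterior), tail(x$free_energy_trace, 1),
              length(x$free_energy_trace)))
  invisible(x)
}

#' Hard state assignment from posterior probabilities
#'
#' Argmax over states per timepoint; ties break toward the lowest state
#' index.
#'
#' @param probs `T x K` matrix of per-timepoint state probabilities.
#' @return integer vector of state ids in `1..K`.
#' @export
hard_assign <- function(probs) {
  stopifnot(is.matrix(probs))
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stopf("posterior rows must sum to 1")
  max.col(probs, ties.method = "first")
}
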