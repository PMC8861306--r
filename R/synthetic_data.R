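# Synthetic multi-subject cohorts drawn from a known Gaussian hidden
# Markov model: planted state means, block-structured transition matrix
# (communities), and a group effect expressed purely through the
# transition dynamics so both groups share state identities.

#' Configuration of a synthetic cohort
#'
#' Collects every knob of the generative model: cohort dimensions, the
#' hidden-chain geometry (number of states, planted transition modules,
#' persistence), the separation of the state mean-activation vectors in
#' units of the observation noise SD, the planted group effect (an absolute
#' shift in stationary fractional occupancy of one state for the case
#' group), and nuisance covariates (age, FIQ, mean framewise displacement,
#' site, with optional linear leakage of age into the dynamics).
#'
#' @param n_per_group subjects per group (length-2 `c(case, control)` or a
#'   single count used for both).
#' @param T_len timepoints per subject (>= 2).
#' @param R number of regions of interest (>= 2).
#' @param K number of hidden states (>= 1).
#' @param n_modules planted transition communities (1 = no block structure).
#' @param state_separation minimum pairwise Euclidean distance between state
#'   means, in units of `noise_scale` (i.e. SD units).
#' @param noise_scale observation noise SD (> 0).
#' @param cov_type `"isotropic"` (default, `noise_scale^2 * I`) or `"full"`
#'   (randomly rotated anisotropic covariance per state).
#' @param stay_prob self-transition probability of every state.
#' @param within_frac fraction of each row's off-diagonal transition mass
#'   assigned to same-module states (must exceed module share for planted
#'   blocks to be detectable).
#' @param effect_state state (1-based) whose occupancy differs between
#'   groups; `0` disables the group effect.
#' @param effect_delta target absolute increase in the case group's
#'   stationary fractional occupancy of `effect_state`.  The default
#'   `NULL` calibrates it to `effect_size_sd` between-subject standard
#'   deviations of that state's fractional occupancy (exact asymptotic
#'   SD over a length-`T_len` path, pooled over the two groups'
#'   chains by a self-consistent iteration).
#' @param effect_size_sd planted effect size in between-subject FO SD
#'   units, used when `effect_delta` is `NULL`.
#' @param n_sites number of acquisition sites.
#' @param site_offset_sd SD of a per-site additive mean offset on every
#'   channel (0 = none).
#' @param age_leakage per-subject tilt of occupancy toward `effect_state`
#'   per SD of age (0 = none); models covariate leakage into the metrics.
#' @param seed integer seed; all randomness in the generator fans out from
#'   it deterministically (subject s uses stream `seed + 1009 * s`).
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_per_group = c(30L, 30L), T_len = 150L, R = 20L,
                          K = 4L, n_modules = 2L, state_separation = 3,
                          noise_scale = 1, cov_type = c("isotropic", "full"),
                          stay_prob = 0.7, within_frac = 0.75,
                          effect_state = 1L, effect_delta = NULL,
                          effect_size_sd = 1,
                          n_sites = 3L, site_offset_sd = 0,
                          age_leakage = 0, seed = 1L) {
  cov_type <- match.arg(cov_type)
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  if (!all(vapply(n_per_group, is_count, TRUE)))
    stopf("n_per_group must be positive counts")
  if (!is_count(T_len, 2L)) stopf("T_len must be an integer >= 2")
  if (!is_count(R, 2L)) stopf("R must be an integer >= 2")
  if (!is_count(K)) stopf("K must be a positive integer")
  if (!is_count(n_modules) || n_modules > K)
    stopf("n_modules must be a count <= K")
  if (!(noise_scale > 0)) stopf("noise_scale must be > 0")
  if (stay_prob < 0 || stay_prob >= 1) stopf("stay_prob must be in [0, 1)")
  if (within_frac <= 0 || within_frac >= 1) stopf("within_frac in (0,1)")
  if (effect_state < 0 || effect_state > K)
    stopf("effect_state must be 0 (off) or a state index in 1..K")
  if (K > R) warnf("K = %d states exceed R = %d regions; state means may not be linearly separable", K, R)
  structure(list(
    n_per_group = as.integer(n_per_group), T_len = as.integer(T_len),
    R = as.integer(R), K = as.integer(K), n_modules = as.integer(n_modules),
    state_separation = state_separation, noise_scale = noise_scale,
    cov_type = cov_type, stay_prob = stay_prob, within_frac = within_frac,
    effect_state = as.integer(effect_state), effect_delta = effect_delta,
    effect_size_sd = effect_size_sd,
    n_sites = as.integer(n_sites), site_offset_sd = site_offset_sd,
    age_leakage = age_leakage, seed = as.integer(seed)),
    class = "cohort_config")
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
stationary_dist <- function(A) {
  e <- eigen(t(A))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- abs(v)
  v / sum(v)
}

# Exact asymptotic SD of the fractional occupancy of `state` over a
# length-T stationary path of the chain A:
#   var(FO) = [pi(1-pi) + 2 * sum_k (1 - k/T) (pi (A^k)_ss - pi^2)] / T
fo_asymptotic_sd <- function(A, state, T_len) {
  p <- stationary_dist(A)
  ps <- p[state]
  acc <- 0
  M <- A
  for (k in seq_len(T_len - 1)) {
    term <- ps * M[state, state] - ps^2
    acc <- acc + (1 - k / T_len) * term
    if (abs(term) < 1e-14) break
    M <- M %*% A
  }
  sqrt((ps * (1 - ps) + 2 * acc) / T_len)
}

# Rescale a transition matrix so its stationary distribution equals
# `target` exactly, staying as close as possible to the original
# dynamics: columns are exponentially tilted (M = rownorm(A diag(c)))
# and the scaling c is found by a damped multiplicative fixed point.
# Column scaling preserves the planted block structure (within- and
# between-module entries of a row are scaled by the same state factors).
adjust_stationary <- function(A, target, tol = 1e-12, max_iter = 10000) {
  check_simplex(target, what = "target stationary distribution")
  if (any(target <= 0)) stopf("target stationary entries must be positive")
  ccol <- rep(1, nrow(A))
  for (i in seq_len(max_iter)) {
    M <- A * rep(ccol, each = nrow(A))
    M <- M / rowSums(M)
    p <- stationary_dist(M)
    if (max(abs(p - target)) < tol) return(M)
    ccol <- ccol * (target / p)^0.7
  }
  warnf("stationary adjustment stopped at %.2e after %d iterations",
        max(abs(p - target)), max_iter)
  M
}

# Group-effect tilt: raise the stationary occupancy of `state` by `delta`,
# funding it proportionally from `donors` only, so non-donor states keep
# their occupancy exactly and remain valid nulls in group comparisons.
tilt_transitions <- function(A, state, delta,
                             donors = setdiff(seq_len(nrow(A)), state)) {
  if (delta == 0) return(A)
  p <- stationary_dist(A)
  if (p[state] + delta >= 1 || p[state] + delta <= 0)
    stopf("effect_delta %.3f pushes occupancy of state %d outside (0,1)", delta, state)
  if (sum(p[donors]) <= delta)
    stopf("donor states carry too little occupancy to fund effect_delta %.3f", delta)
  target <- p
  target[state] <- p[state] + delta
  target[donors] <- p[donors] * (1 - delta / sum(p[donors]))
  adjust_stationary(A, target)
}

#' Construct the ground-truth generative model for a synthetic cohort
#'
#' Builds `K` state mean-activation vectors separated by at least
#' `state_separation * noise_scale` in Euclidean norm, state covariances,
#' a row-stochastic transition matrix with planted block (community)
#' structure in which within-module off-diagonal mass is at least twice the
#' between-module mass, a uniform initial distribution, and per-group
#' transition matrices that differ only by a tilt raising the case group's
#' occupancy of `effect_state` by `effect_delta`.
#'
#' @param config a [cohort_config()].
#' @return an object of class `ground_truth` with elements `n_states`,
#'   `roi_means` (`K x R`), `roi_covs` (list of `R x R`), `trans_by_group`
#'   (named list `case`/`control`), `initial_dist`, `community_labels`.
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  K <- config$K; R <- config$R
  with_seed(config$seed, {
    mu <- matrix(rnorm(K * R), K, R)
    if (K > 1) {
      dmin <- min(dist(mu))
      mu <- mu * (config$state_separation * config$noise_scale / dmin)
    } else mu <- mu * 0
    rownames(mu) <- paste0("state", seq_len(K))
    colnames(mu) <- paste0("ROI", seq_len(R))

    covs <- lapply(seq_len(K), function(k) {
      if (config$cov_type == "isotropic") {
        diag(config$noise_scale^2, R)
      } else {
        # random rotation of a mildly anisotropic spectrum
        Qr <- qr.Q(qr(matrix(rnorm(R * R), R, R)))
        lam <- config$noise_scale^2 * exp(runif(R, -0.5, 0.5))
        S <- Qr %*% diag(lam) %*% t(Qr)
        (S + t(S)) / 2
      }
    })

    labels <- sort(rep_len(seq_len(config$n_modules), K))
    A <- matrix(0, K, K)
    for (i in seq_len(K)) {
      off <- 1 - config$stay_prob
      same <- which(labels == labels[i] & seq_len(K) != i)
      other <- which(labels != labels[i])
      if (length(same) == 0L) {
        if (length(other)) A[i, other] <- off / length(other)
      } else if (length(other) == 0L) {
        A[i, same] <- off / length(same)
      } else {
        A[i, same] <- off * config$within_frac / length(same)
        A[i, other] <- off * (1 - config$within_frac) / length(other)
      }
      A[i, i] <- 1 - sum(A[i, -i])
    }
    check_row_stochastic(A)

    donors <- if (config$effect_state > 0) {
      other <- which(labels != labels[config$effect_state])
      if (length(other)) other else setdiff(seq_len(K), config$effect_state)
    } else integer(0)
    case_A <- A
    if (config$effect_state > 0 && K > 1) {
      s <- config$effect_state
      delta <- config$effect_delta
      if (is.null(delta)) {
        # calibrate to effect_size_sd pooled between-subject FO SDs;
        # the case chain's SD depends on delta, so iterate to a fixed point
        delta <- config$effect_size_sd * fo_asymptotic_sd(A, s, config$T_len)
        for (i in 1:3) {
          cand <- tilt_transitions(A, s, delta, donors = donors)
          pooled <- sqrt((fo_asymptotic_sd(A, s, config$T_len)^2 +
                            fo_asymptotic_sd(cand, s, config$T_len)^2) / 2)
          delta <- config$effect_size_sd * pooled
        }
      }
      case_A <- tilt_transitions(A, s, delta, donors = donors)
    }
    trans <- list(control = A, case = case_A)

    structure(list(n_states = K, roi_means = mu, roi_covs = covs,
                   trans_by_group = trans,
                   initial_dist = rep(1 / K, K),
                   community_labels = labels),
              class = "ground_truth")
  })
}

sample_markov_path <- function(T_len, init, A) {
  K <- length(init)
  path <- integer(T_len)
  path[1] <- sample.int(K, 1L, prob = init)
  if (T_len > 1) {
    u <- runif(T_len - 1L)
    cum <- t(apply(A, 1, cumsum))
    for (t in 2:T_len)
      path[t] <- findInterval(u[t - 1L], cum[path[t - 1L], ]) + 1L
  }
  path
}

#' Simulate a cohort from a ground-truth model
#'
#' Each subject's hidden path is sampled from its group's transition matrix
#' and observations from the state-conditional Gaussians.  True hidden
#' paths are retained so that downstream recovery can be scored.  Subject
#' streams are derived from the global seed by a fixed counter scheme, so
#' cohorts are reproducible subject-by-subject.
#'
#' @param truth a [make_ground_truth()] result.
#' @param config the matching [cohort_config()].
#' @return an object of class `cohort`: list with `subjects` (each holding
#'   `subject_id`, `group`, `site`, `age`, `fiq`, `mean_fd`, `data`
#'   `T x R`, `true_path`), `manifest` (data.frame) and `truth`.
#' @export
simulate_cohort <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "cohort_config"))
  if (truth$n_states != config$K || ncol(truth$roi_means) != config$R)
    stopf("truth and config disagree on K or R")
  K <- config$K; R <- config$R; T_len <- config$T_len
  n <- config$n_per_group
  groups <- rep(c("case", "control"), n)
  ids <- sprintf("sub-%03d", seq_along(groups))
  chol_covs <- lapply(truth$roi_covs, chol)

  site_offsets <- with_seed(config$seed + 7L,
    matrix(rnorm(config$n_sites * R, sd = config$site_offset_sd),
           config$n_sites, R))

  subjects <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    subjects[[s]] <- with_seed(config$seed + 1009L * s, {
      site <- ((s - 1L) %% config$n_sites) + 1L
      age <- round(rnorm(1, 15, 4), 1)
      fiq <- round(rnorm(1, 110, 12), 1)
      fd <- round(abs(rnorm(1, 0.14, 0.08)) + 0.02, 3)
      A <- truth$trans_by_group[[groups[s]]]
      if (config$age_leakage != 0 && config$effect_state > 0) {
        tilt <- config$age_leakage * (age - 15) / 4
        tilt <- max(min(tilt, 0.2), -0.2)
        A <- tilt_transitions(A, config$effect_state, tilt)
      }
      path <- sample_markov_path(T_len, truth$initial_dist, A)
      X <- matrix(rnorm(T_len * R), T_len, R)
      for (k in unique(path)) {
        idx <- which(path == k)
        X[idx, ] <- X[idx, , drop = FALSE] %*% chol_covs[[k]] +
          matrix(truth$roi_means[k, ], length(idx), R, byrow = TRUE)
      }
      X <- X + matrix(site_offsets[site, ], T_len, R, byrow = TRUE)
      colnames(X) <- colnames(truth$roi_means)
      list(subject_id = ids[s], group = groups[s],
           site = paste0("site", site), age = age, fiq = fiq,
           mean_fd = fd, data = X, true_path = path)
    })
  }
  manifest <- data.frame(
    subject_id = ids, group = groups,
    site = vapply(subjects, `[[`, "", "site"),
    age = vapply(subjects, `[[`, 0, "age"),
    fiq = vapply(subjects, `[[`, 0, "fiq"),
    mean_fd = vapply(subjects, `[[`, 0, "mean_fd"),
    path = NA_character_, stringsAsFactors = FALSE)
  structure(list(subjects = subjects, manifest = manifest, truth = truth,
                 config = config), class = "cohort")
}

#' Write a simulated cohort to disk
#'
#' One TSV per subject (`T` rows x `R` columns, ROI labels as header), a
#' cohort manifest TSV and a JSON ground-truth file.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    f <- file.path(dir, paste0(s$subject_id, ".tsv"))
    write_series(s$data, f)
  }
  man <- cohort$manifest
  man$path <- paste0(man$subject_id, ".tsv")
  man_path <- file.path(dir, "manifest.tsv")
  write.table(man, man_path, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(
    list(n_states = tr$n_states, roi_means = tr$roi_means,
         trans_by_group = tr$trans_by_group, initial_dist = tr$initial_dist,
         community_labels = tr$community_labels,
         true_paths = setNames(lapply(cohort$subjects, `[[`, "true_path"),
                               vapply(cohort$subjects, `[[`, "", "subject_id"))),
    file.path(dir, "ground_truth.json"), digits = NA, matrix = "rowmajor")
  invisible(man_path)
}
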