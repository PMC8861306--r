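# Shared fixture builders.  Everything is generated in code at test time.

# A small simulated cohort plus its preprocessing, for tests that need a
# realistic multi-subject dataset quickly.
small_cohort <- function(seed = 1, n_per_group = 6, T_len = 80, R = 10,
                         K = 3, n_modules = 1, state_separation = 3,
                         effect_state = 0, effect_delta = 0.08, ...) {
  cfg <- cohort_config(n_per_group = n_per_group, T_len = T_len, R = R,
                       K = K, n_modules = n_modules,
                       state_separation = state_separation,
                       effect_state = effect_state,
                       effect_delta = effect_delta, seed = seed, ...)
  truth <- make_ground_truth(cfg)
  list(config = cfg, truth = truth,
       cohort = simulate_cohort(truth, cfg))
}

# Independent run-length-encoding oracle: a hand loop, deliberately not
# using rle() (which the implementation uses).
rle_oracle <- function(path, K) {
  runs_val <- integer(0); runs_len <- integer(0)
  cur <- path[1]; len <- 1L
  for (t in seq_along(path)[-1]) {
    if (path[t] == cur) len <- len + 1L
    else {
      runs_val <- c(runs_val, cur); runs_len <- c(runs_len, len)
      cur <- path[t]; len <- 1L
    }
  }
  runs_val <- c(runs_val, cur); runs_len <- c(runs_len, len)
  ends <- cumsum(runs_len)
  starts <- ends - runs_len + 1L
  fo <- sapply(seq_len(K), function(k) sum(runs_len[runs_val == k])) / length(path)
  lifetimes <- lapply(seq_len(K), function(k) runs_len[runs_val == k])
  intervals <- lapply(seq_len(K), function(k) {
    i <- which(runs_val == k)
    if (length(i) < 2L) integer(0)
    else sapply(seq_along(i)[-1], function(j) starts[i[j]] - ends[i[j - 1]] - 1L)
  })
  list(fo = fo, lifetimes = lifetimes, intervals = intervals)
}

# Exhaustive modularity maximum over all partitions of n nodes
# (set-partition enumeration; n <= 8 keeps this in the thousands).
all_set_partitions <- function(n) {
  parts <- list(rep(1L, 1L))
  for (i in seq_len(n)[-1]) {
    new <- list()
    for (p in parts) {
      m <- max(p)
      for (g in seq_len(m + 1L)) new[[length(new) + 1L]] <- c(p, g)
    }
    parts <- new
  }
  parts
}

exhaustive_best_q <- function(A) {
  parts <- all_set_partitions(nrow(A))
  best <- -Inf
  for (p in parts) {
    q <- modularity_q(A, p)
    if (q > best) best <- q
  }
  best
}

# Random directed weighted graph with zero diagonal.
random_digraph <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  A <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < density)
  diag(A) <- 0
  if (sum(A) == 0) A[1, 2] <- 1
  A
}
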