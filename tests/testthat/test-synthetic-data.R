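test_that("ground truth satisfies its structural invariants", {
  cfg <- cohort_config(n_per_group = 4, T_len = 50, R = 12, K = 4,
                       n_modules = 2, seed = 7)
  gt <- make_ground_truth(cfg)
  for (A in gt$trans_by_group) {
    expect_true(all(A >= 0))
    expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-12)
  }
  expect_equal(sum(gt$initial_dist), 1, tolerance = 1e-12)
  expect_true(all(table(gt$community_labels) >= 1))
  expect_length(unique(gt$community_labels), 2)
  for (S in gt$roi_covs) {
    expect_equal(S, t(S))
    expect_true(all(eigen(S, only.values = TRUE)$values > 0))
  }
  # separation: minimum pairwise distance equals the requested separation
  expect_equal(min(dist(gt$roi_means)),
               cfg$state_separation * cfg$noise_scale, tolerance = 1e-10)
})

test_that("single-state chain degenerates to the identity", {
  cfg <- cohort_config(n_per_group = 2, T_len = 20, R = 5, K = 1,
                       n_modules = 1, effect_state = 0, seed = 1)
  gt <- make_ground_truth(cfg)
  expect_equal(gt$trans_by_group$control, matrix(1, 1, 1))
  expect_equal(gt$community_labels, 1L)
})

test_that("planted modules concentrate off-diagonal transition mass within blocks", {
  cfg <- cohort_config(n_per_group = 2, T_len = 20, R = 10, K = 4,
                       n_modules = 2, seed = 3)
  gt <- make_ground_truth(cfg)
  A <- gt$trans_by_group$control
  lab <- gt$community_labels
  off <- row(A) != col(A)
  within <- sum(A[off & outer(lab, lab, `==`)])
  between <- sum(A[off & outer(lab, lab, `!=`)])
  expect_gte(within, 2 * between)
})

test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_per_group = 3, T_len = 30, R = 6, K = 2, seed = 42)
  gt1 <- make_ground_truth(cfg); gt2 <- make_ground_truth(cfg)
  expect_identical(gt1, gt2)
  co1 <- simulate_cohort(gt1, cfg); co2 <- simulate_cohort(gt2, cfg)
  expect_identical(co1$subjects, co2$subjects)
})

test_that("zero-noise observations sit on their emitting state's mean", {
  cfg <- cohort_config(n_per_group = 2, T_len = 40, R = 8, K = 2,
                       state_separation = 5, noise_scale = 1e-8, seed = 5)
  gt <- make_ground_truth(cfg)
  co <- simulate_cohort(gt, cfg)
  for (s in co$subjects) {
    d <- as.matrix(dist(rbind(gt$roi_means, s$data)))[-(1:2), 1:2]
    nearest <- apply(d, 1, which.min)
    expect_equal(nearest, s$true_path, ignore_attr = TRUE)
  }
})

test_that("empirical transition frequencies match the generating chain", {
  # one long chain ~ 50,000 transitions, counted directly
  cfg <- cohort_config(n_per_group = 1, T_len = 25001, R = 4, K = 3,
                       n_modules = 1, effect_state = 0, seed = 9)
  gt <- make_ground_truth(cfg)
  co <- simulate_cohort(gt, cfg)
  counts <- matrix(0, 3, 3)
  for (s in co$subjects) {
    p <- s$true_path
    for (t in seq_along(p)[-1]) counts[p[t - 1], p[t]] <- counts[p[t - 1], p[t]] + 1
  }
  emp <- counts / rowSums(counts)
  expect_lt(max(abs(emp - gt$trans_by_group$control)), 0.02)
})

test_that("hidden paths re-estimated by counting recover the chain within 3 SE", {
  cc <- small_cohort(seed = 21, n_per_group = 10, T_len = 200, K = 3,
                     R = 8)
  A <- cc$truth$trans_by_group$control
  counts <- matrix(0, 3, 3)
  ctrl <- Filter(function(s) s$group == "control", cc$cohort$subjects)
  for (s in ctrl) {
    p <- s$true_path
    for (t in seq_along(p)[-1]) counts[p[t - 1], p[t]] <- counts[p[t - 1], p[t]] + 1
  }
  n_row <- rowSums(counts)
  emp <- counts / n_row
  se <- sqrt(A * (1 - A) / n_row)
  expect_true(all(abs(emp - A) <= 3 * se + 1e-12))
})

test_that("the planted group effect has the designed sign in true occupancy", {
  hits <- vapply(1:20, function(seed) {
    cfg <- cohort_config(n_per_group = 15, T_len = 150, R = 6, K = 3,
                         n_modules = 1, effect_state = 2,
                         effect_delta = 0.08, seed = 300 + seed)
    co <- simulate_cohort(make_ground_truth(cfg), cfg)
    fo <- vapply(co$subjects, function(s)
      fractional_occupancy(s$true_path, 3)[2], 0)
    grp <- vapply(co$subjects, `[[`, "", "group")
    mean(fo[grp == "case"]) > mean(fo[grp == "control"])
  }, TRUE)
  expect_gte(sum(hits), 19)
})

test_that("per-state observation means converge to the planted means", {
  cc <- small_cohort(seed = 4, n_per_group = 8, T_len = 400, K = 3, R = 6)
  X <- do.call(rbind, lapply(cc$cohort$subjects, `[[`, "data"))
  path <- unlist(lapply(cc$cohort$subjects, `[[`, "true_path"))
  for (k in 1:3) {
    n_k <- sum(path == k)
    err <- colMeans(X[path == k, , drop = FALSE]) - cc$truth$roi_means[k, ]
    expect_lt(max(abs(err)), 5 * cc$config$noise_scale / sqrt(n_k))
  }
})

test_that("invalid configurations are rejected and K > R warns", {
  expect_error(cohort_config(T_len = 1), "T_len")
  expect_error(cohort_config(noise_scale = 0), "noise_scale")
  expect_error(cohort_config(n_modules = 5, K = 3), "n_modules")
  expect_warning(cohort_config(K = 6, R = 4, n_modules = 1), "separable")
})

test_that("written cohorts round-trip through the manifest reader", {
  cc <- small_cohort(seed = 8, n_per_group = 2, T_len = 25, R = 5)
  dir <- tempfile("cohort_")
  write_cohort(cc$cohort, dir)
  loaded <- load_cohort(file.path(dir, "manifest.tsv"))
  expect_length(loaded$subjects, 4)
  expect_equal(loaded$subjects[[1]]$data, cc$cohort$subjects[[1]]$data,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(loaded$manifest$age, cc$cohort$manifest$age)
})
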