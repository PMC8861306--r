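test_that("pooled t-test reproduces the textbook formula and t.test", {
  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.0214, tolerance = 1e-2)
  # dual route: agrees with stats::t.test(var.equal = TRUE) to 1e-12
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1)); y <- rnorm(sample(3:30, 1), mean = 0.3)
    ours <- two_sample_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    w <- two_sample_t(x, y, welch = TRUE)
    refw <- t.test(x, y)
    expect_equal(w$t, unname(refw$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(refw$parameter), tolerance = 1e-9)
  }
})

test_that("degenerate t-test inputs are handled", {
  tt <- two_sample_t(c(2, 2, 3, 3), c(2, 3, 2, 3))
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_error(two_sample_t(rep(1, 5), rep(1, 4)), "zero pooled variance")
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("regress_out produces residuals orthogonal to the design", {
  set.seed(10)
  n <- 200
  tab <- data.frame(age = rnorm(n, 15, 4),
                    site = sample(c("a", "b", "c"), n, replace = TRUE),
                    fiq = rnorm(n, 110, 10))
  vals <- 0.3 * tab$age + rnorm(n)
  adj <- regress_out(vals, tab, c("age", "site", "fiq"))
  X <- model.matrix(~ age + site + fiq, tab)
  expect_lt(max(abs(crossprod(X, adj))), 1e-8)
  # values exactly linear in age -> all-zero residuals
  adj0 <- regress_out(5 + 2 * tab$age, tab, "age")
  expect_lt(max(abs(adj0)), 1e-10)
  # empty covariate set -> centered values
  expect_equal(regress_out(vals, tab, character(0)), vals - mean(vals))
})

test_that("regressing an unrelated covariate leaves the signal intact", {
  set.seed(11)
  n <- 1e4
  tab <- data.frame(age = rnorm(n))
  vals <- rnorm(n)
  adj <- regress_out(vals, tab, "age")
  expect_gt(cor(adj, vals - mean(vals)), 0.999)
})

test_that("collinear designs fail with the offending column named", {
  tab <- data.frame(age = 1:10, fiq = 2 * (1:10))
  expect_error(regress_out(rnorm(10), tab, c("age", "fiq")), "fiq")
})

test_that("adjusted t-values are invariant to affine covariate rescaling", {
  set.seed(12)
  n <- 60
  tab <- data.frame(age = rnorm(n, 15, 4))
  grp <- rep(c("case", "control"), each = n / 2)
  vals <- rnorm(n) + 0.5 * (grp == "case") + 0.1 * tab$age
  t1 <- with(list(a = regress_out(vals, tab, "age")),
             two_sample_t(a[grp == "case"], a[grp == "control"]))$t
  tab2 <- data.frame(age = 100 + 7 * tab$age)
  t2 <- with(list(a = regress_out(vals, tab2, "age")),
             two_sample_t(a[grp == "case"], a[grp == "control"]))$t
  expect_equal(t1, t2, tolerance = 1e-8)
})

test_that("bonferroni thresholds by alpha over the family size", {
  expect_true(bonferroni(0.04))
  expect_equal(bonferroni(c(0.0027, rep(0.5, 18))),
               rep(FALSE, 19))                     # 0.0027 > 0.05/19
  expect_true(bonferroni(c(0.0026, rep(0.5, 18)))[1])
  expect_error(bonferroni(numeric(0)), "empty")
  expect_error(bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("group analysis flags planted effects and ignores copied groups", {
  cc <- small_cohort(seed = 41, n_per_group = 25, T_len = 200, R = 8,
                     K = 3, effect_state = 2, effect_delta = 0.1)
  paths <- lapply(cc$cohort$subjects, `[[`, "true_path")
  names(paths) <- vapply(cc$cohort$subjects, `[[`, "", "subject_id")
  m <- cohort_metrics(paths, 3, manifest = cc$cohort$manifest)
  res <- run_group_analysis(m)
  fo_age <- res[res$metric == "FO" & res$covariate_set == "age", ]
  expect_gt(fo_age$t[fo_age$state == 2], 0)        # case-increased
  expect_true(fo_age$significant[fo_age$state == 2])
  # two identical groups (control subjects copied and relabeled as cases)
  ctrl <- m[m$group == "control", ]
  copy <- ctrl
  copy$group <- "case"
  copy$subject_id <- paste0(copy$subject_id, "-copy")
  m_same <- rbind(ctrl, copy)
  res_same <- run_group_analysis(m_same,
                                 covariate_sets = list(age = "age"))
  expect_true(all(abs(res_same$t) < 1e-10, na.rm = TRUE))
  expect_false(any(res_same$significant, na.rm = TRUE))
})

test_that("both covariate sets are always emitted with expected structure", {
  cc <- small_cohort(seed = 42, n_per_group = 8, T_len = 80, R = 6, K = 3)
  paths <- lapply(cc$cohort$subjects, `[[`, "true_path")
  names(paths) <- vapply(cc$cohort$subjects, `[[`, "", "subject_id")
  m <- cohort_metrics(paths, 3, manifest = cc$cohort$manifest)
  res <- run_group_analysis(m)
  expect_setequal(unique(res$covariate_set), c("age", "age_site_fiq"))
  expect_equal(nrow(res), 2 * 3 * 3)               # 2 sets x 3 metrics x 3 states
  expect_true(all(res$df[res$metric == "FO"] ==
                    res$n_case[res$metric == "FO"] +
                    res$n_control[res$metric == "FO"] - 2))
})
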