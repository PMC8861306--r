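# Covariate-adjusted two-sample comparison of temporal statistics.
# Nuisance covariates are regressed out of the pooled sample (group is
# deliberately excluded from the design, so the group signal survives in
# the residuals), then a pooled-variance two-sided t-test compares case
# vs control residuals per state, with Bonferroni control over the K
# states within each metric.

#' Regress nuisance covariates out of a metric
#'
#' Ordinary-least-squares residuals of `values` on an intercept plus the
#' requested covariates, with `site` one-hot encoded (reference level
#' dropped).  Group membership is never part of the design.  An empty
#' covariate set returns mean-centered values.
#'
#' @param values numeric vector, one per subject.
#' @param covariate_table data.frame with one row per subject (columns
#'   among `age`, `site`, `fiq`, ... in the same order as `values`).
#' @param covariates character subset of `names(covariate_table)`.
#' @return numeric vector of residuals (orthogonal to every design column).
#' @export
regress_out <- function(values, covariate_table, covariates = "age") {
  stopifnot(is.numeric(values))
  if (length(covariates) == 0L) return(values - mean(values))
  missing_cov <- setdiff(covariates, names(covariate_table))
  if (length(missing_cov))
    stopf("covariate(s) not in table: %s", paste(missing_cov, collapse = ", "))
  df <- covariate_table[covariates]
  if (nrow(df) != length(values))
    stopf("covariate table has %d rows but %d values given",
          nrow(df), length(values))
  if (anyNA(df)) stopf("missing covariate values")
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  X <- model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopf("rank-deficient covariate design; collinear column(s): %s",
          paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]], collapse = ", "))
  qr.resid(qrX, values)
}

#' Pooled two-sample t-test
#'
#' Classic equal-variance two-sided t-test.  `t` is signed as
#' (mean of `x`) - (mean of `y`), i.e. case minus control when called with
#' case values first.  `welch = TRUE` switches to the unequal-variance
#' form.
#'
#' @param x,y numeric samples (>= 2 each).
#' @param welch use the Welch–Satterthwaite form instead of pooling.
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stopf("need at least 2 observations per group")
  v1 <- var(x); v2 <- var(y)
  d <- mean(x) - mean(y)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) stopf("zero variance in both groups")
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tv <- d / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 == 0) stopf("zero pooled variance")
    df <- n1 + n2 - 2
    tv <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = tv, p = 2 * pt(-abs(tv), df), df = df, mean_diff = d)
}

#' Bonferroni significance flags
#'
#' Flags `p_i < alpha / m` with `m = length(p_values)`; the family is the
#' set of tests passed in (here, the K states within one metric).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise level.
#' @return logical vector of flags.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stopf("empty p-value list")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  !is.na(p_values) & p_values < alpha / length(p_values)
}

#' Group comparison of temporal statistics with covariate adjustment
#'
#' For each metric (fractional occupancy, mean lifetime, mean interval)
#' and each state, regresses the requested covariates out of the pooled
#' sample and applies a two-sided pooled t-test of case vs control
#' residuals, flagging significance by Bonferroni over the K states of
#' that metric.  Run once per covariate set; by default both the primary
#' (`age`) and the robustness (`age + site + fiq`) adjustments are
#' emitted, plus unadjusted p-values for reference.
#'
#' @param metrics a [cohort_metrics()] table including a `group` column
#'   (values `case`/`control`) and the covariate columns.
#' @param covariate_sets named list of character vectors.
#' @param alpha family-wise level.
#' @param welch use Welch instead of pooled t-tests.
#' @return data.frame: `metric`, `state`, `covariate_set`, `t`, `p`, `df`,
#'   `significant`, `p_uncorrected_significant`, `n_case`, `n_control`,
#'   `low_coverage`.
#' @export
run_group_analysis <- function(metrics,
                               covariate_sets = list(
                                 age = "age",
                                 age_site_fiq = c("age", "site", "fiq")),
                               alpha = 0.05, welch = FALSE) {
  stopifnot(is.data.frame(metrics), "group" %in% names(metrics))
  if (!all(metrics$group %in% c("case", "control")))
    stopf("group column must contain only 'case'/'control'")
  metric_cols <- c(FO = "fractional_occupancy", lifetime = "mean_lifetime",
                   interval = "mean_interval")
  states <- sort(unique(metrics$state))
  K <- length(states)
  n_subj <- length(unique(metrics$subject_id))
  out <- list()
  for (set_name in names(covariate_sets)) {
    covs <- covariate_sets[[set_name]]
    for (m in names(metric_cols)) {
      res <- lapply(states, function(k) {
        rows <- metrics[metrics$state == k, , drop = FALSE]
        rows <- rows[!is.na(rows[[metric_cols[m]]]), , drop = FALSE]
        n_case <- sum(rows$group == "case")
        n_ctrl <- sum(rows$group == "control")
        if (n_case < 2L || n_ctrl < 2L)
          return(data.frame(metric = m, state = k, covariate_set = set_name,
                            t = NA_real_, p = NA_real_, df = NA_real_,
                            n_case = n_case, n_control = n_ctrl,
                            low_coverage = TRUE))
        adj <- regress_out(rows[[metric_cols[m]]], rows, covs)
        tt <- two_sample_t(adj[rows$group == "case"],
                           adj[rows$group == "control"], welch = welch)
        data.frame(metric = m, state = k, covariate_set = set_name,
                   t = tt$t, p = tt$p, df = tt$df,
                   n_case = n_case, n_control = n_ctrl,
                   low_coverage = (n_case + n_ctrl) < 0.5 * n_subj)
      })
      res <- do.call(rbind, res)
      res$significant <- FALSE
      ok <- !is.na(res$p)
      if (any(ok)) res$significant[ok] <- bonferroni_family(res$p, K, alpha)[ok]
      res$p_uncorrected_significant <- ok & res$p < alpha
      out[[length(out) + 1L]] <- res
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[c("metric", "state", "covariate_set", "t", "p", "df", "significant",
        "p_uncorrected_significant", "n_case", "n_control", "low_coverage")]
}

# Bonferroni with a fixed family size m = K (states of one metric), even
# when some states were untestable; NA p-values stay non-significant.
bonferroni_family <- function(p, K, alpha) {
  !is.na(p) & p < alpha / K
}
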