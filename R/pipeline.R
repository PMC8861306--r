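# End-to-end orchestration: load (or accept) a cohort, standardize,
# concatenate, PCA-project, fit (or scan) the HMM, compute temporal
# statistics, group tests, and the transition-community analysis, writing
# every result as TSV/JSON stamped with the configuration hash and seed.

#' Build a validated pipeline configuration
#'
#' Nested list mirroring the pipeline stages; unknown keys are rejected.
#'
#' @param manifest path to the cohort manifest TSV (may be `NULL` when a
#'   `cohort` object is passed to [run_pipeline()] directly).
#' @param out_dir output directory.
#' @param preprocessing list: `variance_target` (default 0.90) and/or
#'   `n_components` (wins when both set).
#' @param hmm list: `K` (fixed state count) or `K_range` (scan +
#'   elbow selection), `n_restarts` (default 5), `max_iter` (default 500),
#'   `tol` (default 1e-6), `epsilon` (elbow threshold, default 0.05),
#'   `seed` (default 1).
#' @param stats list: `alpha` (default 0.05), `covariate_sets` (default
#'   primary `age` and robustness `age+site+fiq`), `welch` (default FALSE).
#' @param transitions list: `kept_fraction` (default 0.25).
#' @param units list: `tr_seconds` (optional; reporting only).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL, out_dir = tempfile("brainstates_"),
                            preprocessing = list(), hmm = list(),
                            stats = list(), transitions = list(),
                            units = list()) {
  defaults <- list(
    preprocessing = list(variance_target = 0.90, n_components = NULL),
    hmm = list(K = NULL, K_range = NULL, n_restarts = 5L, max_iter = 500L,
               tol = 1e-6, epsilon = 0.05, seed = 1L),
    stats = list(alpha = 0.05,
                 covariate_sets = list(age = "age",
                                       age_site_fiq = c("age", "site", "fiq")),
                 welch = FALSE),
    transitions = list(kept_fraction = 0.25),
    units = list(tr_seconds = NULL))
  for (stage in names(defaults)) {
    given <- get(stage)
    unknown <- setdiff(names(given), names(defaults[[stage]]))
    if (length(unknown))
      stopf("unknown %s option(s): %s", stage, paste(unknown, collapse = ", "))
    defaults[[stage]] <- modify_list(defaults[[stage]], given)
  }
  cfg <- c(list(manifest = manifest, out_dir = out_dir), defaults)
  h <- cfg$hmm
  if (!is.null(h$K) && !is_count(h$K)) stopf("hmm$K must be a positive count")
  if (is.null(h$K) && is.null(h$K_range)) stopf("set hmm$K or hmm$K_range")
  if (h$tol <= 0 || h$max_iter < 1 || h$n_restarts < 1)
    stopf("invalid hmm options")
  if (cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1) stopf("alpha in (0,1)")
  kf <- cfg$transitions$kept_fraction
  if (kf <= 0 || kf > 1) stopf("kept_fraction in (0, 1]")
  pp <- cfg$preprocessing
  if (is.null(pp$n_components) &&
      (pp$variance_target <= 0 || pp$variance_target > 1))
    stopf("variance_target in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  # stable short fingerprint of the scientific configuration (djb2 over
  # its JSON); filesystem locations are excluded so identical analyses
  # hash identically wherever they run
  cfg <- unclass(cfg)
  cfg$manifest <- NULL
  cfg$out_dir <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                        null = "null")
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full dynamic-state pipeline
#'
#' Stages: load cohort -> per-subject standardization -> concatenation ->
#' PCA -> VB-HMM fit (or K scan + median-FO elbow selection) -> temporal
#' statistics -> covariate-adjusted group comparison -> transition
#' thresholding + Newman community detection + module labeling -> ROI
#' activation maps.  All artifacts are written under `config$out_dir`:
#' `hmm_model.json`, `metrics.tsv`, `group_stats.tsv`, `partition.json`,
#' `state_maps.tsv`, `scan.tsv` (when scanning) and `pipeline_log.txt`.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional `cohort` object (bypasses manifest loading; used
#'   for simulated cohorts).
#' @return invisibly, a list with `fit`, `transform`, `metrics`, `stats`,
#'   `graph`, `partition`, `maps`, `scan` (or `NULL`), `selected_K`,
#'   `config_hash`, `out_dir`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline_log.txt")
  hash <- config_hash(config)
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("brainstates pipeline | config %s | seed %d | %s\n", hash,
              config$hmm$seed, format(t_start, "%Y-%m-%d %H:%M:%S")),
      file = log_path)

  stage <- "load"
  result <- tryCatch({
    if (is.null(cohort)) {
      if (is.null(config$manifest)) stopf("no manifest and no cohort given")
      cohort <- load_cohort(config$manifest)
    }
    logf("load: %d subjects, R = %d regions", length(cohort$subjects),
         ncol(cohort$subjects[[1]]$data))

    stage <- "preprocess"
    prep <- preprocess_cohort(cohort,
                              n_components = config$preprocessing$n_components,
                              variance_target = config$preprocessing$variance_target)
    stacked <- list(data = prep$stacked, spans = prep$spans)
    transform <- prep$transform
    proj <- prep$projected
    logf("preprocess: stacked %d x %d; PCA P = %d (%.1f%% variance)",
         nrow(stacked$data), ncol(stacked$data), transform$P,
         100 * sum(transform$explained_variance_ratio))

    stage <- "hmm"
    scan <- NULL
    if (!is.null(config$hmm$K_range)) {
      scan <- scan_states(proj, stacked$spans, K_range = config$hmm$K_range,
                          n_restarts = config$hmm$n_restarts,
                          max_iter = config$hmm$max_iter, tol = config$hmm$tol,
                          seed = config$hmm$seed)
      sel <- select_n_states(scan, epsilon = config$hmm$epsilon)
      K <- sel$K
      write.table(scan$records, file.path(config$out_dir, "scan.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      logf("scan: K in [%d, %d]; selected K* = %d (plateau %sfound; free energy monotone: %s)",
           min(config$hmm$K_range), max(config$hmm$K_range), K,
           if (sel$warning) "NOT " else "", sel$free_energy_monotone)
    } else K <- config$hmm$K
    fit <- fit_hmm(proj, stacked$spans, K = K,
                   n_restarts = config$hmm$n_restarts,
                   max_iter = config$hmm$max_iter, tol = config$hmm$tol,
                   seed = config$hmm$seed)
    logf("hmm: K = %d, %d iterations, free energy %.3f, best restart seed %d",
         K, length(fit$free_energy_trace), tail(fit$free_energy_trace, 1),
         fit$seed)
    write_hmm_json(fit, file.path(config$out_dir, "hmm_model.json"))

    stage <- "metrics"
    metrics <- cohort_metrics(fit$posterior, K, manifest = cohort$manifest,
                              tr_seconds = config$units$tr_seconds)
    write.table(metrics, file.path(config$out_dir, "metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "stats"
    stats_tbl <- run_group_analysis(metrics,
                                    covariate_sets = config$stats$covariate_sets,
                                    alpha = config$stats$alpha,
                                    welch = config$stats$welch)
    write.table(stats_tbl, file.path(config$out_dir, "group_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    n_sig <- sum(stats_tbl$significant, na.rm = TRUE)
    logf("stats: %d (metric, state, set) tests, %d significant after Bonferroni",
         nrow(stats_tbl), n_sig)

    stage <- "transitions"
    graph <- withCallingHandlers(
      threshold_transitions(fit$transition,
                            kept_fraction = config$transitions$kept_fraction),
      warning = function(w) {
        logf("transitions: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    partition <- newman_modularity(graph)
    partition <- label_modules(partition, stats_tbl,
                               covariate_set = names(config$stats$covariate_sets)[1])
    logf("transitions: kept %d/%d edges (requested %d); %d modules, Q = %.4f",
         graph$n_kept, K * (K - 1), graph$n_requested, partition$n_modules,
         partition$Q)
    write.table(graph$edges, file.path(config$out_dir, "transition_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(membership = partition$membership, Q = partition$Q,
           module_labels = as.list(partition$module_labels),
           config_hash = hash, seed = config$hmm$seed),
      file.path(config$out_dir, "partition.json"), digits = NA,
      auto_unbox = TRUE)

    stage <- "maps"
    maps <- state_maps(fit, transform)
    write.table(data.frame(state = seq_len(K), maps, check.names = FALSE),
                file.path(config$out_dir, "state_maps.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    logf("done in %.1f s", as.numeric(difftime(Sys.time(), t_start, units = "secs")))
    list(fit = fit, transform = transform, metrics = metrics,
         stats = stats_tbl, graph = graph, partition = partition,
         maps = maps, scan = scan, selected_K = K, config_hash = hash,
         out_dir = config$out_dir)
  }, error = function(e) {
    logf("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(result)
}
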