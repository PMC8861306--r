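# Global temporal statistics of the hard state path: fractional
# occupancy, lifetimes (dwell times) and interval times, all in units of
# timepoints.  Computed on hard (argmax) paths, matching the convention
# that a state is "active" at the timepoint where its posterior
# probability is maximal.

check_path <- function(path, K) {
  if (length(path) < 1L) stopf("path must have length >= 1")
  if (any(path < 1L | path > K)) stopf("state id outside 1..K in path")
  invisible(TRUE)
}

#' Fractional occupancy per state
#'
#' Fraction of timepoints assigned to each state: `FO_k = #\{t: path_t = k\}/T`.
#'
#' @param path integer state path (values in `1..K`).
#' @param K number of states.
#' @return length-`K` vector of fractions summing to 1.
#' @export
fractional_occupancy <- function(path, K) {
  check_path(path, K)
  tabulate(path, nbins = K) / length(path)
}

#' Lifetimes (dwell times) per state
#'
#' Lengths of maximal constant runs of each state, in order of occurrence.
#' Runs truncated by the start or end of the sequence are included by
#' default; `censor_boundaries = TRUE` drops them (at the cost of the
#' conservation identity sum of all lifetimes = T).
#'
#' @inheritParams fractional_occupancy
#' @param censor_boundaries drop runs touching either sequence end.
#' @return list of `K` integer vectors of run lengths.
#' @export
state_lifetimes <- function(path, K, censor_boundaries = FALSE) {
  check_path(path, K)
  r <- rle(as.integer(path))
  keep <- rep(TRUE, length(r$lengths))
  if (censor_boundaries && length(r$lengths) > 0) {
    keep[1] <- FALSE
    keep[length(keep)] <- FALSE
  }
  lapply(seq_len(K), function(k)
    r$lengths[keep & r$values == k])
}

#' Interval times per state
#'
#' Gaps (in timepoints) between consecutive visits to a state: if one
#' visit ends at timepoint `e` and the next begins at `s`, the interval is
#' `s - e - 1`.  States visited at most once get an empty vector.
#'
#' @inheritParams fractional_occupancy
#' @return list of `K` integer vectors of gap lengths (each >= 1).
#' @export
state_intervals <- function(path, K) {
  check_path(path, K)
  r <- rle(as.integer(path))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(seq_len(K), function(k) {
    i <- which(r$values == k)
    if (length(i) < 2L) integer(0)
    else starts[i[-1]] - ends[i[-length(i)]] - 1L
  })
}

#' Per-subject, per-state temporal statistics for a cohort
#'
#' Computes fractional occupancy, mean lifetime, number of visits and mean
#' interval for every subject and state from the hard state paths of a
#' fitted HMM (or any list of paths).  Means over empty lists are `NA`
#' (the statistic is undefined for unvisited states).
#'
#' @param posteriors list as in `hmm_fit$posterior` (elements with
#'   `subject_id` and `path`), or a named list of integer paths.
#' @param K number of states.
#' @param manifest optional manifest data.frame (`subject_id`, `group`,
#'   covariates) merged onto the output.
#' @param censor_boundaries see [state_lifetimes()].
#' @param tr_seconds optional repetition time; when given, lifetime and
#'   interval columns are additionally reported in seconds
#'   (`mean_lifetime_s`, `mean_interval_s`).
#' @return a tidy data.frame with one row per (subject, state):
#'   `subject_id`, `state`, `fractional_occupancy`, `mean_lifetime`,
#'   `n_visits`, `mean_interval` (+ manifest columns).
#' @export
cohort_metrics <- function(posteriors, K, manifest = NULL,
                           censor_boundaries = FALSE, tr_seconds = NULL) {
  paths <- lapply(posteriors, function(p) if (is.list(p)) p$path else p)
  ids <- names(posteriors) %||% sprintf("sub-%03d", seq_along(posteriors))
  if (is.list(posteriors[[1]]) && !is.null(posteriors[[1]]$subject_id))
    ids <- unname(vapply(posteriors, `[[`, "", "subject_id"))
  rows <- lapply(seq_along(paths), function(s) {
    fo <- fractional_occupancy(paths[[s]], K)
    lt <- state_lifetimes(paths[[s]], K, censor_boundaries)
    iv <- state_intervals(paths[[s]], K)
    data.frame(
      subject_id = ids[s], state = seq_len(K), fractional_occupancy = fo,
      mean_lifetime = vapply(lt, function(v)
        if (length(v)) mean(v) else NA_real_, 0),
      n_visits = vapply(lt, length, 0L),
      mean_interval = vapply(iv, function(v)
        if (length(v)) mean(v) else NA_real_, 0),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(tr_seconds)) {
    out$mean_lifetime_s <- out$mean_lifetime * tr_seconds
    out$mean_interval_s <- out$mean_interval * tr_seconds
  }
  if (!is.null(manifest))
    out <- merge(out, manifest[setdiff(names(manifest), "path")],
                 by = "subject_id", sort = FALSE)
  out[order(match(out$subject_id, ids), out$state), , drop = FALSE]
}
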