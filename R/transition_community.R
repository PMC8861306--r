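# Community structure of the state-transition matrix: keep the strongest
# off-diagonal transitions, then maximize directed weighted modularity by
# Newman's spectral bisection (on the symmetrized modularity matrix) with
# Kernighan-Lin-style node-moving refinement.

#' Threshold a transition matrix to its strongest off-diagonal entries
#'
#' Removes the diagonal, ranks the remaining entries by weight and keeps
#' the top `ceiling(kept_fraction * K * (K - 1))`; entries tied with the
#' cutoff weight are all retained (and the tie is reported via a warning).
#'
#' @param transition row-stochastic `K x K` matrix (`K >= 2`).
#' @param kept_fraction fraction of off-diagonal entries to keep, in (0, 1].
#' @return object of class `transition_graph`: `adjacency` (`K x K`,
#'   zero diagonal, non-kept entries zeroed), `edges` (data.frame `from`,
#'   `to`, `weight`), `kept_fraction`, `n_requested`, `n_kept`,
#'   `tie_at_cutoff`.
#' @export
threshold_transitions <- function(transition, kept_fraction = 0.25) {
  check_row_stochastic(transition)
  K <- nrow(transition)
  if (K < 2L) stopf("need K >= 2 states")
  if (!is.numeric(kept_fraction) || kept_fraction <= 0 || kept_fraction > 1)
    stopf("kept_fraction must be in (0, 1]")
  A <- transition
  diag(A) <- 0
  w <- A[row(A) != col(A)]
  m <- as.integer(ceiling(kept_fraction * K * (K - 1)))
  cutoff <- sort(w, decreasing = TRUE)[m]
  keep <- A >= cutoff & row(A) != col(A)
  n_kept <- sum(keep)
  if (n_kept > m)
    warnf("ties at the cutoff weight: keeping %d edges instead of %d",
          n_kept, m)
  A[!keep] <- 0
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = idx[, 1], to = idx[, 2],
                      weight = A[idx])
  edges <- edges[order(-edges$weight, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(adjacency = A, edges = edges, kept_fraction = kept_fraction,
                 n_requested = m, n_kept = n_kept,
                 tie_at_cutoff = n_kept > m),
            class = "transition_graph")
}

#' Directed weighted modularity of a partition
#'
#' `Q = (1/w) * sum_ij [A_ij - s_out_i * s_in_j / w] * [c_i == c_j]` with
#' `w` the total edge weight and `s_out`/`s_in` the node out-/in-strengths.
#'
#' @param A weighted adjacency matrix (zero diagonal).
#' @param membership integer module id per node.
#' @return scalar Q.
#' @export
modularity_q <- function(A, membership) {
  w <- sum(A)
  if (w <= 0) stopf("graph has zero total weight")
  s_out <- rowSums(A); s_in <- colSums(A)
  B <- A - outer(s_out, s_in) / w
  same <- outer(membership, membership, `==`)
  sum(B[same]) / w
}

# Greedy node-moving refinement: repeatedly move single nodes to the
# module (incl. a fresh singleton is not allowed; modules fixed) that
# maximally increases Q, until no move helps.  Deterministic order.
refine_partition <- function(A, membership) {
  mods <- sort(unique(membership))
  repeat {
    improved <- FALSE
    for (i in seq_along(membership)) {
      best_q <- modularity_q(A, membership)
      best_m <- membership[i]
      for (m in mods) {
        if (m == membership[i]) next
        cand <- membership
        cand[i] <- m
        q <- modularity_q(A, cand)
        if (q > best_q + 1e-12) { best_q <- q; best_m <- m }
      }
      if (best_m != membership[i]) {
        membership[i] <- best_m
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  membership
}

# One spectral bisection attempt on the node subset `idx` (indices into
# the full graph) using the symmetrized generalized modularity matrix.
spectral_split <- function(Bs, idx) {
  Bg <- Bs[idx, idx, drop = FALSE]
  diag(Bg) <- diag(Bg) - rowSums(Bs[idx, idx, drop = FALSE])
  e <- eigen(Bg, symmetric = TRUE)
  if (e$values[1] <= 1e-10) return(NULL)
  v <- e$vectors[, 1]
  side <- v >= 0
  if (all(side) || !any(side)) return(NULL)
  side
}

#' Newman spectral community detection on a transition graph
#'
#' Maximizes the directed weighted modularity of the thresholded
#' transition graph by recursive spectral bisection of the modularity
#' matrix (the eigen step uses the symmetrized form `(B + B^T)/2`),
#' followed by Kernighan-Lin-style single-node-moving refinement.
#' Bisection of a group stops when the leading eigenvalue of its
#' generalized modularity matrix is non-positive or the split does not
#' increase Q.  Fully deterministic given the input graph.
#'
#' @param graph a [threshold_transitions()] result, or a weighted
#'   adjacency matrix with zero diagonal.
#' @return object of class `community_partition`: `membership` (integer
#'   module per state, ids `1..M`), `Q`, `n_modules`, `module_labels`
#'   (filled by [label_modules()]).
#' @export
newman_modularity <- function(graph) {
  A <- if (inherits(graph, "transition_graph")) graph$adjacency else graph
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  K <- nrow(A)
  if (K < 2L) stopf("need at least 2 nodes")
  w <- sum(A)
  if (w <= 0) stopf("graph has zero total weight")
  B <- A - outer(rowSums(A), colSums(A)) / w
  Bs <- (B + t(B)) / 2

  membership <- rep(1L, K)
  queue <- list(seq_len(K))
  next_id <- 2L
  while (length(queue)) {
    idx <- queue[[1]]
    queue <- queue[-1]
    if (length(idx) < 2L) next
    side <- spectral_split(Bs, idx)
    if (is.null(side)) next
    cand <- membership
    cand[idx[!side]] <- next_id
    # KL-style sweep restricted to the two halves of this split
    cand <- refine_two(A, cand, membership[idx][1], next_id, idx)
    if (modularity_q(A, cand) > modularity_q(A, membership) + 1e-12) {
      membership <- cand
      queue <- c(queue, list(idx[membership[idx] != next_id]),
                 list(idx[membership[idx] == next_id]))
      next_id <- next_id + 1L
    }
  }
  membership <- refine_partition(A, membership)
  membership <- as.integer(factor(membership, levels = unique(membership)))
  structure(list(membership = membership, Q = modularity_q(A, membership),
                 n_modules = length(unique(membership)),
                 module_labels = NULL),
            class = "community_partition")
}

# node-moving between exactly two module ids, restricted to `idx`
refine_two <- function(A, membership, id_a, id_b, idx) {
  repeat {
    improved <- FALSE
    for (i in idx) {
      cur <- membership[i]
      other <- if (cur == id_a) id_b else id_a
      cand <- membership
      cand[i] <- other
      if (sum(membership[idx] == cur) > 1L &&
          modularity_q(A, cand) > modularity_q(A, membership) + 1e-12) {
        membership <- cand
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  membership
}

#' Label transition modules by their group-difference profile
#'
#' A module is `case-related` when more of its states show a significant
#' case-increased fractional occupancy than show a significant decrease,
#' `control-related` in the opposite case, and `mixed` when the counts
#' tie or no state is significant.
#'
#' @param partition a [newman_modularity()] result.
#' @param group_results a [run_group_analysis()] table (the FO rows of one
#'   covariate set are used; pick with `covariate_set`).
#' @param covariate_set which covariate set's results to use.
#' @return the partition with `module_labels` filled (named character
#'   vector, one entry per module id).
#' @export
label_modules <- function(partition, group_results, covariate_set = NULL) {
  stopifnot(inherits(partition, "community_partition"))
  fo <- group_results[group_results$metric == "FO", , drop = FALSE]
  if (!is.null(covariate_set))
    fo <- fo[fo$covariate_set == covariate_set, , drop = FALSE]
  else if (length(unique(fo$covariate_set)) > 1)
    fo <- fo[fo$covariate_set == fo$covariate_set[1], , drop = FALSE]
  labels <- character(0)
  for (m in sort(unique(partition$membership))) {
    states <- which(partition$membership == m)
    rows <- fo[fo$state %in% states, , drop = FALSE]
    up <- sum(rows$significant & rows$t > 0, na.rm = TRUE)
    down <- sum(rows$significant & rows$t < 0, na.rm = TRUE)
    labels[as.character(m)] <-
      if (up > down) "case-related"
      else if (down > up) "control-related"
      else "mixed"
  }
  partition$module_labels <- labels
  partition
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d modules, Q = %.4f\n",
              x$n_modules, x$Q))
  for (m in sort(unique(x$membership))) {
    lab <- if (!is.null(x$module_labels)) x$module_labels[as.character(m)] else ""
    cat(sprintf("  module %d: states %s %s\n", m,
                paste(which(x$membership == m), collapse = ", "),
                if (nzchar(lab)) paste0("(", lab, ")") else ""))
  }
  invisible(x)
}
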