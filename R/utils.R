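# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's
# RNG state afterwards so package functions do not perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == floor(x)
}

check_simplex <- function(p, tol = 1e-8, what = "probability vector") {
  if (any(p < -tol) || abs(sum(p) - 1) > tol)
    stopf("%s must be non-negative and sum to 1", what)
  invisible(TRUE)
}

check_row_stochastic <- function(A, tol = 1e-8) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stopf("transition matrix must be square")
  if (any(A < -tol) || any(abs(rowSums(A) - 1) > tol))
    stopf("transition matrix rows must be non-negative and sum to 1")
  invisible(TRUE)
}

# All permutations of 1..n (n small), as a list.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    i <- i + 1L
    out[[i]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Match estimated states to reference states
#'
#' Finds the permutation of estimated state labels that maximizes the total
#' similarity (negative Euclidean distance) between matched rows of two
#' `K x D` mean matrices.  Exhaustive over permutations for `K <= 8`,
#' greedy otherwise.
#'
#' @param ref reference `K x D` matrix (rows = states).
#' @param est estimated `K x D` matrix.
#' @return integer vector `perm` such that `est[perm[k], ]` matches `ref[k, ]`.
#' @export
match_states <- function(ref, est) {
  stopifnot(is.matrix(ref), is.matrix(est), dim(ref)[1] == dim(est)[1],
            dim(ref)[2] == dim(est)[2])
  K <- nrow(ref)
  D <- as.matrix(dist(rbind(ref, est)))[seq_len(K), K + seq_len(K), drop = FALSE]
  if (K <= 8L) {
    best <- NULL; best_cost <- Inf
    for (p in all_permutations(K)) {
      cost <- sum(D[cbind(seq_len(K), p)])
      if (cost < best_cost) { best_cost <- cost; best <- p }
    }
    as.integer(best)
  } else {
    perm <- integer(K); used <- logical(K)
    for (k in order(apply(D, 1, min))) {
      j <- which.min(replace(D[k, ], used, Inf))
      perm[k] <- j; used[j] <- TRUE
    }
    perm
  }
}

# Simple recursive merge of named lists (user values override defaults).
modify_list <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]))
      base[[nm]] <- modify_list(base[[nm]], new[[nm]])
    else base[[nm]] <- new[[nm]]
  }
  base
}
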