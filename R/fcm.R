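#' Fuzzy c-means cost function
#'
#' Evaluates the Bezdek objective
#' \deqn{J(X, U, C; m) = \sum_{i=1}^n \sum_{j=1}^k u_{ij}^m \, \lVert x_i - c_j \rVert^2,}
#' the quantity the alternating fuzzy c-means updates minimize. Distances are
#' squared Euclidean on the raw feature matrix (here, the 0/1
#' specialty-involvement matrix; no scaling is applied).
#'
#' @param X numeric matrix, n patients x p features.
#' @param U membership matrix, n x k, rows summing to 1.
#' @param C centroid matrix, k x p.
#' @param m fuzziness exponent, must be > 1.
#' @return Non-negative scalar cost.
#' @seealso [fit_fcm()], [fit_fcm_multistart()]
#' @export
fcm_cost <- function(X, U, C, m) {
  X <- as.matrix(X); U <- as.matrix(U); C <- as.matrix(C)
  stopifnot(is.numeric(m), length(m) == 1, m > 1)
  if (nrow(U) != nrow(X) || ncol(U) != nrow(C) || ncol(C) != ncol(X))
    stop("dimension mismatch between X, U, and C")
  D2 <- .sqdist(X, C)
  sum(U^m * D2)
}

# squared Euclidean distances, n x k, clamped at 0 against cancellation
.sqdist <- function(X, C) {
  D2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  D2[D2 < 0] <- 0
  D2
}

#' First-order-optimal membership update
#'
#' Given fixed centroids, returns the row-stochastic membership matrix that
#' minimizes the fuzzy c-means cost:
#' \eqn{u_{ij} = 1 / \sum_l (d_{ij}^2 / d_{il}^2)^{1/(m-1)}}.
#'
#' A patient coinciding exactly with one or more centroids gets its
#' membership split equally over the coincident centroids (1 if unique) and
#' exactly 0 elsewhere; this is the only situation in which memberships of
#' exactly 0 or 1 are produced.
#'
#' @inheritParams fcm_cost
#' @return n x k membership matrix with rows summing to 1.
#' @export
update_memberships <- function(X, C, m) {
  X <- as.matrix(X); C <- as.matrix(C)
  stopifnot(m > 1)
  D2 <- .sqdist(X, C)
  U <- matrix(0, nrow(X), nrow(C))
  zero <- D2 <= .Machine$double.eps
  degenerate <- rowSums(zero) > 0
  if (any(!degenerate)) {
    w <- D2[!degenerate, , drop = FALSE]^(-1 / (m - 1))
    U[!degenerate, ] <- w / rowSums(w)
  }
  if (any(degenerate)) {
    zd <- zero[degenerate, , drop = FALSE]
    U[degenerate, ] <- zd / rowSums(zd)
  }
  U
}

#' First-order-optimal centroid update
#'
#' Given fixed memberships, each centroid is the \eqn{u^m}-weighted mean of
#' the data: \eqn{c_j = \sum_i u_{ij}^m x_i / \sum_i u_{ij}^m}.
#'
#' @inheritParams fcm_cost
#' @return k x p centroid matrix.
#' @export
update_centroids <- function(X, U, m) {
  X <- as.matrix(X); U <- as.matrix(U)
  stopifnot(m > 1, nrow(U) == nrow(X))
  Um <- U^m
  w <- colSums(Um)
  if (any(w <= 0)) stop("cluster with zero total membership weight")
  (t(Um) %*% X) / w
}

#' Fit fuzzy c-means from one random initialization
#'
#' Alternates [update_centroids()] and [update_memberships()] from a random
#' row-stochastic membership matrix (uniform Dirichlet per row) until the
#' maximum absolute membership change drops below `tol` or `max_iter` is
#' reached. The cost sequence is non-increasing; the final cost, iteration
#' count, and per-iteration costs are recorded.
#'
#' @param X numeric matrix, n x p (typically the 0/1 involvement matrix).
#' @param k number of clusters, integer >= 2.
#' @param m fuzziness parameter, > 1. Values near 1 give near-crisp
#'   memberships; large values flatten memberships towards 1/k.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the membership change.
#' @param init_seed integer seed for the random initialization.
#' @return An object of class `fcm_fit`: list with `U` (memberships, rows
#'   named after `rownames(X)`), `C` (centroids), `J` (cost), `k`, `m`,
#'   `n_iter`, `converged`, `seed_used`, `cost_trace`.
#' @export
fit_fcm <- function(X, k, m, max_iter = 200, tol = 1e-6, init_seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(k >= 2, m > 1, tol > 0)
  if (n < k) stop("fewer observations than clusters (n < k)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(init_seed)
  U <- matrix(stats::rexp(n * k), n, k)
  U <- U / rowSums(U)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    C <- update_centroids(X, U, m)
    U_new <- update_memberships(X, C, m)
    trace <- c(trace, fcm_cost(X, U_new, C, m))
    delta <- max(abs(U_new - U))
    U <- U_new
    if (delta < tol) { converged <- TRUE; break }
  }
  rownames(U) <- rownames(X)
  colnames(C) <- colnames(X)
  structure(list(U = U, C = C, J = trace[length(trace)], k = k, m = m,
                 n_iter = iter, converged = converged,
                 seed_used = as.integer(init_seed), cost_trace = trace),
            class = "fcm_fit")
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("Fuzzy c-means fit: n = %d, k = %d, m = %.3g\n",
              nrow(x$U), x$k, x$m))
  cat(sprintf("  cost J = %.6g after %d iterations (%s)\n", x$J, x$n_iter,
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' Multistart fuzzy c-means
#'
#' Because the initialization is random and the objective non-convex, the
#' algorithm is run `n_restarts` times from independent initializations and
#' the run with minimal cost is returned (ties broken by lowest run index).
#' Per-run seeds are drawn deterministically from `seed`, so the whole
#' multistart is reproducible.
#'
#' @inheritParams fit_fcm
#' @param n_restarts number of independent runs (default 100).
#' @param seed master seed from which the per-run seeds are derived.
#' @return The best `fcm_fit`, with an extra element `restart_costs` giving
#'   every run's final cost.
#' @export
fit_fcm_multistart <- function(X, k, m, n_restarts = 100, seed = 1L,
                               max_iter = 200, tol = 1e-6) {
  stopifnot(n_restarts >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)
  best <- NULL
  costs <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    fit <- fit_fcm(X, k, m, max_iter = max_iter, tol = tol,
                   init_seed = run_seeds[r])
    costs[r] <- fit$J
    if (is.null(best) || fit$J < best$J) best <- fit
  }
  best$restart_costs <- costs
  best
}

#' Harden a membership matrix to crisp labels
#'
#' Assigns each patient to the cluster of maximal membership; ties go to the
#' lowest cluster index.
#'
#' @param U membership matrix.
#' @return Integer vector of cluster labels in `1:ncol(U)`.
#' @export
harden <- function(U) {
  max.col(as.matrix(U), ties.method = "first")
}

# Save/restore .Random.seed so fitting never disturbs the caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
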