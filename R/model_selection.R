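#' Xie-Beni index
#'
#' Compactness-to-separation ratio
#' \deqn{XB = J(X, U, C; m) / (n \cdot \min_{j \ne l} \lVert c_j - c_l \rVert^2).}
#' Smaller is better. Undefined (error) when two centroids coincide.
#'
#' @inheritParams fcm_cost
#' @return Positive scalar (0 only when every point sits on a centroid).
#' @export
xie_beni <- function(X, U, C, m) {
  C <- as.matrix(C)
  if (nrow(C) < 2) stop("Xie-Beni requires k >= 2")
  sep <- min(stats::dist(C))^2
  if (sep <= .Machine$double.eps)
    stop("two identical centroids: Xie-Beni index undefined")
  fcm_cost(X, U, C, m) / (nrow(as.matrix(X)) * sep)
}

#' Partition coefficient
#'
#' \eqn{PC = (1/n) \sum_i \sum_j u_{ij}^2}, in \eqn{[1/k, 1]}; 1 for a crisp
#' partition, 1/k for uniform memberships. Larger is better (crisper).
#'
#' @param U membership matrix, rows summing to 1.
#' @export
partition_coefficient <- function(U) {
  U <- as.matrix(U)
  sum(U^2) / nrow(U)
}

#' Partition entropy
#'
#' \eqn{PE = -(1/n) \sum_i \sum_j u_{ij} \log u_{ij}} with
#' \eqn{0 \log 0 := 0}, in \eqn{[0, \log k]} (natural logarithm); 0 for a
#' crisp partition, \eqn{\log k} for uniform memberships. Smaller is better.
#'
#' @param U membership matrix, rows summing to 1.
#' @export
partition_entropy <- function(U) {
  U <- as.matrix(U)
  terms <- ifelse(U > 0, U * log(U), 0)
  -sum(terms) / nrow(U)
}

#' Silhouette index of a (hardened) fuzzy partition
#'
#' Crisp silhouette on the hardened (maximal-membership) labels with plain
#' Euclidean distance: for patient i, a(i) is the mean distance to its own
#' cluster (excluding itself), b(i) the smallest mean distance to another
#' cluster, and the index is the mean of (b - a)/max(a, b). Patients in
#' singleton clusters contribute 0. With `fuzzy = TRUE` a membership-weighted
#' variant is used instead: per-cluster mean distances are weighted by the
#' other patients' memberships, with "own" cluster still the hardened label.
#'
#' @param X data matrix, n x p.
#' @param U membership matrix, n x k.
#' @param fuzzy use the membership-weighted variant (default crisp).
#' @param dist_matrix optional precomputed n x n Euclidean distance matrix
#'   (recycled across grid cells for speed).
#' @return Scalar in \eqn{[-1, 1]}.
#' @export
silhouette_index <- function(X, U, fuzzy = FALSE, dist_matrix = NULL) {
  X <- as.matrix(X); U <- as.matrix(U)
  n <- nrow(X); k <- ncol(U)
  labels <- harden(U)
  if (length(unique(labels)) < 2)
    stop("silhouette undefined: all patients in one hardened cluster")
  if (is.null(dist_matrix)) dist_matrix <- .full_dist(X)
  if (fuzzy) {
    # weighted sums of distances to members of each cluster (n x k)
    S <- dist_matrix %*% U
    W <- matrix(colSums(U), n, k, byrow = TRUE)
    own <- cbind(seq_len(n), labels)
    # exclude self from own-cluster average (self weight = own membership)
    a <- (S[own]) / pmax(W[own] - U[own], .Machine$double.eps)
    B <- S / W
    B[own] <- Inf
    b <- apply(B, 1, min)
  } else {
    M <- outer(labels, seq_len(k), "==") + 0   # n x k crisp indicator
    S <- dist_matrix %*% M
    sizes <- matrix(colSums(M), n, k, byrow = TRUE)
    own <- cbind(seq_len(n), labels)
    a <- S[own] / pmax(sizes[own] - 1, 1)      # singleton handled below
    B <- S / sizes
    B[own] <- Inf
    b <- apply(B, 1, min)
  }
  s <- (b - a) / pmax(a, b)
  singleton <- tabulate(labels, k)[labels] == 1
  s[singleton] <- 0
  s[!is.finite(s)] <- 0
  mean(s)
}

.full_dist <- function(X) {
  G <- tcrossprod(X)
  d2 <- outer(diag(G), diag(G), "+") - 2 * G
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Grid search over the fuzziness parameter and cluster count
#'
#' For every combination of `m_grid` and `k_grid`, runs a multistart fuzzy
#' c-means fit ([fit_fcm_multistart()]) and evaluates the four validity
#' indices on the best run. Per-cell seeds derive deterministically from
#' `seed`.
#'
#' If a cell's hardened partition collapses to a single non-empty cluster
#' its silhouette is recorded as `NA` with a warning and that cell is
#' excluded from the silhouette's vote during selection.
#'
#' @inheritParams fit_fcm_multistart
#' @param m_grid fuzziness values to try (default 1.1 to 1.5 by 0.1).
#' @param k_grid cluster counts to try (default 5:15).
#' @param keep_fits keep each cell's best `fcm_fit` (attribute `"fits"`) for
#'   downstream reuse.
#' @param fuzzy_silhouette evaluate the membership-weighted silhouette
#'   variant instead of the crisp one.
#' @return A data frame of class `fcm_index_table` with columns `m`, `k`,
#'   `XB`, `PC`, `PE`, `SIL`, `J`, one row per grid cell.
#' @seealso [select_m()], [select_k()], [get_fit()]
#' @export
grid_search <- function(X, m_grid = seq(1.1, 1.5, by = 0.1), k_grid = 5:15,
                        n_restarts = 100, seed = 1L, max_iter = 200,
                        tol = 1e-6, keep_fits = TRUE,
                        fuzzy_silhouette = FALSE) {
  X <- as.matrix(X)
  stopifnot(length(m_grid) >= 1, length(k_grid) >= 1)
  if (nrow(X) < max(k_grid)) stop("n smaller than the largest k in the grid")
  cells <- expand.grid(k = k_grid, m = m_grid)[, c("m", "k")]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  Dmat <- .full_dist(X)
  fits <- vector("list", nrow(cells))
  out <- cbind(cells, XB = NA_real_, PC = NA_real_, PE = NA_real_,
               SIL = NA_real_, J = NA_real_)
  for (i in seq_len(nrow(cells))) {
    fit <- fit_fcm_multistart(X, k = cells$k[i], m = cells$m[i],
                              n_restarts = n_restarts, seed = cell_seeds[i],
                              max_iter = max_iter, tol = tol)
    out$XB[i] <- xie_beni(X, fit$U, fit$C, fit$m)
    out$PC[i] <- partition_coefficient(fit$U)
    out$PE[i] <- partition_entropy(fit$U)
    out$SIL[i] <- tryCatch(
      silhouette_index(X, fit$U, fuzzy = fuzzy_silhouette,
                       dist_matrix = Dmat),
      error = function(e) {
        warning(sprintf("silhouette missing at m=%.2g, k=%d: %s",
                        cells$m[i], cells$k[i], conditionMessage(e)))
        NA_real_
      })
    out$J[i] <- fit$J
    if (keep_fits) fits[[i]] <- fit
  }
  if (keep_fits) {
    names(fits) <- sprintf("m=%g,k=%d", cells$m, cells$k)
    attr(out, "fits") <- fits
  }
  class(out) <- c("fcm_index_table", class(out))
  out
}

#' Retrieve the stored best fit for one grid cell
#'
#' @param table an `fcm_index_table` from [grid_search()] with kept fits.
#' @param m,k the grid cell.
#' @export
get_fit <- function(table, m, k) {
  fits <- attr(table, "fits")
  if (is.null(fits)) stop("grid_search() was run with keep_fits = FALSE")
  key <- sprintf("m=%g,k=%d", m, k)
  if (is.null(fits[[key]])) stop("no fit stored for ", key)
  fits[[key]]
}

# smaller-is-better flag per index
.index_direction <- c(XB = -1, PC = 1, PE = -1, SIL = 1)

.optimal_cell <- function(table, index, rows = seq_len(nrow(table))) {
  vals <- table[[index]][rows]
  ok <- which(!is.na(vals))
  if (length(ok) == 0) return(NULL)
  score <- vals[ok] * .index_direction[[index]]
  rows[ok[which.max(score)]]
}

#' Select the fuzziness parameter from an index table
#'
#' Each validity index votes with the `m` of the grid cell where it attains
#' its optimum (minimum for Xie-Beni and partition entropy, maximum for
#' partition coefficient and silhouette). The selected `m` is the mode of
#' the four votes, ties broken towards the smaller `m`.
#'
#' @param table an `fcm_index_table`.
#' @return List with `optimal_m` and the per-index `votes` (named numeric).
#' @export
select_m <- function(table) {
  votes <- vapply(names(.index_direction), function(ix) {
    cell <- .optimal_cell(table, ix)
    if (is.null(cell)) NA_real_ else table$m[cell]
  }, numeric(1))
  list(optimal_m = .mode_smallest(votes), votes = votes)
}

#' Select the cluster count at a fixed fuzziness parameter
#'
#' Restricted to the rows with `m == m_star`, each index votes with its
#' optimizing `k`; the selected `k` is the mode of the votes, ties broken
#' towards the smaller `k`.
#'
#' @param table an `fcm_index_table`.
#' @param m_star the chosen fuzziness parameter (must be in the grid).
#' @return List with `optimal_k` (integer) and per-index `votes`.
#' @export
select_k <- function(table, m_star) {
  rows <- which(abs(table$m - m_star) < 1e-8)
  if (length(rows) == 0) stop("no grid rows at m = ", m_star)
  votes <- vapply(names(.index_direction), function(ix) {
    cell <- .optimal_cell(table, ix, rows)
    if (is.null(cell)) NA_real_ else table$k[cell]
  }, numeric(1))
  list(optimal_k = as.integer(.mode_smallest(votes)), votes = votes)
}

#' Two-stage model selection
#'
#' Convenience wrapper: [select_m()] then [select_k()] at the chosen m.
#'
#' @param table an `fcm_index_table`.
#' @return List with `optimal_m`, `optimal_k`, `m_votes`, `k_votes`.
#' @export
select_model <- function(table) {
  sm <- select_m(table)
  sk <- select_k(table, sm$optimal_m)
  list(optimal_m = sm$optimal_m, optimal_k = sk$optimal_k,
       m_votes = sm$votes, k_votes = sk$votes)
}

# mode of a numeric vector, NA dropped; ties -> smallest value
.mode_smallest <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no votes available")
  tab <- table(x)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  min(winners)
}
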