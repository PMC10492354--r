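# all permutations of 1:n (n small); used for exact cluster matching
.perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))))
}

#' Match fitted clusters to planted prototypes
#'
#' Finds the cluster-to-prototype mapping maximizing agreement between
#' hardened cluster labels and planted pure labels. Exact over all
#' permutations when the count is small (factorial at most 5040), greedy on
#' the confusion matrix otherwise. Requires as many clusters as prototypes.
#'
#' @param labels integer vector of hardened cluster labels for pure patients.
#' @param planted integer vector of planted prototype indices, same length.
#' @param k number of clusters (= number of prototypes).
#' @return Integer vector `map` with `map[cluster] = prototype`.
#' @export
match_clusters <- function(labels, planted, k) {
  stopifnot(length(labels) == length(planted))
  conf <- table(factor(labels, levels = seq_len(k)),
                factor(planted, levels = seq_len(k)))
  if (factorial(k) <= 5040) {
    P <- .perms(k)
    scores <- apply(P, 1, function(perm) sum(conf[cbind(seq_len(k), perm)]))
    as.integer(P[which.max(scores), ])
  } else {
    map <- integer(k)
    C <- as.matrix(conf)
    for (step in seq_len(k)) {
      ij <- arrayInd(which.max(C), dim(C))
      map[ij[1]] <- ij[2]
      C[ij[1], ] <- -1; C[, ij[2]] <- -1
    }
    map
  }
}

#' Planted-structure recovery rates
#'
#' Given a fit's membership matrix, the generator's ground truth, and the
#' raw (pre-size-filter) banding assignment, computes: the adjusted Rand
#' index of hardened labels against planted prototypes on pure patients
#' (after optimal cluster matching the ARI is matching-invariant); the
#' fraction of pure patients assigned to the full-membership subgroup of
#' their planted cluster; and the fraction of blended patients assigned to
#' a two-cluster combination subgroup of exactly their planted pair.
#'
#' @param U membership matrix with patient ids as row names.
#' @param truth ground-truth data frame (`patient_id`, `prototype_1`,
#'   `prototype_2`).
#' @param assignment raw `subgroup_assignment` on the same `U` (computed if
#'   missing).
#' @return List: `map` (cluster to prototype), `ari_pure`,
#'   `pure_full_rate`, `blend_pair_rate`, and the counts involved.
#' @export
planted_recovery <- function(U, truth, assignment = NULL) {
  U <- as.matrix(U)
  k <- ncol(U)
  if (is.null(assignment)) assignment <- assign_subgroups(U)
  ids <- rownames(U)
  stopifnot(!is.null(ids), all(truth$patient_id %in% ids))
  tr <- truth[match(ids, truth$patient_id), ]
  pure <- is.na(tr$prototype_2)
  labels <- harden(U)
  map <- match_clusters(labels[pure], tr$prototype_1[pure], k)
  ari <- mclust::adjustedRandIndex(labels[pure], tr$prototype_1[pure])
  pts <- assignment$patients[match(ids, assignment$patients$patient_id), ]
  # clusters involved in each patient's band pattern, mapped to prototypes
  pat_cl <- lapply(pts$pattern, .pattern_clusters)
  mapped <- lapply(pat_cl, function(cl) sort(map[cl]))
  is_full <- grepl("FULL", pts$pattern)
  pure_full <- pure & is_full &
    vapply(seq_along(mapped), function(i)
      length(mapped[[i]]) == 1 && mapped[[i]] == tr$prototype_1[i],
      logical(1))
  two_combo <- !is_full & lengths(mapped) == 2
  blend_pair <- !pure & two_combo &
    vapply(seq_along(mapped), function(i)
      length(mapped[[i]]) == 2 &&
        all(mapped[[i]] == sort(c(tr$prototype_1[i], tr$prototype_2[i]))),
      logical(1))
  list(map = map,
       ari_pure = ari,
       pure_full_rate = sum(pure_full) / sum(pure),
       blend_pair_rate = if (any(!pure)) sum(blend_pair) / sum(!pure) else NA,
       n_pure = sum(pure), n_blend = sum(!pure))
}
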