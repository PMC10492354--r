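#' Observed and expected specialty prevalence per cluster
#'
#' For specialty x and cluster y, the observed prevalence is the
#' membership-weighted within-cluster prevalence
#' \deqn{O_{xy} = \sum_i u_{iy} X_{ix} / \sum_i u_{iy},}
#' the expected prevalence is the overall sample prevalence
#' \eqn{E_x = \sum_i X_{ix} / n}, and the O/E ratio is their quotient. With
#' `weighting = "hardened"` the crisp variant is computed instead: patients
#' are assigned to their maximal-membership cluster and \eqn{O_{xy}} is the
#' ordinary contingency-table prevalence. Both coincide for crisp
#' memberships.
#'
#' @param U membership matrix, n patients x k clusters, rows summing to 1.
#' @param X binary involvement matrix, n patients x p specialties, sharing
#'   the patient order of `U`.
#' @param weighting `"membership"` (default) or `"hardened"`.
#' @return List with `oe` (p x k matrix of O/E ratios), `observed` (p x k),
#'   `expected` (length-p vector), and `n_x` (patients per specialty).
#'   Specialty names from `colnames(X)` carry through.
#' @export
observed_expected <- function(U, X, weighting = c("membership", "hardened")) {
  weighting <- match.arg(weighting)
  U <- as.matrix(U); X <- as.matrix(X)
  stopifnot(nrow(U) == nrow(X))
  n <- nrow(X)
  E <- colSums(X) / n
  if (any(E == 0))
    stop("specialty with zero involvement: expected prevalence undefined")
  W <- if (weighting == "membership") U else
    outer(harden(U), seq_len(ncol(U)), "==") + 0
  O <- t(t(crossprod(X, W)) / colSums(W))   # p x k
  oe <- O / E
  dimnames(oe) <- dimnames(O) <-
    list(colnames(X), paste0("cluster_", seq_len(ncol(U))))
  list(oe = oe, observed = O, expected = stats::setNames(E, colnames(X)),
       n_x = stats::setNames(colSums(X), colnames(X)))
}

#' Exclusivity ratio of each specialty for each cluster
#'
#' \deqn{EX_{xy} = \Big(\sum_{i:\, X_{ix} = 1} u_{iy}\Big) / n_x,}
#' the cluster's share of the total membership mass carried by the patients
#' with specialty x involved (\eqn{n_x} of them). Because each patient's
#' memberships sum to 1, each specialty's exclusivities sum to 1 across
#' clusters.
#'
#' @inheritParams observed_expected
#' @return p x k matrix of exclusivity ratios in (0, 1).
#' @export
exclusivity <- function(U, X) {
  U <- as.matrix(U); X <- as.matrix(X)
  stopifnot(nrow(U) == nrow(X))
  n_x <- colSums(X)
  if (any(n_x == 0)) stop("specialty involved for no patient: n_x = 0")
  EX <- crossprod(X, U) / n_x
  dimnames(EX) <- list(colnames(X), paste0("cluster_", seq_len(ncol(U))))
  EX
}

#' Label clusters by their characterizing specialties
#'
#' A specialty characterizes a cluster when its O/E ratio is at least
#' `oe_threshold` (default 2) or its exclusivity at least `ex_threshold`
#' (default 0.25); both thresholds are inclusive. Each cluster's label lists
#' its characterizing specialties in descending O/E order; a cluster with no
#' characterizing specialty gets an empty label and a warning.
#'
#' @param oe p x k matrix of O/E ratios (rownames = specialties).
#' @param ex p x k matrix of exclusivity ratios, aligned with `oe`.
#' @param oe_threshold,ex_threshold inclusive thresholds.
#' @return Named list, one character vector of specialties per cluster.
#' @export
label_clusters <- function(oe, ex, oe_threshold = 2, ex_threshold = 0.25) {
  stopifnot(identical(dim(oe), dim(ex)))
  labels <- lapply(seq_len(ncol(oe)), function(y) {
    hit <- which(oe[, y] >= oe_threshold | ex[, y] >= ex_threshold)
    hit <- hit[order(-oe[hit, y], rownames(oe)[hit])]
    rownames(oe)[hit]
  })
  names(labels) <- colnames(oe)
  empty <- vapply(labels, length, integer(1)) == 0
  if (any(empty))
    warning("clusters with no characterizing specialty: ",
            paste(names(labels)[empty], collapse = ", "))
  labels
}

#' Characterize all clusters of a fit
#'
#' Convenience wrapper combining [observed_expected()], [exclusivity()] and
#' [label_clusters()].
#'
#' @inheritParams observed_expected
#' @inheritParams label_clusters
#' @return List of class `cluster_characterization`: `oe`, `observed`,
#'   `expected`, `n_x`, `exclusivity`, `labels`.
#' @export
characterize_clusters <- function(U, X, oe_threshold = 2, ex_threshold = 0.25,
                                  weighting = c("membership", "hardened")) {
  oem <- observed_expected(U, X, weighting = match.arg(weighting))
  ex <- exclusivity(U, X)
  labels <- label_clusters(oem$oe, ex, oe_threshold, ex_threshold)
  structure(c(oem, list(exclusivity = ex, labels = labels)),
            class = "cluster_characterization")
}

#' @export
print.cluster_characterization <- function(x, ...) {
  cat("Cluster characterization (", nrow(x$oe), " specialties, ",
      ncol(x$oe), " clusters)\n", sep = "")
  for (y in names(x$labels)) {
    lab <- if (length(x$labels[[y]])) paste(x$labels[[y]], collapse = " / ")
           else "(none)"
    cat("  ", y, ": ", lab, "\n", sep = "")
  }
  invisible(x)
}
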