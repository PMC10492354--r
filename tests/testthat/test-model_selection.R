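test_that("partition coefficient and entropy: limits and hand values", {
  for (k in c(2, 6, 15)) {
    crisp <- outer(rep(1:k, length.out = 3 * k), 1:k, "==") + 0
    expect_equal(partition_coefficient(crisp), 1, tolerance = 1e-12)
    expect_equal(partition_entropy(crisp), 0, tolerance = 1e-12)
    unif <- matrix(1 / k, 7, k)
    expect_equal(partition_coefficient(unif), 1 / k, tolerance = 1e-12)
    expect_equal(partition_entropy(unif), log(k), tolerance = 1e-12)
  }
  U <- matrix(c(0.8, 0.2), 1, 2)
  expect_equal(partition_coefficient(U), 0.68)
  expect_equal(partition_entropy(U), -(0.8 * log(0.8) + 0.2 * log(0.2)))
})

test_that("PC and PE bounds and coherence hold for fitted memberships", {
  blobs <- two_blob_data(n = 60, p = 4)
  for (k in 2:4) for (m in c(1.1, 2)) {
    fit <- fit_fcm(blobs$X, k, m, init_seed = k * 10 + m)
    pc <- partition_coefficient(fit$U)
    pe <- partition_entropy(fit$U)
    expect_gte(pc, 1 / k); expect_lte(pc, 1)
    expect_gte(pe, 0); expect_lte(pe, log(k))
    # PC = 1 iff PE = 0
    expect_equal(isTRUE(all.equal(pc, 1)), isTRUE(all.equal(pe, 0)))
  }
})

test_that("Xie-Beni index: hand value, scale invariance, degeneracy", {
  # two singleton clusters sitting on their centroids: zero numerator
  X <- rbind(c(0, 0), c(3, 4))
  U <- diag(2)
  expect_equal(xie_beni(X, U, X, m = 2), 0)
  # hand instance: 4 points, k = 2
  X <- rbind(c(0, 0), c(1, 0), c(4, 0), c(5, 0))
  U <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.1, 0.9))
  C <- rbind(c(0.5, 0), c(4.5, 0))
  m <- 2
  J <- sum(U^m * cbind(rowSums(t(t(X) - C[1, ])^2),
                       rowSums(t(t(X) - C[2, ])^2)))
  expect_equal(xie_beni(X, U, C, m), J / (4 * sum((C[1, ] - C[2, ])^2)))
  # multiplying all coordinates by s leaves the ratio unchanged
  for (s in c(0.5, 3)) expect_equal(xie_beni(s * X, U, s * C, m),
                                    xie_beni(X, U, C, m))
  expect_error(xie_beni(X, U, rbind(C[1, ], C[1, ]), m), "identical")
})

test_that("silhouette matches brute force and the cluster package", {
  # two tight far-separated pairs of identical points: a = 0, s -> 1
  X <- rbind(c(0, 0), c(0, 0), c(100, 0), c(100, 0))
  U <- outer(c(1, 1, 2, 2), 1:2, "==") + 0
  expect_gt(silhouette_index(X, U), 0.99)
  # rectangle tuned so a = b for every point (within 4, across mean 4): s = 0
  X <- rbind(c(0, 0), c(4, 0), c(0, 3), c(4, 3))
  U <- outer(c(1, 1, 2, 2), 1:2, "==") + 0
  expect_equal(silhouette_index(X, U), 0)
  # 5-point hand instance vs exhaustive pairwise oracle
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(6, 5))
  U <- outer(c(1, 1, 1, 2, 2), 1:2, "==") + 0
  expect_equal(silhouette_index(X, U), bf_silhouette(X, c(1, 1, 1, 2, 2)))
  # random fuzzy memberships, hardened: oracle + reference implementation
  set.seed(4)
  X <- matrix(rnorm(80), 40, 2)
  U <- rand_U(40, 3)
  lab <- harden(U)
  expect_equal(silhouette_index(X, U), bf_silhouette(X, lab))
  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(lab, stats::dist(X))
  expect_equal(silhouette_index(X, U), mean(ref[, "sil_width"]))
  # degenerate single hardened cluster
  expect_error(silhouette_index(X, matrix(c(0.9, 0.1), 40, 2, byrow = TRUE)),
               "silhouette undefined")
})

test_that("grid_search covers the grid deterministically", {
  blobs <- two_blob_data(n = 60, p = 6)
  tab <- grid_search(blobs$X, m_grid = c(1.2, 1.4), k_grid = 2:4,
                     n_restarts = 3, seed = 8)
  expect_equal(nrow(tab), 6)
  expect_false(anyNA(tab$J))
  tab2 <- grid_search(blobs$X, m_grid = c(1.2, 1.4), k_grid = 2:4,
                      n_restarts = 3, seed = 8)
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
  # a 1-cell grid equals direct evaluation of the stored fit
  one <- grid_search(blobs$X, m_grid = 1.3, k_grid = 2, n_restarts = 3,
                     seed = 8)
  fit <- get_fit(one, 1.3, 2)
  expect_equal(one$XB, xie_beni(blobs$X, fit$U, fit$C, 1.3))
  expect_equal(one$PC, partition_coefficient(fit$U))
  expect_equal(one$PE, partition_entropy(fit$U))
  expect_equal(one$SIL, silhouette_index(blobs$X, fit$U))
  expect_equal(one$J, fit$J)
})

# build an index table whose per-index optima sit at chosen (m, k) cells
fake_table <- function(opt) {  # opt: list(XB=c(m,k), PC=..., PE=..., SIL=...)
  grid <- expand.grid(k = 4:8, m = c(1.1, 1.3, 1.5))[, c("m", "k")]
  tab <- grid
  tab$XB <- 1; tab$PE <- 1; tab$PC <- 0; tab$SIL <- 0; tab$J <- 1
  hit <- function(ix) which(grid$m == opt[[ix]][1] & grid$k == opt[[ix]][2])
  tab$XB[hit("XB")] <- 0; tab$PE[hit("PE")] <- 0
  tab$PC[hit("PC")] <- 1; tab$SIL[hit("SIL")] <- 1
  class(tab) <- c("fcm_index_table", class(tab))
  tab
}

test_that("select_m takes the mode of the per-index optima, ties small", {
  tab <- fake_table(list(XB = c(1.1, 5), PC = c(1.1, 7),
                         PE = c(1.1, 6), SIL = c(1.1, 4)))
  expect_equal(select_m(tab)$optimal_m, 1.1)
  tab <- fake_table(list(XB = c(1.1, 5), PC = c(1.1, 7),
                         PE = c(1.3, 6), SIL = c(1.5, 4)))
  sel <- select_m(tab)
  expect_equal(sel$optimal_m, 1.1)
  expect_equal(sort(unname(sel$votes)), c(1.1, 1.1, 1.3, 1.5))
  # two-two tie resolved towards the smaller m
  tab <- fake_table(list(XB = c(1.1, 5), PC = c(1.3, 7),
                         PE = c(1.1, 6), SIL = c(1.3, 4)))
  expect_equal(select_m(tab)$optimal_m, 1.1)
})

test_that("select_k votes at the chosen m, ties small, handles NA", {
  tab <- fake_table(list(XB = c(1.1, 6), PC = c(1.1, 6),
                         PE = c(1.1, 6), SIL = c(1.1, 8)))
  expect_equal(select_k(tab, 1.1)$optimal_k, 6L)
  tab <- fake_table(list(XB = c(1.1, 5), PC = c(1.1, 6),
                         PE = c(1.1, 6), SIL = c(1.1, 5)))
  expect_equal(select_k(tab, 1.1)$optimal_k, 5L)
  # single-k grid returns that k
  one <- fake_table(list(XB = c(1.1, 5), PC = c(1.1, 5),
                         PE = c(1.1, 5), SIL = c(1.1, 5)))
  one <- one[one$k == 5, ]
  class(one) <- c("fcm_index_table", class(one))
  expect_equal(select_k(one, 1.1)$optimal_k, 5L)
  # a missing silhouette is excluded from the vote
  tab <- fake_table(list(XB = c(1.1, 6), PC = c(1.1, 7),
                         PE = c(1.1, 6), SIL = c(1.1, 4)))
  tab$SIL <- NA_real_
  sel <- select_k(tab, 1.1)
  expect_true(is.na(sel$votes[["SIL"]]))
  expect_equal(sel$optimal_k, 6L)
})

test_that("model selection recovers a small planted cluster count", {
  cfg <- generator_config(n_patients = 400, n_prototypes = 3,
                          signature_size = 4, blend_fraction = 0,
                          high_prob = 0.95, low_prob = 0.03, seed = 13)
  sim <- simulate_cohort(cfg)
  X <- build_involvement_matrix(apply_inclusion_filter(sim$encounters))
  tab <- grid_search(X, m_grid = c(1.2, 1.4), k_grid = 2:5,
                     n_restarts = 5, seed = 14)
  sel <- select_model(tab)
  expect_equal(sel$optimal_k, 3L)
})
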