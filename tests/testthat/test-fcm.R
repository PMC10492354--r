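test_that("fcm_cost matches direct summation and its limits", {
  # single patient at its sole... (k >= 2 enforced elsewhere; cost itself is
  # defined for any k): point on a centroid contributes zero
  X <- matrix(c(1, 2), 1, 2)
  U <- matrix(c(1, 0), 1, 2)
  C <- rbind(c(1, 2), c(5, 5))
  expect_equal(fcm_cost(X, U, C, m = 2), 0)

  # crisp memberships: cost is the within-cluster sum of squares for any m
  set.seed(1)
  X <- matrix(rnorm(12), 6, 2)
  lab <- c(1, 1, 1, 2, 2, 2)
  U <- outer(lab, 1:2, "==") + 0
  C <- rbind(colMeans(X[1:3, ]), colMeans(X[4:6, ]))
  wss <- sum((X - C[lab, ])^2)
  for (m in c(1.1, 2, 5)) expect_equal(fcm_cost(X, U, C, m), wss)

  # hand instance: brute-force double loop
  X <- rbind(c(0, 0), c(1, 0), c(0, 2))
  U <- rbind(c(0.7, 0.3), c(0.4, 0.6), c(0.5, 0.5))
  C <- rbind(c(0.2, 0.1), c(0.8, 0.9))
  m <- 1.5
  J <- 0
  for (i in 1:3) for (j in 1:2)
    J <- J + U[i, j]^m * sum((X[i, ] - C[j, ])^2)
  expect_equal(fcm_cost(X, U, C, m), J)
  expect_error(fcm_cost(X, U[, 1, drop = FALSE], C, m), "dimension")
})

test_that("membership update obeys the closed form and degeneracies", {
  # equidistant from both centroids
  U <- update_memberships(matrix(0, 1, 1), rbind(-1, 1), m = 2)
  expect_equal(c(U), c(0.5, 0.5))
  # exactly on one centroid: crisp degenerate row
  U <- update_memberships(matrix(c(-1), 1, 1), rbind(-1, 1), m = 2)
  expect_equal(c(U), c(1, 0))
  # coincident with several centroids: equal split among them
  U <- update_memberships(matrix(0, 1, 1), rbind(0, 0, 5), m = 2)
  expect_equal(c(U), c(0.5, 0.5, 0))
  # 1D closed form: x = 0, centroids -1 and +2, m = 2 -> (4/5, 1/5)
  U <- update_memberships(matrix(0, 1, 1), rbind(-1, 2), m = 2)
  expect_equal(c(U), c(4 / 5, 1 / 5))
  expect_equal(rowSums(update_memberships(matrix(rnorm(10), 5, 2),
                                          rbind(c(0, 0), c(1, 1)), 1.3)),
               rep(1, 5))
})

test_that("centroid update is the u^m-weighted mean", {
  set.seed(2)
  X <- matrix(rnorm(8), 4, 2)
  # crisp: per-cluster arithmetic means
  U <- outer(c(1, 1, 2, 2), 1:2, "==") + 0
  C <- update_centroids(X, U, m = 1.7)
  expect_equal(unname(C), rbind(colMeans(X[1:2, ]), colMeans(X[3:4, ])))
  # uniform: every centroid at the global mean
  U <- matrix(0.5, 4, 2)
  C <- update_centroids(X, U, m = 2)
  expect_equal(unname(C), rbind(colMeans(X), colMeans(X)))
  # hand-weighted mean at m = 1.5
  U <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.3, 0.7), c(0.2, 0.8))
  m <- 1.5
  C <- update_centroids(X, U, m)
  for (j in 1:2) {
    w <- U[, j]^m
    expect_equal(unname(C[j, ]), colSums(w * X) / sum(w))
  }
})

test_that("fit_fcm separates planted clouds, descends, and is stationary", {
  blobs <- two_blob_data(n = 80, p = 6, flip = 0.02)
  fit <- fit_fcm(blobs$X, k = 2, m = 1.3, init_seed = 7)
  expect_true(fit$converged)
  # hardened labels split the clouds exactly (up to label swap)
  lab <- harden(fit$U)
  expect_true(mclust::adjustedRandIndex(lab, blobs$labels) == 1)
  # cost sequence is monotone non-increasing
  expect_true(all(diff(fit$cost_trace) <= 1e-10))
  # recorded J equals a recomputation of the cost
  expect_equal(fit$J, fcm_cost(blobs$X, fit$U, fit$C, fit$m), tolerance = 1e-8)
  # determinism
  fit2 <- fit_fcm(blobs$X, k = 2, m = 1.3, init_seed = 7)
  expect_identical(fit$U, fit2$U)
  # stationarity: one more sweep moves memberships by < 10 * tol
  C2 <- update_centroids(blobs$X, fit$U, fit$m)
  U2 <- update_memberships(blobs$X, C2, fit$m)
  expect_lt(max(abs(U2 - fit$U)), 10 * 1e-6)
  expect_error(fit_fcm(blobs$X[1, , drop = FALSE], k = 2, m = 1.5), "n < k")
})

test_that("membership rows are row-stochastic and strictly inside (0,1)", {
  blobs <- two_blob_data(n = 60, p = 6)
  for (m in c(1.1, 1.5, 3)) {
    fit <- fit_fcm(blobs$X, k = 3, m = m, init_seed = 11)
    expect_lt(max(abs(rowSums(fit$U) - 1)), 1e-9)
    degenerate <- rowSums(fit$U == 0 | fit$U == 1) > 0
    expect_true(all(fit$U[!degenerate, ] > 0 & fit$U[!degenerate, ] < 1))
  }
})

test_that("permutation of patients permutes memberships identically", {
  set.seed(3)
  X <- matrix(rnorm(30), 15, 2)
  C <- rbind(c(-1, 0), c(1, 0))
  U <- update_memberships(X, C, 1.4)
  perm <- sample(15)
  expect_equal(update_memberships(X[perm, ], C, 1.4), U[perm, ])
  expect_equal(update_centroids(X[perm, ], U[perm, ], 1.4),
               update_centroids(X, U, 1.4))
})

test_that("multistart returns the minimum over restarts, reproducibly", {
  blobs <- two_blob_data(n = 40, p = 4)
  fit <- fit_fcm_multistart(blobs$X, k = 2, m = 1.2, n_restarts = 8, seed = 5)
  expect_equal(fit$J, min(fit$restart_costs))
  expect_true(all(fit$J <= fit$restart_costs))
  fitb <- fit_fcm_multistart(blobs$X, k = 2, m = 1.2, n_restarts = 8, seed = 5)
  expect_identical(fit$U, fitb$U)
  # single-restart multistart == fit_fcm with the derived seed
  one <- fit_fcm_multistart(blobs$X, k = 2, m = 1.2, n_restarts = 1, seed = 5)
  expect_identical(one$J, fit_fcm(blobs$X, k = 2, m = 1.2,
                                  init_seed = one$seed_used)$J)
})

test_that("fitted solution agrees with an independent FCM implementation", {
  skip_if_not_installed("e1071")
  blobs <- two_blob_data(n = 100, p = 6)
  m <- 1.6
  mine <- fit_fcm_multistart(blobs$X, k = 2, m = m, n_restarts = 10, seed = 9)
  ref <- e1071::cmeans(blobs$X, centers = 2, m = m, iter.max = 300)
  J_ref <- fcm_cost(blobs$X, ref$membership, ref$centers, m)
  expect_equal(mine$J, J_ref, tolerance = 1e-4)
  expect_equal(mclust::adjustedRandIndex(harden(mine$U), ref$cluster), 1)
})

test_that("fuzziness limits: near-crisp at small m, flatter at large m", {
  blobs <- two_blob_data(n = 100, p = 6)
  crisp <- fit_fcm_multistart(blobs$X, k = 2, m = 1.05, n_restarts = 5, seed = 2)
  km <- stats::kmeans(blobs$X, centers = 2, nstart = 10)
  expect_equal(mclust::adjustedRandIndex(harden(crisp$U), km$cluster), 1)
  # growing m flattens memberships monotonically towards 1/k
  devs <- vapply(c(1.1, 2, 10), function(m)
    max(abs(fit_fcm_multistart(blobs$X, k = 2, m = m, n_restarts = 5,
                               seed = 2)$U - 0.5)), numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_gt(devs[1], 0.45)   # near-crisp at m = 1.1
  expect_lt(devs[3], 0.35)   # strongly flattened at m = 10
  # and the large-m solution agrees with an independent implementation
  skip_if_not_installed("e1071")
  flat <- fit_fcm_multistart(blobs$X, k = 2, m = 10, n_restarts = 10, seed = 2)
  set.seed(3)
  ref <- e1071::cmeans(blobs$X, centers = 2, m = 10, iter.max = 500)
  expect_equal(flat$J, fcm_cost(blobs$X, ref$membership, ref$centers, 10),
               tolerance = 1e-5)
})
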