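#!/usr/bin/env Rscript

# Step 3 — hyperparameter grid search and model selection.
#
# For every (m, k) on the grid, fits fuzzy c-means with 20 independent
# restarts (keeping the minimum-cost run) and evaluates the Xie-Beni
# index, partition coefficient, partition entropy, and silhouette. The
# fuzziness parameter is selected first (mode of the four indices' global
# optima), then the cluster count at that m.

library(morbclust)

seed <- 1L
X <- read_cohort_matrix("results/cohort_matrix.csv")
tab <- grid_search(X, m_grid = c(1.1, 1.3, 1.5), k_grid = 4:9,
                   n_restarts = 20, seed = seed + 2L)
utils::write.csv(as.data.frame(tab), "results/validity_indices.csv",
                 row.names = FALSE)
sel <- select_model(tab)
cat(sprintf("Selected m = %.1f (votes: %s)\n", sel$optimal_m,
            paste(names(sel$m_votes), sel$m_votes, sep = "=", collapse = ", ")))
cat(sprintf("Selected k = %d (votes: %s)\n", sel$optimal_k,
            paste(names(sel$k_votes), sel$k_votes, sep = "=", collapse = ", ")))

fit <- get_fit(tab, sel$optimal_m, sel$optimal_k)
U <- data.frame(patient_id = rownames(fit$U), fit$U, check.names = FALSE)
names(U)[-1] <- paste0("cluster_", seq_len(fit$k))
utils::write.csv(U, "results/memberships.csv", row.names = FALSE)
utils::write.csv(data.frame(cluster = seq_len(fit$k), fit$C,
                            check.names = FALSE),
                 "results/centroids.csv", row.names = FALSE)
meta <- list(optimal_m = sel$optimal_m, optimal_k = sel$optimal_k,
             m_votes = as.list(sel$m_votes), k_votes = as.list(sel$k_votes),
             J = fit$J, n_iter = fit$n_iter, converged = fit$converged,
             seed_used = fit$seed_used)
jsonlite::write_json(meta, "results/selection.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("Best fit: J = %.2f after %d iterations.\n", fit$J, fit$n_iter))
cat("Wrote results/validity_indices.csv, memberships.csv, centroids.csv, selection.json\n")
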