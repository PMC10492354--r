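#!/usr/bin/env Rscript

# Step 4 — cluster characterization.
#
# Computes membership-weighted observed/expected prevalence ratios and
# exclusivity ratios per (specialty, cluster) and labels each cluster by
# the specialties with O/E >= 2 or exclusivity >= 25%.

library(morbclust)

X <- read_cohort_matrix("results/cohort_matrix.csv")
Ud <- utils::read.csv("results/memberships.csv", check.names = FALSE)
U <- as.matrix(Ud[, -1])
rownames(U) <- Ud$patient_id
stopifnot(identical(rownames(U), rownames(X)))

chr <- characterize_clusters(U, X)
utils::write.csv(data.frame(specialty = rownames(chr$oe), chr$oe,
                            check.names = FALSE),
                 "results/oe_ratios.csv", row.names = FALSE)
utils::write.csv(data.frame(specialty = rownames(chr$exclusivity),
                            chr$exclusivity, check.names = FALSE),
                 "results/exclusivity_ratios.csv", row.names = FALSE)
jsonlite::write_json(chr$labels, "results/cluster_labels.json",
                     auto_unbox = FALSE)
print(chr)
cat("Wrote results/oe_ratios.csv, exclusivity_ratios.csv, cluster_labels.json\n")
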