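#!/usr/bin/env Rscript

# Step 1 — simulate the study cohort.
#
# The restricted hospital extract is emulated by a synthetic cohort of
# 5,000 adult patients with multimorbidity: six planted prototype patterns
# of specialty involvement over the 22-specialty catalog, 20% of patients
# blending two prototypes, Bernoulli involvement noise, and per-patient
# demographics and care-activity counts. Sixty patients violating the
# inclusion criteria are appended to exercise the filter downstream.

library(morbclust)

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(n_patients = 5000, seed = seed)
sim <- simulate_cohort(cfg)
enc <- inject_subthreshold_patients(sim$encounters, 60, seed = seed + 1L)

utils::write.csv(enc, "results/encounters.csv", row.names = FALSE)
write_ground_truth(sim$truth, "results/ground_truth.csv")

cat(sprintf("Simulated %d eligible patients (%d encounter rows) + 60 sub-threshold patients.\n",
            length(unique(sim$encounters$patient_id)), nrow(sim$encounters)))
cat(sprintf("Blended patients: %d (%.1f%%).\n",
            sum(!is.na(sim$truth$prototype_2)),
            100 * mean(!is.na(sim$truth$prototype_2))))
cat("Wrote results/encounters.csv and results/ground_truth.csv\n")
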