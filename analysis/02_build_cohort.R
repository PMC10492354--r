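#!/usr/bin/env Rscript

# Step 2 — inclusion filter and involvement matrix.
#
# Retains adults (18+) with two or more chronic and/or oncological
# diagnoses under outpatient care, then builds the patient x specialty
# binary involvement matrix that is the clustering feature space, plus a
# small baseline-characteristics table.

library(morbclust)

enc_all <- read_encounters("results/encounters.csv")
enc <- apply_inclusion_filter(enc_all)
X <- build_involvement_matrix(enc)
write_cohort_matrix(X, "results/cohort_matrix.csv")

n_all <- length(unique(enc_all$patient_id))
n <- nrow(X)
cat(sprintf("Inclusion filter: %d of %d patients retained (%d excluded).\n",
            n, n_all, n_all - n))

ps <- patient_summary(enc)
baseline <- data.frame(
  statistic = c("n", "female_pct", "age_median", "age_iqr",
                "specialties_median", "outpatient_median", "ed_median",
                "inpatient_median", "diagnoses_median"),
  value = c(n, 100 * mean(ps$sex == "female"),
            stats::median(ps$age_years), stats::IQR(ps$age_years),
            stats::median(rowSums(X)), stats::median(ps$outpatient_visits),
            stats::median(ps$ed_visits), stats::median(ps$inpatient_days),
            stats::median(ps$n_diagnoses)))
utils::write.csv(baseline, "results/baseline.csv", row.names = FALSE)
prev <- sort(colMeans(X), decreasing = TRUE)
cat("Most involved specialties (%):\n")
print(round(100 * utils::head(prev, 5), 1))
cat("Wrote results/cohort_matrix.csv and results/baseline.csv\n")
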