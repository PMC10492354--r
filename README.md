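# morbclust

Clusters of medical specialties around patients with multimorbidity.

Hospital care is organized per specialty, but patients with multimorbidity
(two or more chronic and/or oncological diagnoses) see several specialties
at once. `morbclust` identifies *which sets of specialties are
simultaneously involved in the same patients* from routine encounter
records, for analysts and hospital teams exploring where multidisciplinary
collaboration would help. The pipeline:

1. **Cohort construction** — read long-format patient–specialty–diagnosis
   records, apply the multimorbidity inclusion filter (adults with ≥ 2
   chronic/oncological diagnoses under outpatient care), and build the
   patient × specialty binary involvement matrix.
2. **Fuzzy c-means** — soft-cluster patients by minimizing the Bezdek cost
   *J(U, C; m) = Σᵢ Σⱼ uᵢⱼᵐ ‖xᵢ − cⱼ‖²* with alternating first-order
   updates and multistart (100 restarts by default, minimum-cost run
   kept). Each patient gets a membership degree uᵢⱼ ∈ (0, 1) in every
   cluster, summing to 1.
3. **Model selection** — grid search over the fuzziness parameter m and
   cluster count k, scored by four validity indices (Xie–Beni, partition
   coefficient, partition entropy, silhouette); two-stage vote selects m
   first, then k at that m.
4. **Cluster characterization** — per (specialty x, cluster y) the
   observed/expected prevalence ratio (O/E)ₓᵧ = Oₓᵧ/Eₓ (membership-weighted
   within-cluster prevalence over overall prevalence) and the exclusivity
   ratio EXₓᵧ = Σ_{i: Xᵢₓ=1} uᵢᵧ / nₓ; a specialty characterizes a cluster
   when O/E ≥ 2 or EX ≥ 25%.
5. **Subgroups** — memberships banded into [80–100] (full), [60–80)
   (dominant), [40–60), [20–40), < 20% (insignificant); a five-step
   procedure assigns every patient to a band-pattern subgroup or the rest
   group, subgroups under 100 patients dissolve into the rest group, and
   each subgroup is profiled (size, memberships, demographics,
   utilization, top specialties and diagnosis groups).
6. **Synthetic cohort generator** — encounter tables with planted
   overlapping involvement structure (prototype patterns, blended
   patients, Bernoulli noise), so the whole pipeline is testable without
   restricted hospital data.

The methods vignette (`vignettes/specialty-coclustering.Rmd`) documents
the model, the numerical choices, and what the synthetic validation does
and does not show. The `analysis/` directory holds the numbered driver
scripts of the full workflow (simulate → cohort → select → characterize →
subgroups), writing tables under `results/`.

## Worked example

```r
library(morbclust)

# 1. simulate a cohort with planted structure (3 prototypes, no blends)
cfg <- generator_config(n_patients = 600, n_prototypes = 3,
                        signature_size = 4, high_prob = 0.95,
                        low_prob = 0.03, blend_fraction = 0, seed = 7)
sim <- simulate_cohort(cfg)

# 2. inclusion filter and involvement matrix
enc <- apply_inclusion_filter(sim$encounters)
X <- build_involvement_matrix(enc)
dim(X)
#> [1] 600  22

# 3. grid search and two-stage model selection
tab <- grid_search(X, m_grid = c(1.1, 1.3), k_grid = 2:5,
                   n_restarts = 10, seed = 8)
sel <- select_model(tab)
c(m = sel$optimal_m, k = sel$optimal_k)
#>   m   k
#> 1.1 3.0
sel$k_votes
#>  XB  PC  PE SIL
#>   3   2   3   3
```

Three of the four indices vote for the planted k = 3 (the partition
coefficient prefers the coarser merge; the mode rule settles it) and the
crispest fuzziness m = 1.1 is selected. At the selected model:

```r
# 4. characterize clusters at the selected model
fit <- get_fit(tab, sel$optimal_m, sel$optimal_k)
characterize_clusters(fit$U, X)
#> Cluster characterization (22 specialties, 3 clusters)
#>   cluster_1: orthopedic surgery / rheumatology / gastroenterology / urology / ...
#>   cluster_2: neurology / cardiology / internal medicine / general surgery / ...
#>   cluster_3: ophthalmology / otorhinolaryngology / pulmonology / dermatology / ...

# 5. band memberships into subgroups and profile them
named <- name_subgroups(enforce_min_size(assign_subgroups(fit$U), 25))
named
#> Subgroup assignment: 600 patients, 3 subgroups, rest group 1 (0.2%)
#>   minimum subgroup size enforced: 25
profile_subgroups(named, enc, X, fit$U)
#> Subgroup profiles (4 groups)
#>   1        n =   184  median age 67  top specialty gastroenterology
#>   2        n =   207  median age 68  top specialty cardiology
#>   3        n =   208  median age 70  top specialty dermatology
#>   REST     n =     1  median age 87  top specialty internal medicine

# 6. compare against the planted truth
rec <- planted_recovery(fit$U, sim$truth)
round(c(ari = rec$ari_pure, pure_full = rec$pure_full_rate), 3)
#>       ari pure_full
#>     1.000     0.998
```

The three characterizing-specialty lists are exactly the planted
signature blocks (each prototype's four signature specialties head its
cluster's O/E ranking), the hardened labels match the planted labels
perfectly (adjusted Rand index 1.0), and 99.8% of patients fall in the
full-membership subgroup of their planted cluster.

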