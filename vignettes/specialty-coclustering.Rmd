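---
title: "Clustering medical specialty co-involvement in multimorbidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering medical specialty co-involvement in multimorbidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospital care is organized around medical specialties, but patients with
multimorbidity — two or more chronic and/or oncological diagnoses — are
treated by several specialties at once. Knowing *which sets of specialties
are simultaneously involved in the same patients*, and for how many
patients, points to where multidisciplinary collaboration would pay off.
`morbclust` implements that analysis as a reusable pipeline: build a
patient × specialty binary involvement matrix from encounter-level
records, soft-cluster the patients, select the model with validity
indices, describe each cluster by the specialties that characterize it,
and enumerate patient subgroups from the membership degrees.

Because hospital billing extracts of this kind cannot be shared, the
package ships a synthetic cohort generator with *planted* overlapping
structure, so every stage can be exercised and validated end to end.

## Cohort construction

The unit of input is one row per patient–specialty–diagnosis combination
with the diagnosis group and type and counts of outpatient visits, ED
visits, and inpatient days (`read_encounters()`). The inclusion filter
(`apply_inclusion_filter()`) retains adults (≥ 18 years) whose count of
distinct chronic-type plus oncological-type diagnoses under outpatient
care is at least two — the union of the three clinical disjuncts (two
chronic; two oncological; one of each).

Two operationalizations are deliberate choices, exposed as switches
because encounter extracts do not pin them down:

* *"outpatient clinical care for a diagnosis"* means the diagnosis has at
  least one recorded outpatient visit (`require_outpatient_visit = TRUE`);
* diagnoses are counted as distinct *codes*; `count_level = "group"`
  counts classification groups instead. On data where several codes share
  a group the two differ, and neither is asserted as canonical.

`build_involvement_matrix()` then sets cell (i, j) to 1 iff patient i has
any encounter with specialty j, with lexicographic column order and sorted
patient ids so the matrix is reproducible byte for byte.

## Fuzzy c-means

Patients are clustered on the raw 0/1 involvement matrix with fuzzy
c-means, minimizing

$$J(U, C; m) = \sum_{i=1}^{n}\sum_{j=1}^{k} u_{ij}^{m}\,\lVert x_i - c_j\rVert^2,$$

by alternating the first-order-optimal updates for memberships and
centroids. Memberships are strictly inside (0, 1) and each row of $U$
sums to one; the single exception is a patient coinciding exactly with a
centroid, whose membership is split equally over the coincident centroids.

Numerical choices (the literature leaves them open, so they are fixed
here and documented rather than inherited silently):

* **Distance**: squared Euclidean on the unscaled binary matrix. All
  features are on the same 0/1 scale, so no standardization is applied.
* **Initialization**: a random row-stochastic membership matrix (uniform
  Dirichlet per row) rather than random centroids. Under the alternating
  scheme the two are interchangeable — the first half-step turns either
  into the other — and the membership start is numerically safer (no
  coincident random centroids).
* **Convergence**: maximum absolute membership change < `1e-6`, cap 200
  iterations. The cost sequence is non-increasing by construction and is
  recorded in the fit (`cost_trace`).
* **Restarts**: the objective is non-convex, so `fit_fcm_multistart()`
  runs 100 independent fits by default (20 in the scaled-down analysis
  scripts), with per-run seeds drawn deterministically from one master
  seed, and keeps the minimum-cost run, ties to the lowest run index.
* **Hardening** (`harden()`): maximal membership, ties to the lowest
  cluster index.

The fuzziness parameter $m$ controls softness: near 1 memberships are
pushed to 0/1 (the k-means limit — at $m = 1.05$ on separable data the
hardened labels equal Lloyd's k-means exactly), large $m$ flattens them
toward $1/k$. One caution established while validating against
`e1071::cmeans`: on *well-separated* data the flattening is slow in $m$ —
at $m = 10$ the cost-optimal solution still keeps centroids at the group
means (the $u^m$ weights re-amplify small membership differences), and
memberships deviate from $1/k$ by ~0.3. Exact agreement with the
independent implementation confirms this is a property of the objective,
not of the optimizer.

## Model selection

`grid_search()` fits every combination of a fuzziness grid (default 1.1
to 1.5 in steps of 0.1) and a cluster-count grid (default 5–15) and
evaluates four validity indices on the best run per cell: Xie–Beni
(compactness over separation, minimize), partition coefficient
(maximize), partition entropy (natural log; the base rescales but never
reorders, so selection is unaffected; minimize), and the silhouette index.
Selection is two-stage: `select_m()` lets each index vote with the $m$ of
its global optimum and takes the mode, ties to the smaller $m$;
`select_k()` repeats the vote over $k$ restricted to the chosen $m$. The
mode-with-ties-to-smaller rule is this package's reconciliation of
disagreeing indices; the votes are always reported alongside the winner
so a disagreement is visible, not hidden.

The silhouette is computed on hardened labels with plain Euclidean
distance (the classical crisp index); a membership-weighted variant is
available behind `fuzzy_silhouette = TRUE`. If a grid cell's hardened
partition collapses to one cluster, its silhouette is recorded as missing
with a warning and excluded from that index's vote.

## Characterizing clusters

For specialty $x$ and cluster $y$,

$$O_{xy} = \frac{\sum_i u_{iy} X_{ix}}{\sum_i u_{iy}}, \qquad
  E_x = \frac{\sum_i X_{ix}}{n}, \qquad
  EX_{xy} = \frac{\sum_{i:\,X_{ix}=1} u_{iy}}{n_x}.$$

The observed prevalence is membership-weighted; in the crisp limit both
$O_{xy}$ and $EX_{xy}$ reduce to ordinary contingency-table prevalences
(tested), and a hardened-counting variant is available behind
`weighting = "hardened"` since published analyses do not always state
which was used. Two exact identities are enforced in tests: each
specialty's exclusivities sum to one across clusters, and the
cluster-mass-weighted observed prevalences recover $E_x \cdot n$. A
specialty *characterizes* a cluster when $O/E \ge 2$ or $EX \ge 0.25$
(both thresholds inclusive and configurable); cluster labels list
characterizing specialties by descending O/E.

## Membership banding and subgroups

Memberships are banded into five equal intervals: full [80–100%],
dominant [60–80%), mid [40–60%), low [20–40%), insignificant (< 20%),
closed below and open above. The five-step assignment: (1) any full
membership defines the patient's subgroup outright (a patient at exactly
0.80/0.20 carries a full and a low band; full absorbs, because such
patients belong to one cluster fully); (2) else a dominant band plus any
low secondaries; (3) else all mid and low bands; (4) else all low bands;
(5) else the rest group. This sequential procedure is provably equivalent
to keying each patient by its canonical band pattern with the
full-dominance exception, and the test suite checks that equivalence
against an independently coded classifier on 10^4 random rows, exactly.
Band feasibility (no two full bands, no full plus dominant — membership
mass would exceed one) is asserted, not assumed. A dominant patient with
two exact-0.20 secondaries is keyed by its true {dominant, low, low}
pattern; such micro-patterns fall into the rest group via the size rule
in practice.

Subgroups smaller than `min_size` (default 100 patients — a feasible
target population for a hospital-level intervention) are dissolved into
the rest group. Naming follows the cluster-index convention: full
subgroups are named by their cluster ("4"); all others by their ascending
cluster indices joined by hyphens plus a letter suffix per distinct band
pattern, lettered by descending subgroup size (the suffix order is this
package's convention; ties fall back to the canonical pattern string).
Profiles report, per subgroup: n; mean (SD) membership per involved
cluster; female n (%); median (IQR, reported as the single value Q3 − Q1
under type-7 linear interpolation) of age, involved specialties,
outpatient visits, ED visits, inpatient days, and distinct diagnoses; the
top-5 specialties by % involved; and the top-10 diagnosis groups by %
affected, with alphabetical tie-breaks.

## The synthetic cohort: what it emulates, and what it does not

`generator_config()` defaults encode the study conditions: n = 5,000
patients, K = 6 planted prototypes over the 22-specialty catalog, each
prototype involving its 3 signature specialties with probability 0.9
against a 0.05 background, and 20% of patients drawn from the elementwise
mean of two prototype rows — the generative picture behind combination
subgroups, patients genuinely shared between two specialty patterns.
Involved specialties receive chronic/oncological diagnosis rows with
outpatient visits (so generated patients pass the inclusion filter by
construction), Poisson utilization counts (means 2 / 0.3 / 0.5 per
involved specialty for outpatient / ED / inpatient), age normal (68, 15)
floored at 18, and 56% female. Everything is reproducible from one seed,
and `inject_subthreshold_patients()` appends patients that must fail the
filter (minors, acute-only, no outpatient care).

The generator emulates co-involvement *structure*, not the marginal
distributions of any real hospital: real involvement prevalences are
heavily skewed, specialties correlate beyond shared cluster membership,
and utilization is over-dispersed rather than Poisson. Passing the
recovery tests therefore shows the pipeline recovers planted overlap
structure under realistic noise — it does not certify behavior on any
particular hospital's data.

At these conditions the pipeline is self-consistent end to end (problem
sizes chosen to keep the whole analysis re-runnable on a laptop): the
grid m ∈ {1.1, 1.3, 1.5} × k ∈ 4..9 with 20 restarts selects m = 1.1 and
k = 6, the hardened labels agree with the planted pure labels at
ARI ≈ 0.96, and ~97% of pure patients land in the full-membership
subgroup of their planted cluster. One structural limitation is worth
stating plainly: a blended patient draws each signature specialty of its
two prototypes with probability 0.475, so a substantial share of blends
realize an involvement vector indistinguishable from a pure patient of
one prototype (all of one signature, none of the other). Only about a
quarter of blends are *identifiably* ambiguous, and those are the ones
that land in two-cluster combination subgroups (~20% of all blends;
among blends that do land in a two-cluster subgroup, ~80% land in exactly
their planted pair). This ceiling is a property of the generative
process, not of the clustering or banding code.

## Known limitations

* The index-disagreement reconciliation (mode, ties small) is one
  defensible rule among several; with strongly disagreeing indices the
  reported votes matter more than the single winner.
* Crisp silhouette on hardened labels discards membership information;
  the fuzzy variant is provided but not the default.
* The characterization's membership-weighted observed prevalence is a
  choice; the hardened variant can differ materially at large m.
* Banding thresholds (20/40/60/80) and the 100-patient relevance rule are
  clinical conventions, configurable but not data-driven.
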