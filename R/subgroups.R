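.band_levels <- c("FULL", "DOM", "MID", "LOW", "INSIGNIFICANT")

#' Band of a membership degree
#'
#' Memberships are divided into five equal-width categories:
#' `FULL` \eqn{[0.8, 1]}, `DOM` \eqn{[0.6, 0.8)}, `MID` \eqn{[0.4, 0.6)},
#' `LOW` \eqn{[0.2, 0.4)}, and `INSIGNIFICANT` below 0.2. Intervals are
#' closed below and open above. Memberships produced by fuzzy c-means are
#' strictly inside (0, 1) except in the coincident-centroid degeneracy, so
#' exact 0 and 1 are accepted and map to `INSIGNIFICANT` and `FULL`; values
#' outside \eqn{[0, 1]} are an error.
#'
#' @param membership numeric vector of membership degrees.
#' @return Character vector of band names.
#' @export
band_of <- function(membership) {
  if (any(!is.finite(membership)) ||
      any(membership < 0) || any(membership > 1))
    stop("membership outside [0, 1]")
  cut(membership, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf), right = FALSE,
      labels = c("INSIGNIFICANT", "LOW", "MID", "DOM", "FULL")) |>
    as.character()
}

# canonical pattern string for a set of (cluster, band) pairs
.pattern_string <- function(clusters, bands) {
  o <- order(clusters)
  paste(sprintf("%d:%s", clusters[o], bands[o]), collapse = "+")
}

#' Assign every patient to a band-pattern subgroup
#'
#' Implements the five-step sequential banding procedure on a membership
#' matrix: (1) patients with a full membership (>= 80%) in some cluster form
#' that cluster's full-membership subgroup, any other band being discarded;
#' (2) remaining patients with a dominant membership (60-80%) form subgroups
#' keyed by the dominant cluster plus any 20-40% secondaries; (3) remaining
#' patients with a 40-60% membership are keyed by all their 40-60% and
#' 20-40% entries; (4) remaining patients with only 20-40% entries are keyed
#' by those; (5) the rest — no membership reaching 20% — form the rest
#' group. Members of one subgroup share an identical band pattern.
#'
#' This is the raw assignment: no minimum-size rule is applied yet (see
#' [enforce_min_size()]) and subgroups are identified by their canonical
#' pattern string, not yet named (see [name_subgroups()]).
#'
#' @param U membership matrix (rows summing to 1). Row names are used as
#'   patient ids (defaulting to `1:n`).
#' @return Object of class `subgroup_assignment`: list with `patients`
#'   (data frame: `patient_id`, `pattern`, `step`, `subgroup`), `subgroups`
#'   (data frame: `subgroup`, `pattern`, `size`, `clusters`, `is_full`),
#'   `k`, and `min_size` (NA until enforced).
#' @export
assign_subgroups <- function(U) {
  U <- as.matrix(U)
  n <- nrow(U); k <- ncol(U)
  ids <- rownames(U)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  bands <- matrix(band_of(as.vector(U)), n, k)
  n_full <- rowSums(bands == "FULL")
  n_dom <- rowSums(bands == "DOM")
  # infeasible mass: two FULLs, or FULL + DOM, would exceed a row sum of 1
  stopifnot(all(n_full <= 1), all(n_full + n_dom <= 1))
  pattern <- character(n)
  step <- integer(n)
  for (i in seq_len(n)) {
    b <- bands[i, ]
    if (any(b == "FULL")) {            # step 1: full membership absorbs
      pattern[i] <- .pattern_string(which(b == "FULL"), "FULL")
      step[i] <- 1L
    } else if (any(b == "DOM")) {      # step 2: dominant + LOW secondaries
      sel <- which(b %in% c("DOM", "LOW"))
      pattern[i] <- .pattern_string(sel, b[sel])
      step[i] <- 2L
    } else if (any(b == "MID")) {      # step 3: MID combinations
      sel <- which(b %in% c("MID", "LOW"))
      pattern[i] <- .pattern_string(sel, b[sel])
      step[i] <- 3L
    } else if (any(b == "LOW")) {      # step 4: LOW-only combinations
      sel <- which(b == "LOW")
      pattern[i] <- .pattern_string(sel, b[sel])
      step[i] <- 4L
    } else {                           # step 5: rest group
      pattern[i] <- "REST"
      step[i] <- 5L
    }
  }
  patients <- data.frame(patient_id = ids, pattern = pattern, step = step,
                         subgroup = pattern, stringsAsFactors = FALSE)
  structure(list(patients = patients,
                 subgroups = .subgroup_table(patients),
                 k = k, min_size = NA_integer_),
            class = "subgroup_assignment")
}

.pattern_clusters <- function(pattern) {
  if (pattern == "REST") return(integer(0))
  as.integer(sub(":.*", "", strsplit(pattern, "+", fixed = TRUE)[[1]]))
}

.subgroup_table <- function(patients) {
  pat <- patients$subgroup[patients$subgroup != "REST"]
  tab <- table(pat)
  sg <- names(tab)
  data.frame(subgroup = sg, pattern = sg, size = as.integer(tab),
             clusters = vapply(sg, function(p)
               paste(.pattern_clusters(p), collapse = "-"), character(1)),
             is_full = grepl("FULL", sg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dissolve subgroups below the clinical relevance threshold
#'
#' Every subgroup with fewer than `min_size` patients (default 100, chosen
#' as a feasible target size for a hospital intervention) is dissolved into
#' the rest group; retained subgroups are unchanged.
#'
#' @param assignment a `subgroup_assignment`.
#' @param min_size inclusive minimum subgroup size.
#' @export
enforce_min_size <- function(assignment, min_size = 100) {
  stopifnot(inherits(assignment, "subgroup_assignment"), min_size >= 1)
  p <- assignment$patients
  p$subgroup <- p$pattern
  keep <- names(which(table(p$pattern[p$pattern != "REST"]) >= min_size))
  p$subgroup[!(p$subgroup %in% keep)] <- "REST"
  assignment$patients <- p
  assignment$subgroups <- .subgroup_table(p)
  assignment$min_size <- as.integer(min_size)
  assignment
}

#' Name subgroups in the field's cluster-index style
#'
#' Full-membership subgroups are named by their cluster index (`"4"`). All
#' other subgroups are named by their involved cluster indices in ascending
#' order joined by hyphens, plus a letter suffix `a`, `b`, `c`, ...
#' disambiguating distinct band patterns over the same cluster set, assigned
#' in order of descending subgroup size (ties by the canonical pattern
#' string). So a dominant-only subgroup of cluster 3 is `"3-a"` and the
#' combination subgroups of clusters 1 and 5 are `"1-5-a"`, `"1-5-b"`, ...
#'
#' @param assignment a `subgroup_assignment` (normally size-filtered).
#' @return The assignment with a `name` column added to both `patients` and
#'   `subgroups` (`"REST"` for the rest group).
#' @export
name_subgroups <- function(assignment) {
  stopifnot(inherits(assignment, "subgroup_assignment"))
  sg <- assignment$subgroups
  sg$name <- NA_character_
  sg$name[sg$is_full] <- sg$clusters[sg$is_full]
  for (set in unique(sg$clusters[!sg$is_full])) {
    idx <- which(!sg$is_full & sg$clusters == set)
    idx <- idx[order(-sg$size[idx], sg$pattern[idx])]
    sg$name[idx] <- paste(set, letters[seq_along(idx)], sep = "-")
  }
  assignment$subgroups <- sg
  map <- c(stats::setNames(sg$name, sg$pattern), REST = "REST")
  assignment$patients$name <- map[assignment$patients$subgroup]
  names(assignment$patients$name) <- NULL
  assignment
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  n <- nrow(x$patients)
  n_rest <- sum(x$patients$subgroup == "REST")
  cat(sprintf("Subgroup assignment: %d patients, %d subgroups, rest group %d (%.1f%%)\n",
              n, nrow(x$subgroups), n_rest, 100 * n_rest / n))
  if (!is.na(x$min_size))
    cat(sprintf("  minimum subgroup size enforced: %d\n", x$min_size))
  invisible(x)
}

# type-7 (linear interpolation) quantiles; IQR reported as the single
# value Q3 - Q1, matching the "median (IQR)" display convention
.median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], iqr = q[3] - q[1])
}

#' Per-patient summary of an encounter table
#'
#' Collapses a long-format encounter table to one row per patient: age, sex,
#' total outpatient/ED visits and inpatient days, and the number of distinct
#' diagnosis codes.
#'
#' @param encounters an encounter table (see [read_encounters()]).
#' @return Data frame with one row per patient.
#' @export
patient_summary <- function(encounters) {
  sp <- split(encounters, encounters$patient_id)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    patient_id = d$patient_id[1],
    age_years = d$age_years[1],
    sex = d$sex[1],
    outpatient_visits = sum(d$outpatient_visits),
    ed_visits = sum(d$ed_visits),
    inpatient_days = sum(d$inpatient_days),
    n_diagnoses = length(unique(d$diagnosis_code)),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Descriptive profile of every subgroup
#'
#' For each subgroup (and the rest group, flagged): size; mean and SD of the
#' membership (in %) for each cluster in the subgroup's band pattern; female
#' count and percentage; median and IQR (single value, Q3 - Q1, linear
#' interpolation) of age, number of involved specialties, outpatient visits,
#' ED visits, inpatient days, and number of distinct diagnoses; the top five
#' specialties by percentage of members involved; and the top ten diagnosis
#' groups by percentage of members affected. Top lists are sorted by
#' descending percentage with alphabetical tie-break.
#'
#' @param assignment a named `subgroup_assignment` (see [name_subgroups()]).
#' @param encounters the encounter table the cohort was built from.
#' @param X the binary involvement matrix (patients x specialties), rows
#'   aligned with `U`.
#' @param U the membership matrix the assignment came from.
#' @return List of class `subgroup_profiles`, one profile per subgroup.
#' @export
profile_subgroups <- function(assignment, encounters, X, U) {
  stopifnot(inherits(assignment, "subgroup_assignment"))
  if (is.null(assignment$patients$name))
    assignment <- name_subgroups(assignment)
  X <- as.matrix(X); U <- as.matrix(U)
  pts <- assignment$patients
  if (!all(pts$patient_id %in% rownames(X)) ||
      !all(pts$patient_id %in% encounters$patient_id))
    stop("subgroup references a patient absent from the cohort data")
  psum <- patient_summary(encounters)
  psum <- psum[match(pts$patient_id, psum$patient_id), ]
  Xo <- X[pts$patient_id, , drop = FALSE]
  Uo <- U[pts$patient_id, , drop = FALSE]
  groups <- setdiff(sort(unique(pts$name)), "REST")
  if (any(pts$name == "REST")) groups <- c(groups, "REST")
  profiles <- lapply(groups, function(g) {
    sel <- pts$name == g
    n <- sum(sel)
    pat <- pts$pattern[sel][1]
    cl <- if (g == "REST") integer(0) else .pattern_clusters(pat)
    memb <- lapply(cl, function(j) {
      v <- 100 * Uo[sel, j]
      c(mean = mean(v), sd = stats::sd(v))
    })
    if (length(memb)) names(memb) <- paste0("cluster_", cl)
    spec_pct <- sort(100 * colMeans(Xo[sel, , drop = FALSE]),
                     decreasing = TRUE)
    spec_pct <- spec_pct[order(-spec_pct, names(spec_pct))]
    enc_sel <- encounters[encounters$patient_id %in% pts$patient_id[sel], ]
    dg_pct <- 100 * table(unlist(
      lapply(split(enc_sel$diagnosis_group, enc_sel$patient_id), unique))) / n
    dg_pct <- c(dg_pct)[order(-c(dg_pct), names(dg_pct))]
    ps <- psum[sel, ]
    list(name = g, n = n, is_rest = g == "REST",
         pattern = if (g == "REST") "REST" else pat,
         membership = memb,
         sex_female_n = sum(ps$sex == "female"),
         sex_female_pct = 100 * mean(ps$sex == "female"),
         age = .median_iqr(ps$age_years),
         n_specialties = .median_iqr(rowSums(Xo[sel, , drop = FALSE])),
         outpatient_visits = .median_iqr(ps$outpatient_visits),
         ed_visits = .median_iqr(ps$ed_visits),
         inpatient_days = .median_iqr(ps$inpatient_days),
         n_diagnoses = .median_iqr(ps$n_diagnoses),
         top_specialties = utils::head(spec_pct, 5),
         top_diagnosis_groups = utils::head(dg_pct, 10))
  })
  names(profiles) <- groups
  structure(profiles, class = "subgroup_profiles")
}

#' @export
print.subgroup_profiles <- function(x, ...) {
  cat("Subgroup profiles (", length(x), " groups)\n", sep = "")
  for (p in x)
    cat(sprintf("  %-8s n = %5d  median age %.0f  top specialty %s\n",
                p$name, p$n, p$age[["median"]],
                if (length(p$top_specialties)) names(p$top_specialties)[1]
                else "-"))
  invisible(x)
}
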