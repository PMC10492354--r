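#' Default specialty catalog
#'
#' The 22 medical specialties of a Dutch general hospital used as the
#' default feature space of the synthetic cohort generator.
#'
#' @return Character vector of 22 specialty names.
#' @export
default_specialty_catalog <- function() {
  c("internal medicine", "cardiology", "general surgery", "neurology",
    "pulmonology", "dermatology", "ophthalmology", "otorhinolaryngology",
    "orthopedic surgery", "urology", "gastroenterology", "rheumatology",
    "gynecology", "geriatrics", "plastic surgery", "anesthesiology",
    "dental surgery", "physiatry", "psychiatry", "neurosurgery",
    "pediatrics", "radiology")
}

# group name pools by diagnosis type (a ~30-group stand-in for the 233-group
# clinical classification level)
.chronic_groups <- c(
  "Osteoarthritis", "Asthma",
  "Chronic obstructive pulmonary disease and bronchiectasis",
  "Diabetes mellitus with complications",
  "Congestive heart failure; non-hypertensive", "Cardiac dysrhythmias",
  "Chronic kidney disease", "Thyroid disorders", "Osteoporosis",
  "Essential hypertension", "Other connective tissue disease",
  "Spondylosis; intervertebral disc disorders; other back problems",
  "Other nervous system disorders", "Parkinson's disease",
  "Other skin disorders", "Other inflammatory condition of skin",
  "Other circulatory disease", "Other gastrointestinal disorders",
  "Other ear and sense organ disorders", "Headache; including migraine",
  "Other eye disorders", "Cataract")
.oncological_groups <- c(
  "Other non-epithelial cancer of skin", "Cancer of breast",
  "Cancer of bronchus; lung", "Melanomas of skin",
  "Malignant neoplasm without specification of site")
.acute_groups <- c("Pneumonia", "Acute cerebrovascular disease",
                   "Nonspecific chest pain")
.other_groups <- c("Residual codes; unclassified",
                   "Other screening for suspected conditions",
                   "Other aftercare")

#' Default diagnosis catalog
#'
#' One row per diagnosis code with its group, type, and the specialty it is
#' affiliated with. Each specialty carries two chronic codes, one
#' oncological code (for a subset of specialties), and one acute or "other"
#' code, so any involved specialty can supply qualifying (chronic or
#' oncological) diagnoses for the multimorbidity inclusion criterion.
#'
#' @param specialties character vector of specialty names.
#' @return Data frame: `diagnosis_code`, `diagnosis_group`,
#'   `diagnosis_type`, `specialty`.
#' @export
default_diagnosis_catalog <- function(specialties = default_specialty_catalog()) {
  p <- length(specialties)
  rows <- list()
  recyc <- function(pool, i) pool[((i - 1) %% length(pool)) + 1]
  for (i in seq_len(p)) {
    sp <- specialties[i]
    rows[[length(rows) + 1]] <- data.frame(
      diagnosis_group = c(recyc(.chronic_groups, 2 * i - 1),
                          recyc(.chronic_groups, 2 * i)),
      diagnosis_type = "chronic", specialty = sp,
      stringsAsFactors = FALSE)
    if (i %% 3 == 0)
      rows[[length(rows) + 1]] <- data.frame(
        diagnosis_group = recyc(.oncological_groups, i %/% 3),
        diagnosis_type = "oncological", specialty = sp,
        stringsAsFactors = FALSE)
    pool <- if (i %% 2 == 0) .acute_groups else .other_groups
    rows[[length(rows) + 1]] <- data.frame(
      diagnosis_group = recyc(pool, i),
      diagnosis_type = if (i %% 2 == 0) "acute" else "other",
      specialty = sp, stringsAsFactors = FALSE)
  }
  cat <- do.call(rbind, rows)
  cat$diagnosis_code <- sprintf("C%03d", seq_len(nrow(cat)))
  cat[, c("diagnosis_code", "diagnosis_group", "diagnosis_type", "specialty")]
}

#' Configuration for the synthetic cohort generator
#'
#' Encodes the planted structure the generator emulates: `n_prototypes`
#' prototype involvement patterns over the specialty catalog, each with
#' `signature_size` signature specialties involved with probability
#' `high_prob` against a `low_prob` background; a `blend_fraction` of
#' patients drawn from the elementwise mean of two prototype rows
#' (patients genuinely shared between two specialty patterns); and
#' per-patient demographics and Poisson utilization counts.
#'
#' @param n_patients cohort size.
#' @param specialties specialty catalog (ordered).
#' @param n_prototypes number of planted prototypes K.
#' @param high_prob involvement probability on signature specialties.
#' @param low_prob background involvement probability.
#' @param signature_size signature specialties per prototype; signatures
#'   are disjoint, so `n_prototypes * signature_size` must not exceed the
#'   number of specialties.
#' @param blend_fraction fraction of patients blending two prototypes.
#' @param diagnosis_catalog data frame as in [default_diagnosis_catalog()].
#' @param outpatient_mean,ed_mean,inpatient_mean Poisson means of the
#'   care-activity counts per involved specialty (outpatient visits get +1
#'   so qualifying diagnoses always show outpatient care).
#' @param extra_diagnosis_prob probability that an involved specialty
#'   contributes an additional acute/other diagnosis row.
#' @param age_mean,age_sd age distribution (normal, rounded, floored at 18).
#' @param female_prob probability of sex "female".
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_patients = 5000,
                             specialties = default_specialty_catalog(),
                             n_prototypes = 6,
                             high_prob = 0.9, low_prob = 0.05,
                             signature_size = 3, blend_fraction = 0.2,
                             diagnosis_catalog =
                               default_diagnosis_catalog(specialties),
                             outpatient_mean = 2, ed_mean = 0.3,
                             inpatient_mean = 0.5,
                             extra_diagnosis_prob = 0.3,
                             age_mean = 68, age_sd = 15,
                             female_prob = 0.56, seed = 1L) {
  stopifnot(n_patients >= 0, n_prototypes >= 1,
            low_prob >= 0, low_prob <= high_prob, high_prob <= 1,
            blend_fraction >= 0, blend_fraction <= 1, signature_size >= 1)
  if (n_prototypes * signature_size > length(specialties))
    stop("disjoint signatures impossible: ",
         "n_prototypes * signature_size exceeds the number of specialties")
  structure(as.list(environment()), class = "generator_config")
}

#' Planted prototype involvement probabilities
#'
#' Row j has probability `high_prob` on prototype j's signature specialties
#' (disjoint consecutive blocks of the catalog) and `low_prob` elsewhere.
#'
#' @param config a `generator_config`.
#' @return K x p matrix of involvement probabilities.
#' @export
make_prototypes <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  p <- length(config$specialties)
  K <- config$n_prototypes
  P <- matrix(config$low_prob, K, p,
              dimnames = list(paste0("prototype_", seq_len(K)),
                              config$specialties))
  for (j in seq_len(K)) {
    sig <- ((j - 1) * config$signature_size + 1):(j * config$signature_size)
    P[j, sig] <- config$high_prob
  }
  P
}

#' Simulate a synthetic encounter table with planted structure
#'
#' Each patient is drawn from one prototype (probability
#' `1 - blend_fraction`, uniform over prototypes) or from an equal blend of
#' two (uniform over pairs); its specialty-involvement vector is Bernoulli
#' from the prototype row or the elementwise mean of the pair. Every
#' involved specialty contributes at least one chronic or oncological
#' diagnosis row with at least one outpatient visit, and patients with a
#' single involved specialty get a second qualifying diagnosis for it, so
#' every generated patient passes the multimorbidity inclusion filter by
#' construction. Ages are >= 18. Fully reproducible from `config$seed`.
#'
#' @param config a `generator_config`.
#' @return List with `encounters` (long-format encounter data frame),
#'   `truth` (data frame `patient_id`, `prototype_1`, `prototype_2`, the
#'   latter `NA` for pure patients), `involvement` (the drawn binary
#'   matrix), and `prototypes`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patients
  P <- make_prototypes(config)
  K <- config$n_prototypes
  specs <- config$specialties
  p <- length(specs)
  if (n == 0) {
    empty <- validate_encounters(
      as.data.frame(stats::setNames(rep(list(character(0)), 10),
                                    .encounter_cols))[0, ])
    return(list(encounters = empty,
                truth = data.frame(patient_id = character(0),
                                   prototype_1 = integer(0),
                                   prototype_2 = integer(0)),
                involvement = matrix(0L, 0, p, dimnames = list(NULL, specs)),
                prototypes = P))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  ids <- sprintf("P%05d", seq_len(n))
  pairs <- if (K >= 2) t(utils::combn(K, 2)) else matrix(1L, 1, 2)
  is_blend <- stats::runif(n) < config$blend_fraction & K >= 2
  proto1 <- integer(n); proto2 <- rep(NA_integer_, n)
  proto1[!is_blend] <- sample.int(K, sum(!is_blend), replace = TRUE)
  if (any(is_blend)) {
    pick <- sample.int(nrow(pairs), sum(is_blend), replace = TRUE)
    proto1[is_blend] <- pairs[pick, 1]
    proto2[is_blend] <- pairs[pick, 2]
  }
  prob <- P[proto1, , drop = FALSE]
  prob[is_blend, ] <- (P[proto1[is_blend], , drop = FALSE] +
                         P[proto2[is_blend], , drop = FALSE]) / 2
  inv <- matrix((stats::runif(n * p) < prob) + 0L, n, p,
                dimnames = list(ids, specs))
  none <- rowSums(inv) == 0
  if (any(none)) {  # force the first signature specialty of prototype 1
    j <- (proto1[none] - 1) * config$signature_size + 1
    inv[cbind(which(none), j)] <- 1L
  }
  age <- pmax(18, round(stats::rnorm(n, config$age_mean, config$age_sd)))
  sex <- ifelse(stats::runif(n) < config$female_prob, "female", "male")

  cat <- config$diagnosis_catalog
  qual_idx <- lapply(specs, function(sp)
    which(cat$specialty == sp &
            cat$diagnosis_type %in% c("chronic", "oncological")))
  names(qual_idx) <- specs
  if (any(lengths(qual_idx) < 2))
    stop("diagnosis catalog must provide >= 2 chronic/oncological codes per specialty")
  extra_idx <- lapply(specs, function(sp)
    which(cat$specialty == sp &
            cat$diagnosis_type %in% c("acute", "elective", "other")))
  names(extra_idx) <- specs

  hit <- which(inv == 1L, arr.ind = TRUE)
  pi_ <- hit[, 1]; sj <- hit[, 2]
  # one qualifying diagnosis per involved specialty
  q1 <- vapply(sj, function(j) {
    ix <- qual_idx[[j]]
    ix[sample.int(length(ix), 1)]
  }, integer(1))
  rows <- data.frame(
    patient_id = ids[pi_],
    specialty = specs[sj],
    cat_row = q1,
    outpatient_visits = 1L + stats::rpois(length(pi_), config$outpatient_mean),
    ed_visits = stats::rpois(length(pi_), config$ed_mean),
    inpatient_days = stats::rpois(length(pi_), config$inpatient_mean),
    stringsAsFactors = FALSE)
  # second qualifying code for single-specialty patients (distinct code)
  single <- which(rowSums(inv) == 1)
  if (length(single)) {
    sj1 <- apply(inv[single, , drop = FALSE], 1, which.max)
    q2 <- mapply(function(j, used) {
      ix <- setdiff(qual_idx[[j]], used)
      ix[sample.int(length(ix), 1)]
    }, sj1, q1[match(single, pi_)])
    rows <- rbind(rows, data.frame(
      patient_id = ids[single], specialty = specs[sj1], cat_row = q2,
      outpatient_visits = 1L + stats::rpois(length(single),
                                            config$outpatient_mean),
      ed_visits = stats::rpois(length(single), config$ed_mean),
      inpatient_days = stats::rpois(length(single), config$inpatient_mean),
      stringsAsFactors = FALSE))
  }
  # occasional extra acute/other diagnosis per involved specialty
  add <- which(stats::runif(length(pi_)) < config$extra_diagnosis_prob &
                 lengths(extra_idx)[sj] > 0)
  if (length(add)) {
    e1 <- vapply(sj[add], function(j) {
      ix <- extra_idx[[j]]
      ix[sample.int(length(ix), 1)]
    }, integer(1))
    rows <- rbind(rows, data.frame(
      patient_id = ids[pi_[add]], specialty = specs[sj[add]], cat_row = e1,
      outpatient_visits = stats::rpois(length(add), config$outpatient_mean),
      ed_visits = stats::rpois(length(add), config$ed_mean),
      inpatient_days = stats::rpois(length(add), config$inpatient_mean),
      stringsAsFactors = FALSE))
  }
  ord <- order(match(rows$patient_id, ids), rows$specialty, rows$cat_row)
  rows <- rows[ord, ]
  enc <- data.frame(
    patient_id = rows$patient_id,
    age_years = age[match(rows$patient_id, ids)],
    sex = sex[match(rows$patient_id, ids)],
    specialty = rows$specialty,
    diagnosis_code = cat$diagnosis_code[rows$cat_row],
    diagnosis_group = cat$diagnosis_group[rows$cat_row],
    diagnosis_type = cat$diagnosis_type[rows$cat_row],
    outpatient_visits = rows$outpatient_visits,
    ed_visits = rows$ed_visits,
    inpatient_days = rows$inpatient_days,
    stringsAsFactors = FALSE)
  rownames(enc) <- NULL
  list(encounters = validate_encounters(enc),
       truth = data.frame(patient_id = ids, prototype_1 = proto1,
                          prototype_2 = proto2, stringsAsFactors = FALSE),
       involvement = inv, prototypes = P)
}

#' Append patients that violate the inclusion criteria
#'
#' Stress input for the inclusion filter: appends `count` patients cycling
#' through three violation modes — minors with several chronic diagnoses,
#' adults with only acute diagnoses, and adults whose chronic diagnoses
#' have no outpatient visits.
#'
#' @param encounters an encounter table to extend.
#' @param count number of sub-threshold patients to append.
#' @param seed integer seed.
#' @return The extended encounter table; with `count = 0`, unchanged.
#' @export
inject_subthreshold_patients <- function(encounters, count, seed = 1L) {
  stopifnot(count >= 0)
  if (count == 0) return(encounters)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cat <- default_diagnosis_catalog()
  chronic <- cat[cat$diagnosis_type == "chronic", ]
  acute <- cat[cat$diagnosis_type == "acute", ]
  out <- list(encounters)
  for (i in seq_len(count)) {
    id <- sprintf("SUB%04d", i)
    mode <- (i - 1) %% 3
    if (mode == 0) {        # minor, 3 chronic diagnoses with visits
      pick <- chronic[sample.int(nrow(chronic), 3), ]
      age <- 17; ov <- rep(2L, 3)
    } else if (mode == 1) { # adult, acute-only care
      pick <- acute[sample.int(nrow(acute), 2), ]
      age <- 70; ov <- rep(1L, 2)
    } else {                # adult, chronic but no outpatient visits
      pick <- chronic[sample.int(nrow(chronic), 2), ]
      age <- 70; ov <- rep(0L, 2)
    }
    out[[i + 1]] <- data.frame(
      patient_id = id, age_years = age,
      sex = ifelse(stats::runif(1) < 0.5, "female", "male"),
      specialty = pick$specialty,
      diagnosis_code = pick$diagnosis_code,
      diagnosis_group = pick$diagnosis_group,
      diagnosis_type = pick$diagnosis_type,
      outpatient_visits = ov,
      ed_visits = if (mode == 2) rep(1L, nrow(pick)) else rep(0L, nrow(pick)),
      inpatient_days = rep(0L, nrow(pick)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a ground-truth table
#'
#' Serialized as delimited text: `patient_id`, `prototype_1`, `prototype_2`
#' (blank for pure patients).
#'
#' @param truth ground-truth data frame from [simulate_cohort()].
#' @param path destination path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c("character", "integer", "integer"))
  x$prototype_2[is.na(x$prototype_2)] <- NA_integer_
  x
}
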