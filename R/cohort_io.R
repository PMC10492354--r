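.encounter_cols <- c("patient_id", "age_years", "sex", "specialty",
                     "diagnosis_code", "diagnosis_group", "diagnosis_type",
                     "outpatient_visits", "ed_visits", "inpatient_days")
.count_cols <- c("outpatient_visits", "ed_visits", "inpatient_days")
.diagnosis_types <- c("acute", "chronic", "elective", "oncological", "other")

#' Read a long-format encounter table
#'
#' One row per patient-specialty-diagnosis combination, with the diagnosis
#' group and type and the care-activity counts (outpatient visits, emergency
#' department visits, inpatient days), mirroring the structure of Dutch
#' Diagnosis-Treatment Combination extracts. The header must contain
#' `patient_id`, `age_years`, `sex`, `specialty`, `diagnosis_code`,
#' `diagnosis_group`, `diagnosis_type`, `outpatient_visits`, `ed_visits`,
#' `inpatient_days`.
#'
#' @param path path to a delimited text file (UTF-8).
#' @param sep field delimiter, default comma.
#' @param quote quote character.
#' @return A validated encounter data frame.
#' @export
read_encounters <- function(path, sep = ",", quote = "\"") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = quote,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  validate_encounters(raw)
}

#' Validate an encounter table
#'
#' Checks the schema (all required columns present), parses the numeric
#' columns (reporting offending row numbers on failure), and enforces the
#' row invariants: non-empty patient and specialty, a known diagnosis type,
#' non-negative counts, and a single age and sex per patient.
#'
#' @param x data frame of raw (possibly all-character) encounter rows.
#' @return The encounter data frame with typed columns.
#' @export
validate_encounters <- function(x) {
  missing_cols <- setdiff(.encounter_cols, names(x))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  x <- x[, .encounter_cols]
  for (col in c("age_years", .count_cols)) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric %s in row(s): %s", col,
                   paste(utils::head(bad, 10), collapse = ", ")))
    if (anyNA(v)) stop("missing ", col, " values")
    x[[col]] <- v
  }
  x[.count_cols] <- lapply(x[.count_cols], as.integer)
  if (any(x$age_years < 0)) stop("negative age_years")
  if (any(vapply(x[.count_cols], function(v) any(v < 0), logical(1))))
    stop("negative care-activity counts")
  empty <- which(x$patient_id == "" | x$specialty == "")
  if (length(empty))
    stop("empty patient_id or specialty in row(s): ",
         paste(utils::head(empty, 10), collapse = ", "))
  bad_type <- which(!(x$diagnosis_type %in% .diagnosis_types))
  if (length(bad_type))
    stop("unknown diagnosis_type in row(s): ",
         paste(utils::head(bad_type, 10), collapse = ", "))
  per_pat <- unique(x[, c("patient_id", "age_years", "sex")])
  dup <- per_pat$patient_id[duplicated(per_pat$patient_id)]
  if (length(dup))
    stop("conflicting age or sex across rows for patient(s): ",
         paste(utils::head(unique(dup), 10), collapse = ", "))
  rownames(x) <- NULL
  x
}

#' Apply the multimorbidity inclusion filter
#'
#' Retains adult patients (age >= `min_age`, default 18) who received
#' outpatient clinical care for two or more chronic diagnoses, two or more
#' oncological diagnoses, or at least one chronic and one oncological
#' diagnosis — equivalently, whose count of distinct chronic-type plus
#' oncological-type diagnoses is at least two. "Received outpatient clinical
#' care for" a diagnosis is operationalized as that diagnosis having at
#' least one outpatient visit recorded (switch off via
#' `require_outpatient_visit`). Diagnoses are counted as distinct
#' `diagnosis_code`s by default; `count_level = "group"` counts distinct
#' `diagnosis_group`s instead. All rows of retained patients are kept,
#' including their acute/elective/other rows.
#'
#' @param encounters a validated encounter table.
#' @param min_age minimum age in years (inclusive).
#' @param require_outpatient_visit only diagnoses with >= 1 outpatient visit
#'   qualify (default TRUE).
#' @param count_level count distinct diagnosis codes (default) or groups.
#' @return The filtered encounter table (possibly empty).
#' @export
apply_inclusion_filter <- function(encounters, min_age = 18,
                                   require_outpatient_visit = TRUE,
                                   count_level = c("code", "group")) {
  count_level <- match.arg(count_level)
  x <- encounters
  qual <- x$diagnosis_type %in% c("chronic", "oncological")
  if (require_outpatient_visit) qual <- qual & x$outpatient_visits >= 1
  key <- if (count_level == "code") x$diagnosis_code else x$diagnosis_group
  counts <- tapply(key[qual], x$patient_id[qual],
                   function(v) length(unique(v)))
  ages <- tapply(x$age_years, x$patient_id, `[`, 1)
  eligible <- names(ages)[ages >= min_age &
                            !is.na(counts[names(ages)]) &
                            counts[names(ages)] >= 2]
  out <- x[x$patient_id %in% eligible, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the binary specialty-involvement matrix
#'
#' Cell (i, j) is 1 iff patient i has at least one encounter row with
#' specialty j. Rows are ordered by patient id and columns
#' lexicographically by specialty name, so the matrix is deterministic for
#' a given table.
#'
#' @param encounters an inclusion-filtered encounter table.
#' @return Binary matrix with patient ids as row names and specialty names
#'   as column names; every row has at least one 1.
#' @export
build_involvement_matrix <- function(encounters) {
  if (nrow(encounters) == 0) stop("no patients after filtering")
  ids <- sort(unique(encounters$patient_id))
  specs <- sort(unique(encounters$specialty))
  M <- matrix(0L, length(ids), length(specs), dimnames = list(ids, specs))
  M[cbind(match(encounters$patient_id, ids),
          match(encounters$specialty, specs))] <- 1L
  M
}

#' Load a diagnosis code to (group, type) map
#'
#' Reads a delimited file with header `diagnosis_code`, `diagnosis_group`,
#' `diagnosis_type` — a stand-in for a clinical classification (such as the
#' Dutch DHD-CCS grouping of diagnoses into 233 groups and five types). The
#' mapping must be unambiguous: a code occurring twice with different
#' targets is an integrity error.
#'
#' @param path path to the delimited file.
#' @param sep field delimiter.
#' @return Data frame with one row per code.
#' @export
load_diagnosis_group_map <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = "character", fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
  need <- c("diagnosis_code", "diagnosis_group", "diagnosis_type")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  bad_type <- unique(x$diagnosis_type[!(x$diagnosis_type %in% .diagnosis_types)])
  if (length(bad_type))
    stop("unknown diagnosis_type label(s): ", paste(bad_type, collapse = ", "))
  u <- unique(x[, need])
  dup <- unique(u$diagnosis_code[duplicated(u$diagnosis_code)])
  if (length(dup))
    stop("diagnosis code(s) with conflicting mappings: ",
         paste(utils::head(dup, 10), collapse = ", "))
  rownames(u) <- NULL
  u
}

#' Write / read a binary involvement matrix as delimited text
#'
#' First column `patient_id`, remaining columns one per specialty, cells
#' 0/1.
#'
#' @param M binary involvement matrix with dimnames.
#' @param path destination path.
#' @export
write_cohort_matrix <- function(M, path) {
  df <- data.frame(patient_id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort_matrix
#' @export
read_cohort_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "integer"
  rownames(M) <- df$patient_id
  M
}
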