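#' traumaGrading: validation machinery for polytrauma risk scores
#'
#' Stratifies severe-trauma cohorts with four published grading systems
#' (CGS, mCGS, PTGS, EAC) loaded from declarative threshold definitions,
#' compares the scores with contingency odds ratios, chi-square tests,
#' Krippendorff's alpha and nested logistic ROC/AUC models, and generates
#' calibrated synthetic cohorts for end-to-end testing.
#'
#' @keywords internal
"_PACKAGE"

# Column schema of a cohort file: name -> storage type. Booleans are stored
# as 0/1 in CSV, death_cause is text, empty cells are absent optionals.
.cohort_types <- c(
  patient_id = "character",
  age_years = "numeric",
  iss = "integer",
  niss = "integer",
  gcs = "integer",
  systolic_bp = "numeric",
  lactate = "numeric",
  ph = "numeric",
  base_excess = "numeric",
  platelet_count = "numeric",
  fibrinogen = "numeric",
  prothrombin_ratio = "numeric",
  inr = "numeric",
  prbc_2h = "integer",
  prbc_24h = "integer",
  temperature_core = "numeric",
  chest_ais = "integer",
  abdomen_moore_grade = "integer",
  extremity_soft_tissue_ais = "integer",
  died = "logical",
  death_hour = "numeric",
  death_cause = "character",
  pneumonia = "logical",
  sepsis = "logical",
  bacteraemia = "logical",
  septic_shock = "logical",
  infection = "logical",
  ards = "logical",
  mof = "logical"
)

#' Cohort CSV column names, in file order
#' @return Character vector of the 29 schema columns.
#' @export
cohort_columns <- function() names(.cohort_types)

.death_causes <- c("TBI", "exsanguination", "MOF", "other")

#' Validate a patient cohort
#'
#' Checks the documented invariants of the cohort schema: column presence and
#' type, unique patient identifiers, physiological ranges (pH in 6.5--8, GCS
#' 3--15, AIS grades 0--6, Moore grade 0--5, non-negative lactate and
#' transfusion counts), injury-score constraints (16 <= ISS <= 75,
#' NISS >= ISS), and outcome consistency (death hour and cause present exactly
#' when the patient died, septic shock implies sepsis).
#'
#' @param cohort data frame following the cohort schema (see
#'   [cohort_columns()]).
#' @return The cohort, invisibly, with class `trauma_cohort`.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(names(.cohort_types), names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cohort <- cohort[, names(.cohort_types)]
  if (nrow(cohort) == 0L) {
    class(cohort) <- unique(c("trauma_cohort", class(cohort)))
    return(invisible(cohort))
  }

  fail <- function(id, field, msg) {
    stop(sprintf("cohort validation error: patient '%s', field '%s': %s",
                 id, field, msg), call. = FALSE)
  }
  id <- cohort$patient_id
  if (anyNA(id) || any(!nzchar(id))) {
    fail(id[which(is.na(id) | !nzchar(id))[1L]], "patient_id", "missing identifier")
  }
  if (anyDuplicated(id)) {
    fail(id[anyDuplicated(id)], "patient_id", "duplicate identifier")
  }

  check_range <- function(field, lo, hi, integer = FALSE) {
    x <- cohort[[field]]
    bad <- !is.na(x) & (x < lo | x > hi | (integer & x != floor(x)))
    if (any(bad)) {
      fail(id[which(bad)[1L]], field,
           sprintf("value %s outside %s[%s, %s]", x[which(bad)[1L]],
                   if (integer) "integer " else "", lo, hi))
    }
  }
  check_range("age_years", 16, 120)
  check_range("iss", 16, 75, integer = TRUE)
  check_range("niss", 0, 75, integer = TRUE)
  check_range("gcs", 3, 15, integer = TRUE)
  check_range("ph", 6.5, 8.0)
  check_range("lactate", 0, Inf)
  check_range("platelet_count", 0, Inf)
  check_range("fibrinogen", 0, Inf)
  check_range("prothrombin_ratio", 0, 150)
  check_range("inr", 0, Inf)
  check_range("prbc_2h", 0, Inf, integer = TRUE)
  check_range("prbc_24h", 0, Inf, integer = TRUE)
  check_range("temperature_core", 20, 45)
  check_range("chest_ais", 0, 6, integer = TRUE)
  check_range("abdomen_moore_grade", 0, 5, integer = TRUE)
  check_range("extremity_soft_tissue_ais", 0, 6, integer = TRUE)
  check_range("death_hour", 0, Inf)

  bad <- !is.na(cohort$niss) & !is.na(cohort$iss) & cohort$niss < cohort$iss
  if (any(bad)) fail(id[which(bad)[1L]], "niss", "NISS < ISS")

  for (field in c("died", "pneumonia", "sepsis", "bacteraemia", "septic_shock",
                  "infection", "ards", "mof")) {
    if (anyNA(cohort[[field]])) {
      fail(id[which(is.na(cohort[[field]]))[1L]], field, "boolean flag absent")
    }
  }
  died <- cohort$died
  bad <- died & is.na(cohort$death_hour)
  if (any(bad)) fail(id[which(bad)[1L]], "death_hour", "absent although died")
  bad <- !died & !is.na(cohort$death_hour)
  if (any(bad)) fail(id[which(bad)[1L]], "death_hour", "present although alive")
  bad <- died & (is.na(cohort$death_cause) |
                   !(cohort$death_cause %in% .death_causes))
  if (any(bad)) {
    fail(id[which(bad)[1L]], "death_cause",
         paste("must be one of", paste(.death_causes, collapse = "/")))
  }
  bad <- !died & !is.na(cohort$death_cause)
  if (any(bad)) fail(id[which(bad)[1L]], "death_cause", "present although alive")
  bad <- cohort$septic_shock & !cohort$sepsis
  if (any(bad)) fail(id[which(bad)[1L]], "septic_shock", "septic shock without sepsis")

  class(cohort) <- unique(c("trauma_cohort", class(cohort)))
  invisible(cohort)
}

#' Read a patient cohort from CSV
#'
#' Reads the documented one-row-per-patient CSV schema (booleans as 0/1,
#' empty cells as absent optional fields) and validates every invariant.
#'
#' @param path Path to a cohort CSV written by [write_cohort()] or following
#'   the same schema.
#' @return A validated `trauma_cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  header <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  if (nrow(utils::read.csv(path, nrows = 1L)) == 0L) {
    header <- strsplit(readLines(path, n = 1L), ",")[[1L]]
    header <- gsub('^"|"$', "", header)
  }
  missing_cols <- setdiff(names(.cohort_types), header)
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  read_types <- .cohort_types
  read_types[read_types == "logical"] <- "integer"
  raw <- utils::read.csv(path, colClasses = read_types[header],
                         na.strings = "", stringsAsFactors = FALSE)
  raw <- raw[, names(.cohort_types)]
  for (field in names(.cohort_types)[.cohort_types == "logical"]) {
    x <- raw[[field]]
    if (any(!is.na(x) & !(x %in% c(0L, 1L)))) {
      stop("cohort schema error: column '", field, "' must be 0/1",
           call. = FALSE)
    }
    raw[[field]] <- x == 1L
  }
  validate_cohort(raw)
}

#' Write a patient cohort to CSV
#'
#' Writes the documented column order with booleans as 0/1 and absent optional
#' fields as empty cells; the file round-trips through [read_cohort()].
#'
#' @param cohort A validated cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- as.data.frame(cohort)[, names(.cohort_types)]
  for (field in names(.cohort_types)[.cohort_types == "logical"]) {
    out[[field]] <- as.integer(out[[field]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Early/late complication labels for one outcome record
#'
#' Early complications are death within 72 hours of admission, death from
#' traumatic brain injury, and death from exsanguination; late complications
#' are pneumonia, sepsis, and death from multiple organ failure. The 72-hour
#' boundary is closed: a death at exactly hour 72 counts as early.
#'
#' @param outcome A single patient row (or list) with fields `died`,
#'   `death_hour`, `death_cause`, `pneumonia`, `sepsis`.
#' @return Character vector of labels among `death_72h`, `death_tbi`,
#'   `death_exsanguination` (early) and `pneumonia`, `sepsis`, `death_mof`
#'   (late).
#' @export
classify_complication_timing <- function(outcome) {
  labels <- character(0)
  died <- isTRUE(outcome$died) | isTRUE(outcome$died == 1)
  if (died && !is.na(outcome$death_hour) && outcome$death_hour <= 72) {
    labels <- c(labels, "death_72h")
  }
  if (died && identical(outcome$death_cause, "TBI")) {
    labels <- c(labels, "death_tbi")
  }
  if (died && identical(outcome$death_cause, "exsanguination")) {
    labels <- c(labels, "death_exsanguination")
  }
  if (isTRUE(outcome$pneumonia)) labels <- c(labels, "pneumonia")
  if (isTRUE(outcome$sepsis)) labels <- c(labels, "sepsis")
  if (died && identical(outcome$death_cause, "MOF")) {
    labels <- c(labels, "death_mof")
  }
  labels
}

#' Grouping of complication labels into early and late phases
#' @return Named list with `early` and `late` label vectors.
#' @export
complication_phases <- function() {
  list(early = c("death_72h", "death_tbi", "death_exsanguination"),
       late = c("pneumonia", "sepsis", "death_mof"))
}

#' Per-patient boolean endpoint from a cohort
#'
#' Vectorized endpoint extraction used by all analysis stages.
#'
#' @param cohort A validated cohort.
#' @param endpoint One of `pneumonia`, `sepsis`, `bacteraemia`,
#'   `septic_shock`, `infection`, `ards`, `mof`, `mortality`, `death_72h`,
#'   `death_late`, `death_tbi`, `death_exsanguination`, `death_mof`,
#'   `early_complication`, `late_complication`.
#' @return Logical vector, one element per patient.
#' @export
endpoint_flag <- function(cohort, endpoint) {
  died <- cohort$died
  hour <- cohort$death_hour
  cause <- cohort$death_cause
  switch(endpoint,
    pneumonia = cohort$pneumonia,
    sepsis = cohort$sepsis,
    bacteraemia = cohort$bacteraemia,
    septic_shock = cohort$septic_shock,
    infection = cohort$infection,
    ards = cohort$ards,
    mof = cohort$mof,
    mortality = died,
    death_72h = died & !is.na(hour) & hour <= 72,
    death_late = died & !is.na(hour) & hour > 72,
    death_tbi = died & !is.na(cause) & cause == "TBI",
    death_exsanguination = died & !is.na(cause) & cause == "exsanguination",
    death_mof = died & !is.na(cause) & cause == "MOF",
    early_complication = (died & !is.na(hour) & hour <= 72) |
      (died & !is.na(cause) & cause %in% c("TBI", "exsanguination")),
    late_complication = cohort$pneumonia | cohort$sepsis |
      (died & !is.na(cause) & cause == "MOF"),
    stop("unknown endpoint: ", endpoint, call. = FALSE)
  )
}

#' Coverage percentage from stratification counts
#'
#' @param n_stratified Number of patients assigned a stratum.
#' @param n_total Cohort size.
#' @param digits Decimal places of the printed percentage (default 1).
#' @return Percentage of the cohort that was stratifiable.
#' @export
coverage_percent <- function(n_stratified, n_total, digits = 1) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  round(100 * n_stratified / n_total, digits)
}
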