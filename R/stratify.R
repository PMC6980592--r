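# Stratification engine: applies a declarative score definition to patients.
# All paths are vectorized over the cohort so large synthetic cohorts are
# cheap to stratify.

# Band index (1 = lowest stratum) attained by a vector of measurements under
# one criterion. NA in -> NA out.
.criterion_band <- function(values, criterion) {
  band <- rep(1L, length(values))
  for (j in seq_along(criterion$cut_values)) {
    v <- criterion$cut_values[j]
    incl <- criterion$cut_inclusive[j]
    met <- if (criterion$direction == "high_is_worse") {
      if (incl) values >= v else values > v
    } else {
      if (incl) values <= v else values < v
    }
    met[is.na(met)] <- FALSE
    band[met] <- criterion$cut_band[j]
  }
  band[is.na(values)] <- NA_integer_
  band
}

#' Evaluate one criterion against a measurement
#'
#' Returns the most severe stratum whose cut is met, else the lowest stratum.
#' Boundary semantics are stored per cut: an exclusive cut of 75 under
#' `low_is_worse` means "< 75" (a value of exactly 75 stays in the milder
#' band); an inclusive cut means "75 or less".
#'
#' @param value A single measurement (must be present).
#' @param criterion A criterion from a validated [load_score_definition()].
#' @param strata Ordered stratum labels of the definition.
#' @return The attained stratum label.
#' @export
evaluate_criterion <- function(value, criterion, strata) {
  if (length(value) != 1L || is.na(value)) {
    stop("evaluate_criterion requires a single present value", call. = FALSE)
  }
  strata[.criterion_band(value, criterion)]
}

#' Is a patient complete for a score?
#'
#' A patient can be stratified only when every required criterion's parameter
#' is present; optional criteria contribute when present but do not block
#' stratification.
#'
#' @param patient One-row cohort data frame (or list of fields).
#' @param definition A validated `score_definition`.
#' @return `TRUE` iff all required parameters are present.
#' @export
completeness <- function(patient, definition) {
  req <- vapply(definition$criteria, function(cr) isTRUE(cr$required), logical(1))
  params <- vapply(definition$criteria, function(cr) cr$parameter, character(1))[req]
  all(vapply(params, function(p) !is.null(patient[[p]]) && !is.na(patient[[p]]),
             logical(1)))
}

# Internal vectorized core: returns list(band = integer vector with NA for
# not-stratifiable, band_matrix = per-criterion bands).
.stratify_bands <- function(cohort, definition) {
  n <- nrow(cohort)
  strata <- definition$strata
  k <- length(definition$criteria)
  bands <- matrix(NA_integer_, nrow = n, ncol = k)
  required <- logical(k)
  for (i in seq_len(k)) {
    cr <- definition$criteria[[i]]
    bands[, i] <- .criterion_band(cohort[[cr$parameter]], cr)
    required[i] <- isTRUE(cr$required)
  }
  complete <- if (any(required)) {
    rowSums(is.na(bands[, required, drop = FALSE])) == 0L
  } else {
    rep(TRUE, n)
  }

  band <- rep(NA_integer_, n)
  if (definition$aggregation == "worst_criterion") {
    worst <- apply(bands, 1L, function(b) if (all(is.na(b))) NA_integer_ else max(b, na.rm = TRUE))
    band[complete] <- worst[complete]
  } else if (definition$aggregation == "point_sum") {
    pts_per_band <- vapply(strata, function(s) as.numeric(definition$band_points[[s]]),
                           numeric(1))
    pts <- matrix(pts_per_band[bands], nrow = n)
    total <- rowSums(pts, na.rm = TRUE)
    assigned <- rep(1L, n)
    for (s in names(definition$point_table)) {
      idx <- match(s, strata)
      assigned[total >= as.numeric(definition$point_table[[s]])] <- idx
    }
    band[complete] <- assigned[complete]
  } else { # majority_vote (sensitivity-analysis policy)
    vote <- apply(bands, 1L, function(b) {
      b <- b[!is.na(b)]
      if (length(b) == 0L) return(NA_integer_)
      tab <- tabulate(b, nbins = length(strata))
      max(which(tab == max(tab))) # tie goes to the more severe stratum
    })
    band[complete] <- vote[complete]
  }
  list(band = band, band_matrix = bands, complete = complete)
}

#' Stratify one patient
#'
#' Applies the score's aggregation policy (worst criterion for CGS/mCGS/EAC,
#' point sum for PTGS) and reports the criteria justifying the assigned
#' stratum. Patients missing any required parameter are `not_stratifiable`.
#'
#' @param patient One-row cohort data frame.
#' @param definition A validated `score_definition`.
#' @return A `stratification_result`: list with `patient_id`, `score_name`,
#'   `stratum` (label or `"not_stratifiable"`), `stratum_index` (NA when not
#'   stratifiable), and `triggered`, a data frame of (parameter, value,
#'   band) for criteria attaining a band above the lowest stratum.
#' @export
stratify <- function(patient, definition) {
  patient <- as.data.frame(patient, stringsAsFactors = FALSE)
  if (nrow(patient) != 1L) stop("stratify expects a single patient", call. = FALSE)
  res <- .stratify_bands(patient, definition)
  strata <- definition$strata
  band <- res$band[1L]
  triggered <- data.frame(parameter = character(0), value = numeric(0),
                          band = character(0), stringsAsFactors = FALSE)
  if (!is.na(band) && band > 1L) {
    crit_bands <- res$band_matrix[1L, ]
    hit <- if (definition$aggregation == "point_sum") {
      which(!is.na(crit_bands) & crit_bands > 1L)
    } else {
      which(!is.na(crit_bands) & crit_bands == band)
    }
    triggered <- data.frame(
      parameter = vapply(definition$criteria[hit], `[[`, character(1), "parameter"),
      value = vapply(hit, function(i) {
        as.numeric(patient[[definition$criteria[[i]]$parameter]])
      }, numeric(1)),
      band = strata[crit_bands[hit]],
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    patient_id = patient$patient_id,
    score_name = definition$name,
    stratum = if (is.na(band)) "not_stratifiable" else strata[band],
    stratum_index = band,
    triggered = triggered
  ), class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("<%s> patient %s: %s", x$score_name, x$patient_id, x$stratum))
  if (nrow(x$triggered) > 0L) {
    cat(" [", paste(sprintf("%s=%g", x$triggered$parameter, x$triggered$value),
                    collapse = ", "), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Stratify a whole cohort
#'
#' @param cohort A validated cohort.
#' @param definition A validated `score_definition`.
#' @return A data frame of class `cohort_stratification` with columns
#'   `patient_id`, `stratum` (label or `"not_stratifiable"`) and
#'   `stratum_index`; attribute `coverage` holds the stratified fraction
#'   (NA with attribute `coverage_undefined = TRUE` for an empty cohort),
#'   attribute `score_name` the score, attribute `strata` the stratum order.
#' @export
stratify_cohort <- function(cohort, definition) {
  n <- nrow(cohort)
  if (n == 0L) {
    out <- data.frame(patient_id = character(0), stratum = character(0),
                      stratum_index = integer(0), stringsAsFactors = FALSE)
    attr(out, "coverage") <- NA_real_
    attr(out, "coverage_undefined") <- TRUE
  } else {
    res <- .stratify_bands(cohort, definition)
    out <- data.frame(
      patient_id = cohort$patient_id,
      stratum = ifelse(is.na(res$band), "not_stratifiable",
                       definition$strata[res$band]),
      stratum_index = res$band,
      stringsAsFactors = FALSE
    )
    attr(out, "coverage") <- mean(!is.na(res$band))
    attr(out, "coverage_undefined") <- FALSE
  }
  attr(out, "score_name") <- definition$name
  attr(out, "strata") <- definition$strata
  class(out) <- c("cohort_stratification", "data.frame")
  out
}
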