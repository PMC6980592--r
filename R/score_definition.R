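# Declarative score definitions: each grading system is a YAML file listing
# ordered strata and per-parameter threshold criteria; the engine never
# hard-codes a cut value.

.valid_directions <- c("high_is_worse", "low_is_worse")
.valid_aggregations <- c("worst_criterion", "point_sum", "majority_vote")

# Fields a criterion may reference (physiology snapshot + injury scores).
.criterion_parameters <- c(
  "systolic_bp", "lactate", "ph", "base_excess", "platelet_count",
  "fibrinogen", "prothrombin_ratio", "inr", "prbc_2h", "prbc_24h",
  "temperature_core", "chest_ais", "abdomen_moore_grade",
  "extremity_soft_tissue_ais", "gcs", "iss", "niss", "age_years"
)

#' Path to a shipped score definition file
#'
#' @param name One of `"CGS"`, `"mCGS"`, `"PTGS"`, `"EAC"` (case-insensitive).
#' @return Path to the YAML definition installed with the package.
#' @export
default_definition_path <- function(name) {
  file <- paste0(tolower(name), ".yaml")
  path <- system.file("definitions", file, package = "traumaGrading")
  if (!nzchar(path)) {
    stop("no shipped definition for score '", name, "'", call. = FALSE)
  }
  path
}

#' Load and validate a score definition
#'
#' Parses a YAML threshold definition and checks its structural invariants:
#' known parameter names, valid direction, cut strata drawn from the declared
#' stratum order, strictly monotone cut values consistent with the direction
#' (thresholds must worsen with severity), and a complete point table for
#' point-sum scores. Shipped defaults exist for all four supported systems
#' (see [default_definition_path()]); every shipped value is an overridable
#' reconstruction of the source publications.
#'
#' @param path Path to a YAML definition, or a score name with a shipped
#'   default (`"CGS"`, `"mCGS"`, `"PTGS"`, `"EAC"`).
#' @return A validated `score_definition` object.
#' @export
load_score_definition <- function(path) {
  if (!file.exists(path) && toupper(path) %in% c("CGS", "MCGS", "PTGS", "EAC")) {
    path <- default_definition_path(path)
  }
  if (!file.exists(path)) {
    stop("score definition file not found: ", path, call. = FALSE)
  }
  def <- yaml::read_yaml(path)
  validate_score_definition(def)
}

#' Validate a score definition object
#'
#' @param def A list with fields `name`, `strata`, `aggregation`, `criteria`
#'   (and `band_points`/`point_table` for point-sum scores).
#' @return The definition with class `score_definition`.
#' @export
validate_score_definition <- function(def) {
  fail <- function(...) {
    stop("score definition error [", def$name %||% "?", "]: ", ...,
         call. = FALSE)
  }
  for (field in c("name", "strata", "aggregation", "criteria")) {
    if (is.null(def[[field]])) fail("missing field '", field, "'")
  }
  strata <- as.character(def$strata)
  if (length(strata) < 2L || anyDuplicated(strata)) {
    fail("strata must be >= 2 distinct ordered labels")
  }
  if (!(def$aggregation %in% .valid_aggregations)) {
    fail("unknown aggregation '", def$aggregation, "'")
  }
  if (length(def$criteria) < 1L) fail("at least one criterion required")

  for (i in seq_along(def$criteria)) {
    cr <- def$criteria[[i]]
    if (is.null(cr$parameter) || !(cr$parameter %in% .criterion_parameters)) {
      fail("criterion ", i, ": unknown parameter '", cr$parameter, "'")
    }
    if (is.null(cr$direction) || !(cr$direction %in% .valid_directions)) {
      fail("criterion '", cr$parameter, "': invalid direction")
    }
    if (is.null(cr$required) || !is.logical(cr$required)) {
      fail("criterion '", cr$parameter, "': 'required' must be true/false")
    }
    if (length(cr$cuts) < 1L) {
      fail("criterion '", cr$parameter, "': no cuts")
    }
    bad_strata <- setdiff(names(cr$cuts), strata[-1L])
    if (length(bad_strata) > 0L) {
      fail("criterion '", cr$parameter, "': cut for unknown stratum '",
           bad_strata[1L], "' (the lowest stratum has no cut)")
    }
    # order cuts by stratum severity, then check strict monotonicity
    ord <- order(match(names(cr$cuts), strata))
    cr$cuts <- cr$cuts[ord]
    vals <- vapply(cr$cuts, function(ct) as.numeric(ct$value), numeric(1))
    incl <- vapply(cr$cuts, function(ct) isTRUE(ct$inclusive), logical(1))
    if (anyNA(vals)) fail("criterion '", cr$parameter, "': non-numeric cut")
    if (length(vals) > 1L) {
      d <- diff(vals)
      mono <- if (cr$direction == "high_is_worse") all(d > 0) else all(d < 0)
      if (!mono) {
        fail("criterion '", cr$parameter,
             "': cut values not strictly monotone in stratum severity")
      }
    }
    cr$cut_values <- vals
    cr$cut_inclusive <- incl
    cr$cut_band <- match(names(cr$cuts), strata)
    def$criteria[[i]] <- cr
  }

  if (def$aggregation == "point_sum") {
    if (is.null(def$band_points) || is.null(def$point_table)) {
      fail("point_sum aggregation requires 'band_points' and 'point_table'")
    }
    if (!all(strata %in% names(def$band_points))) {
      fail("band_points must cover every stratum")
    }
    bad <- setdiff(names(def$point_table), strata[-1L])
    if (length(bad) > 0L) fail("point_table names unknown stratum '", bad[1L], "'")
    pts <- unlist(def$point_table[intersect(strata, names(def$point_table))])
    if (is.unsorted(pts, strictly = TRUE)) {
      fail("point_table cut-offs must increase with stratum severity")
    }
  }
  def$strata <- strata
  class(def) <- "score_definition"
  def
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("<score_definition> %s: %s (%s over %d criteria)\n",
              x$name, paste(x$strata, collapse = " < "), x$aggregation,
              length(x$criteria)))
  invisible(x)
}

#' Load all four shipped score definitions
#'
#' @return Named list of `score_definition` objects (CGS, mCGS, PTGS, EAC).
#' @export
shipped_definitions <- function() {
  names <- c("CGS", "mCGS", "PTGS", "EAC")
  defs <- lapply(names, function(nm) load_score_definition(default_definition_path(nm)))
  names(defs) <- names
  defs
}
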