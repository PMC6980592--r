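# Analysis pipeline: strata-wise endpoint odds ratios, inter-score
# agreement, early/late EAC profile, cross-stratification, and nested
# physiological-system prediction models. Every stage is complete-case on
# the patients it needs and reports the subset size it used.

.joined_strat <- function(cohort, stratification) {
  idx <- match(cohort$patient_id, stratification$patient_id)
  if (anyNA(idx)) stop("stratification does not cover the cohort", call. = FALSE)
  stratification[idx, , drop = FALSE]
}

#' Strata-wise odds ratios for a set of endpoints
#'
#' For every stratum above the reference (the lowest stratum), builds the
#' 2x2 table of (stratum vs reference) x (endpoint yes/no) and computes the
#' odds ratio with 95% CI via [odds_ratio()]. Strata with no patients are
#' omitted from the result rather than reported as zero.
#'
#' @param cohort A validated cohort.
#' @param stratification A [stratify_cohort()] result covering the cohort.
#' @param endpoints Character vector of endpoints (see [endpoint_flag()]).
#' @return Data frame of class `endpoint_or_table` with one row per
#'   (stratum, endpoint): `score`, `stratum`, `endpoint`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `corrected`, `n_stratum`, `n_reference`;
#'   attribute `reference` names the reference stratum.
#' @export
endpoint_or_table <- function(cohort, stratification,
                              endpoints = c("pneumonia", "sepsis",
                                            "death_mof", "death_72h")) {
  strat <- .joined_strat(cohort, stratification)
  strata <- attr(stratification, "strata")
  reference <- strata[1L]
  keep <- strat$stratum != "not_stratifiable"
  cohort <- cohort[keep, , drop = FALSE]
  labels <- strat$stratum[keep]
  if (sum(labels == reference) == 0L) {
    stop("analysis error: reference stratum '", reference, "' is empty",
         call. = FALSE)
  }
  rows <- list()
  for (stratum in strata[-1L]) {
    in_stratum <- labels == stratum
    if (sum(in_stratum) == 0L) next
    for (endpoint in endpoints) {
      flag <- endpoint_flag(cohort, endpoint)
      tab <- rbind(
        c(sum(flag[in_stratum]), sum(!flag[in_stratum])),
        c(sum(flag[labels == reference]), sum(!flag[labels == reference]))
      )
      est <- odds_ratio(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        score = attr(stratification, "score_name"), stratum = stratum,
        endpoint = endpoint, or = est$or, ci_low = est$ci_low,
        ci_high = est$ci_high, p_value = est$p_value,
        corrected = est$corrected, n_stratum = sum(in_stratum),
        n_reference = sum(labels == reference), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  class(out) <- c("endpoint_or_table", "data.frame")
  out
}

#' Agreement analysis from paired stratum labels
#'
#' @param a,b Paired stratum labels (label of score A and score B for the
#'   same patient), drawn from the shared ordered `strata`.
#' @param strata Ordered stratum labels shared by the two scores.
#' @param metric Krippendorff difference function, default nominal.
#' @return An `agreement_report`: `cross_tab` (rows = score A, cols =
#'   score B), `alpha` ([krippendorff_alpha()]), `n_shifted_toward_stable`
#'   (B milder than A), `n_shifted_toward_severe` (B more severe), `n_units`.
#' @export
agreement_from_pairs <- function(a, b, strata, metric = "nominal") {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("analysis error: need >= 2 jointly stratified patients", call. = FALSE)
  }
  fa <- factor(a, levels = strata)
  fb <- factor(b, levels = strata)
  if (anyNA(fa) || anyNA(fb)) stop("label outside the stratum set", call. = FALSE)
  cross_tab <- unclass(table(fa, fb))
  ia <- as.integer(fa)
  ib <- as.integer(fb)
  structure(list(
    cross_tab = cross_tab,
    alpha = krippendorff_alpha(as.character(fa), as.character(fb),
                               metric = metric, categories = strata),
    n_shifted_toward_stable = sum(ib < ia),
    n_shifted_toward_severe = sum(ib > ia),
    n_units = length(a)
  ), class = "agreement_report")
}

#' Inter-score agreement on a cohort
#'
#' Stratifies the cohort with both definitions, restricts to the jointly
#' complete subset, and reports the cross-tabulation, Krippendorff's alpha
#' and directional shift counts (how many patients score B grades milder or
#' more severe than score A).
#'
#' @param cohort A validated cohort.
#' @param def_a,def_b Score definitions sharing the same stratum order
#'   (e.g. CGS and mCGS).
#' @param metric Passed to [krippendorff_alpha()].
#' @return An `agreement_report`, see [agreement_from_pairs()].
#' @export
agreement_analysis <- function(cohort, def_a, def_b, metric = "nominal") {
  if (!identical(def_a$strata, def_b$strata)) {
    stop("agreement requires scores with a shared stratum order", call. = FALSE)
  }
  sa <- stratify_cohort(cohort, def_a)
  sb <- stratify_cohort(cohort, def_b)
  both <- sa$stratum != "not_stratifiable" & sb$stratum != "not_stratifiable"
  if (sum(both) < 2L) {
    stop("analysis error: fewer than 2 patients complete for both scores",
         call. = FALSE)
  }
  agreement_from_pairs(sa$stratum[both], sb$stratum[both], def_a$strata,
                       metric = metric)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d units, alpha (%s) = %.4f\n", x$n_units,
              x$alpha$metric, x$alpha$alpha))
  cat(sprintf("  shifts: %d toward stable, %d toward severe\n",
              x$n_shifted_toward_stable, x$n_shifted_toward_severe))
  print(x$cross_tab)
  invisible(x)
}

#' Expand a cross-tabulation back into paired labels
#'
#' Inverse of the tabulation in [agreement_from_pairs()]: each cell (i, j)
#' with count c yields c units rated (row i, column j).
#'
#' @param cross_tab Count matrix with stratum dimnames.
#' @return List with vectors `a` (row labels) and `b` (column labels).
#' @export
pairs_from_crosstab <- function(cross_tab) {
  idx <- which(cross_tab > 0, arr.ind = TRUE)
  counts <- cross_tab[idx]
  list(a = rep(rownames(cross_tab)[idx[, 1L]], counts),
       b = rep(colnames(cross_tab)[idx[, 2L]], counts))
}

#' Early versus late complication profile across EAC strata
#'
#' Per-endpoint event rates in the low- and high-risk strata with a
#' Yates-corrected chi-square test on each 2x2 table. Endpoints are grouped
#' into the early phase (death within 72 h, death from TBI, death from
#' exsanguination) and the late phase (pneumonia, sepsis, death from MOF).
#' Endpoints with no events (or only events) in the stratified subset are
#' flagged degenerate with an NA test.
#'
#' @param cohort A validated cohort.
#' @param stratification A 2-stratum [stratify_cohort()] result (EAC);
#'   both strata must be populated.
#' @return Data frame of class `early_late_profile`: `endpoint`, `phase`,
#'   `rate_low`, `rate_high`, `statistic`, `p_value`, `degenerate`;
#'   attribute `n_per_stratum` gives the stratified group sizes.
#' @export
eac_early_late_profile <- function(cohort, stratification) {
  strat <- .joined_strat(cohort, stratification)
  strata <- attr(stratification, "strata")
  if (length(strata) != 2L) {
    stop("profile requires a dichotomous score", call. = FALSE)
  }
  keep <- strat$stratum != "not_stratifiable"
  cohort <- cohort[keep, , drop = FALSE]
  labels <- strat$stratum[keep]
  n_low <- sum(labels == strata[1L])
  n_high <- sum(labels == strata[2L])
  if (n_low == 0L || n_high == 0L) {
    stop("analysis error: a stratum is empty", call. = FALSE)
  }
  phases <- complication_phases()
  rows <- list()
  for (phase in names(phases)) {
    for (endpoint in phases[[phase]]) {
      flag <- endpoint_flag(cohort, endpoint)
      high <- labels == strata[2L]
      tab <- rbind(c(sum(flag[!high]), sum(!flag[!high])),
                   c(sum(flag[high]), sum(!flag[high])))
      degenerate <- any(colSums(tab) == 0)
      if (degenerate) {
        statistic <- NA_real_
        p_value <- NA_real_
      } else {
        test <- chi_square(tab, yates = TRUE)
        statistic <- test$statistic
        p_value <- test$p_value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = endpoint, phase = phase,
        rate_low = sum(flag[!high]) / n_low,
        rate_high = sum(flag[high]) / n_high,
        statistic = statistic, p_value = p_value, degenerate = degenerate,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_per_stratum") <- stats::setNames(c(n_low, n_high), strata)
  class(out) <- c("early_late_profile", "data.frame")
  out
}

#' Conditional stratum distribution of one score within a stratum of another
#'
#' Among patients assigned `filter_stratum` by the filter score, tabulates
#' the strata assigned by the target score (over patients stratifiable by
#' both).
#'
#' @param cohort A validated cohort.
#' @param filter_stratification,target_stratification [stratify_cohort()]
#'   results covering the cohort.
#' @param filter_stratum Stratum label selecting the subset.
#' @return Data frame with `stratum`, `count`, `fraction` (one row per
#'   target stratum); attribute `n_subset` is the subset size.
#' @export
cross_stratification <- function(cohort, filter_stratification, filter_stratum,
                                 target_stratification) {
  fs <- .joined_strat(cohort, filter_stratification)
  ts <- .joined_strat(cohort, target_stratification)
  keep <- fs$stratum == filter_stratum & ts$stratum != "not_stratifiable"
  if (sum(keep) == 0L) {
    stop("analysis error: empty filter subset '", filter_stratum, "'",
         call. = FALSE)
  }
  target_strata <- attr(target_stratification, "strata")
  counts <- table(factor(ts$stratum[keep], levels = target_strata))
  out <- data.frame(stratum = target_strata, count = as.integer(counts),
                    fraction = as.numeric(counts) / sum(keep),
                    stringsAsFactors = FALSE)
  attr(out, "n_subset") <- sum(keep)
  out
}

# Predictor blocks of the nested physiological-system models, in nesting
# order.
.system_predictors <- list(
  acid_base = c("lactate", "ph", "base_excess"),
  coagulation = c("platelet_count", "fibrinogen", "prothrombin_ratio"),
  hemorrhage = c("systolic_bp", "prbc_2h"),
  soft_tissue = c("chest_ais", "abdomen_moore_grade", "extremity_soft_tissue_ais")
)

#' Nested physiological-system prediction models
#'
#' Fits logistic models for strictly nested predictor sets -- acid-base
#' (lactate, pH, base excess), then + coagulation (platelets, fibrinogen,
#' prothrombin ratio), + hemorrhage (systolic blood pressure, 2-h pRBC),
#' + soft tissue (chest AIS, abdominal Moore grade, extremity soft-tissue
#' AIS) -- on the complete cases of the largest set, and reports the
#' in-sample ROC AUC with DeLong 95% CI of each model.
#'
#' @param cohort A validated cohort.
#' @param endpoint Endpoint to predict (default `early_complication`).
#' @return Data frame of class `nested_auc_report`: `model`, `n_predictors`,
#'   `auc`, `ci_low`, `ci_high`, `separation`; attribute `n_used` is the
#'   complete-case subset size.
#' @export
nested_system_auc <- function(cohort, endpoint = "early_complication") {
  all_predictors <- unlist(.system_predictors, use.names = FALSE)
  complete <- rowSums(is.na(as.matrix(cohort[, all_predictors]))) == 0L
  sub <- cohort[complete, , drop = FALSE]
  y <- endpoint_flag(sub, endpoint)
  if (length(unique(y)) < 2L) {
    stop("endpoint must have both classes in the complete-case subset",
         call. = FALSE)
  }
  systems <- names(.system_predictors)
  rows <- list()
  for (i in seq_along(systems)) {
    predictors <- unlist(.system_predictors[seq_len(i)], use.names = FALSE)
    fit <- fit_logistic(as.matrix(sub[, predictors, drop = FALSE]), y)
    est <- roc_auc(fit$fitted, y)
    rows[[i]] <- data.frame(
      model = paste(systems[seq_len(i)], collapse = "+"),
      n_predictors = length(predictors), auc = est$auc, ci_low = est$ci_low,
      ci_high = est$ci_high, separation = fit$separation,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "n_used") <- nrow(sub)
  attr(out, "endpoint") <- endpoint
  class(out) <- c("nested_auc_report", "data.frame")
  out
}
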