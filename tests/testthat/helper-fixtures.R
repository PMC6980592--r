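# Shared fixtures: hand-built patients with normal physiology, and the
# published CGS-vs-mCGS cross-tabulation used by the agreement tests.

make_patient <- function(id = "P1", ...) {
  base <- list(
    patient_id = id, age_years = 40, iss = 20L, niss = 25L, gcs = 15L,
    systolic_bp = 120, lactate = 1.0, ph = 7.40, base_excess = 0,
    platelet_count = 250, fibrinogen = 3.0, prothrombin_ratio = 100,
    inr = 0.9, prbc_2h = 0L, prbc_24h = 0L, temperature_core = 37,
    chest_ais = 0L, abdomen_moore_grade = 0L, extremity_soft_tissue_ais = 0L,
    died = FALSE, death_hour = NA_real_, death_cause = NA_character_,
    pneumonia = FALSE, sepsis = FALSE, bacteraemia = FALSE,
    septic_shock = FALSE, infection = FALSE, ards = FALSE, mof = FALSE
  )
  override <- list(...)
  base[names(override)] <- override
  as.data.frame(base, stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# Published 4x4 cross-tabulation of the CGS-to-mCGS modification
# (rows = mCGS, columns = CGS), 2155 jointly stratified patients.
grading_strata <- c("stable", "borderline", "unstable", "in_extremis")
published_shift_table <- matrix(
  c(757, 193,   9,  1,
      0, 726, 107,  1,
      0,   0, 331, 12,
      0,   0,   0, 18),
  nrow = 4, byrow = TRUE,
  dimnames = list(mCGS = grading_strata, CGS = grading_strata)
)

published_shift_pairs <- function() {
  idx <- which(published_shift_table > 0, arr.ind = TRUE)
  counts <- published_shift_table[idx]
  list(cgs = rep(colnames(published_shift_table)[idx[, 2]], counts),
       mcgs = rep(rownames(published_shift_table)[idx[, 1]], counts))
}

# Closed-form nominal alpha for two raters: Do from the disagreeing unit
# count, De from the category marginals. Independent of the coincidence
# matrix implementation.
nominal_alpha_closed_form <- function(a, b) {
  n_units <- length(a)
  N <- 2 * n_units
  n_c <- table(c(a, b))
  Do <- 2 * sum(a != b) / N
  De <- 1 - sum(n_c * (n_c - 1)) / (N * (N - 1))
  1 - Do / De
}
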