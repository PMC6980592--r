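defs <- shipped_definitions()

test_that("shipped definitions encode the documented structure", {
  eac <- defs$EAC
  expect_equal(eac$strata, c("low_risk", "high_risk"))
  expect_true(all(vapply(eac$criteria, function(cr) cr$pathway, character(1))
                  == "acid_base"))
  expect_setequal(vapply(eac$criteria, function(cr) cr$parameter, character(1)),
                  c("lactate", "ph", "base_excess"))

  expect_equal(defs$PTGS$strata, c("stable", "borderline", "unstable"))
  expect_equal(defs$PTGS$aggregation, "point_sum")

  # transfusion windows: CGS counts 2-hour units, mCGS 24-hour units
  cgs_params <- vapply(defs$CGS$criteria, function(cr) cr$parameter, character(1))
  mcgs_params <- vapply(defs$mCGS$criteria, function(cr) cr$parameter, character(1))
  expect_true("prbc_2h" %in% cgs_params && !("prbc_24h" %in% cgs_params))
  expect_true("prbc_24h" %in% mcgs_params && !("prbc_2h" %in% mcgs_params))
  expect_true("fibrinogen" %in% cgs_params && !("fibrinogen" %in% mcgs_params))
})

test_that("malformed definitions are rejected with definition errors", {
  bad <- list(
    name = "X", strata = c("stable", "borderline", "unstable"),
    aggregation = "worst_criterion",
    criteria = list(list(parameter = "lactate", direction = "high_is_worse",
                         required = TRUE,
                         cuts = list(borderline = list(value = 4, inclusive = TRUE),
                                     unstable = list(value = 2, inclusive = TRUE)))))
  expect_error(validate_score_definition(bad), "monotone")
  bad$criteria[[1]]$parameter <- "haemoglobin"
  expect_error(validate_score_definition(bad), "unknown parameter")
  bad$criteria[[1]]$parameter <- "lactate"
  bad$aggregation <- "point_sum"
  expect_error(validate_score_definition(bad), "monotone|point")
})

test_that("criterion evaluation honours exclusive and inclusive boundaries", {
  bp <- defs$PTGS$criteria[[
    which(vapply(defs$PTGS$criteria, function(cr) cr$parameter, character(1))
          == "systolic_bp")]]
  strata <- defs$PTGS$strata
  expect_equal(evaluate_criterion(120, bp, strata), "stable")
  expect_equal(evaluate_criterion(70, bp, strata), "borderline")
  expect_equal(evaluate_criterion(75, bp, strata), "stable") # "< 75" is exclusive
  expect_equal(evaluate_criterion(59, bp, strata), "unstable")

  prbc <- defs$CGS$criteria[[
    which(vapply(defs$CGS$criteria, function(cr) cr$parameter, character(1))
          == "prbc_2h")]]
  expect_equal(evaluate_criterion(15, prbc, defs$CGS$strata), "in_extremis")
  expect_error(evaluate_criterion(NA, prbc, defs$CGS$strata), "present")
})

test_that("completeness requires every required parameter", {
  expect_true(completeness(make_patient("A"), defs$EAC))
  expect_true(completeness(make_patient("A", chest_ais = NA_integer_), defs$CGS))
  expect_false(completeness(make_patient("A", fibrinogen = NA_real_), defs$CGS))
  expect_true(completeness(make_patient("A", fibrinogen = NA_real_), defs$mCGS))
  expect_false(completeness(make_patient("A", lactate = NA_real_), defs$EAC))
})

test_that("an all-normal patient is lowest stratum everywhere, untriggered", {
  normal <- make_patient("N")
  for (def in defs) {
    res <- stratify(normal, def)
    expect_equal(res$stratum, def$strata[1])
    expect_equal(nrow(res$triggered), 0L)
  }
})

test_that("deranged acid-base physiology is EAC high risk with both criteria", {
  res <- stratify(make_patient("A", lactate = 6.0, ph = 7.1), defs$EAC)
  expect_equal(res$stratum, "high_risk")
  expect_setequal(res$triggered$parameter, c("lactate", "ph"))
})

test_that("stratify is deterministic and matches the cohort-level path", {
  cohort <- generate_cohort(default_params(), n = 200, seed = 3)
  strat <- stratify_cohort(cohort, defs$CGS)
  for (i in c(1, 50, 137, 200)) {
    single <- stratify(cohort[i, ], defs$CGS)
    expect_identical(single$stratum, strat$stratum[i])
    expect_identical(single$stratum,
                     stratify(cohort[i, ], defs$CGS)$stratum)
  }
})

test_that("cohort coverage counts stratifiable patients", {
  cohort <- make_cohort(
    make_patient("A"), make_patient("B"), make_patient("C"),
    make_patient("D", lactate = NA_real_))
  strat <- stratify_cohort(cohort, defs$EAC)
  expect_equal(attr(strat, "coverage"), 0.75)
  expect_equal(strat$stratum[4], "not_stratifiable")

  empty <- stratify_cohort(generate_cohort(default_params(), n = 0), defs$EAC)
  expect_true(is.na(attr(empty, "coverage")))
  expect_true(attr(empty, "coverage_undefined"))
})

test_that("default missingness orders coverage EAC > CGS > PTGS ~ mCGS", {
  cohort <- generate_cohort(default_params(), n = 20000, seed = 5)
  cov <- vapply(defs, function(def) attr(stratify_cohort(cohort, def), "coverage"),
                numeric(1))
  expect_gt(cov[["EAC"]], cov[["CGS"]])
  expect_gt(cov[["CGS"]], cov[["PTGS"]])
  expect_gt(cov[["CGS"]], cov[["mCGS"]])
  expect_lt(abs(cov[["PTGS"]] - cov[["mCGS"]]), 0.03)
})

test_that("worsening any single parameter never lowers the stratum", {
  params <- default_params()
  params$missingness[] <- 0
  cohort <- generate_cohort(params, n = 150, seed = 13)
  set.seed(99)
  for (def in defs) {
    base <- stratify_cohort(cohort, def)
    for (cr in def$criteria) {
      worse <- cohort
      shift <- stats::runif(nrow(cohort), 0, 20)
      worse[[cr$parameter]] <- if (cr$direction == "high_is_worse") {
        worse[[cr$parameter]] + shift
      } else {
        worse[[cr$parameter]] - shift
      }
      res <- .stratify_bands(worse, def)
      expect_true(all(res$band >= base$stratum_index, na.rm = TRUE),
                  info = paste(def$name, cr$parameter))
    }
  }
})

test_that("the mCGS never grades a patient more severely than the CGS", {
  cohort <- generate_cohort(default_params(), n = 20000, seed = 17)
  cgs <- stratify_cohort(cohort, defs$CGS)
  mcgs <- stratify_cohort(cohort, defs$mCGS)
  both <- cgs$stratum != "not_stratifiable" & mcgs$stratum != "not_stratifiable"
  expect_gt(sum(both), 1000)
  expect_true(all(mcgs$stratum_index[both] <= cgs$stratum_index[both]))
})

test_that("EAC stratification depends only on acid-base fields", {
  cohort <- generate_cohort(default_params(), n = 500, seed = 19)
  base <- stratify_cohort(cohort, defs$EAC)$stratum
  perturbed <- cohort
  for (field in c("systolic_bp", "platelet_count", "fibrinogen", "prbc_2h",
                  "prbc_24h", "chest_ais", "iss", "niss", "temperature_core")) {
    perturbed[[field]] <- rev(perturbed[[field]])
  }
  expect_identical(stratify_cohort(perturbed, defs$EAC)$stratum, base)
})
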