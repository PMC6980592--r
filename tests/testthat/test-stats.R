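test_that("odds ratio matches the closed form and flags zero cells", {
  est <- odds_ratio(matrix(c(10, 10, 10, 10), 2, byrow = TRUE))
  expect_equal(est$or, 1)
  expect_lt(est$ci_low, 1)
  expect_gt(est$ci_high, 1)

  # counts reconstructed from published stratum sizes and event rates
  est <- odds_ratio(matrix(c(158, 123, 390, 2355), 2, byrow = TRUE))
  expect_equal(est$or, (158 * 2355) / (123 * 390))
  expect_equal(round(est$or, 2), 7.76)

  est <- odds_ratio(matrix(c(5, 0, 10, 90), 2, byrow = TRUE))
  expect_true(est$corrected)
  expect_true(is.finite(est$or) && est$or > 0)
  expect_error(odds_ratio(matrix(c(0, 0, 10, 90), 2, byrow = TRUE)), "margin")
})

test_that("odds ratio symmetry: table flips invert or preserve the estimate", {
  set.seed(42)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    est <- odds_ratio(tab)
    expect_equal(odds_ratio(tab[2:1, 2:1])$or, est$or)
    expect_equal(odds_ratio(tab[2:1, ])$or, 1 / est$or)
    expect_equal(odds_ratio(tab[, 2:1])$or, 1 / est$or)
  }
})

test_that("chi-square matches the textbook formula and base R on all small 2x2s", {
  grid <- expand.grid(a = 0:5, b = 0:5, c = 0:5, d = 0:5)
  for (i in seq_len(nrow(grid))) {
    tab <- matrix(as.numeric(grid[i, ]), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    plain <- chi_square(tab)
    yates <- chi_square(tab, yates = TRUE)
    oracle_plain <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    oracle_yates <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(plain$statistic, unname(oracle_plain$statistic))
    expect_equal(plain$p_value, oracle_plain$p.value)
    expect_equal(yates$statistic, unname(oracle_yates$statistic))
    expect_lte(yates$statistic, plain$statistic)
    # odds-ratio closed form on the same exhaustive fixtures
    if (all(tab > 0)) {
      expect_equal(odds_ratio(tab)$or, tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
    }
  }
})

test_that("chi-square degenerate and usage errors", {
  tab <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(chi_square(tab)$statistic, 0)
  expect_equal(chi_square(tab)$p_value, 1)
  expect_error(chi_square(matrix(c(3, 0, 4, 0, 5, 0), 2), yates = FALSE),
               "zero expected")
  expect_error(chi_square(matrix(1:6, 2), yates = TRUE), "2x2")
})

test_that("Krippendorff alpha reproduces hand-computed coincidence values", {
  expect_equal(krippendorff_alpha(c("a", "b", "a"), c("a", "b", "a"))$alpha, 1)

  est <- krippendorff_alpha(c("a", "b"), c("b", "a"))
  expect_equal(est$Do, 1)
  expect_equal(est$De, 2 / 3)
  expect_equal(est$alpha, -0.5)

  expect_error(krippendorff_alpha(c("a", "a"), c("a", "a")), "undefined")
})

test_that("nominal alpha equals the closed form on every small pairing", {
  cats <- c("lo", "hi")
  for (n_units in 2:4) {
    combos <- expand.grid(rep(list(1:4), n_units))
    pair_map <- expand.grid(a = cats, b = cats, stringsAsFactors = FALSE)
    for (row in seq_len(nrow(combos))) {
      a <- pair_map$a[as.integer(combos[row, ])]
      b <- pair_map$b[as.integer(combos[row, ])]
      if (length(unique(c(a, b))) < 2) next # De = 0, alpha undefined
      est <- krippendorff_alpha(a, b, categories = cats)
      expect_equal(est$alpha, nominal_alpha_closed_form(a, b))
      # symmetry in the raters and invariance to unit order
      expect_equal(krippendorff_alpha(b, a, categories = cats)$alpha, est$alpha)
      perm <- sample(seq_along(a))
      expect_equal(krippendorff_alpha(a[perm], b[perm], categories = cats)$alpha,
                   est$alpha)
    }
  }
})

test_that("ordinal and interval metrics respect distance structure", {
  a <- c("s", "s", "b", "u", "u", "b")
  b <- c("s", "b", "b", "u", "b", "u")
  cats <- c("s", "b", "u")
  nominal <- krippendorff_alpha(a, b, "nominal", cats)$alpha
  ordinal <- krippendorff_alpha(a, b, "ordinal", cats)$alpha
  interval <- krippendorff_alpha(a, b, "interval", cats)$alpha
  # all disagreements here are one-step, so distance metrics forgive more
  expect_gt(ordinal, nominal)
  expect_gt(interval, nominal)
})

test_that("ROC AUC equals brute-force pair counting on random small fixtures", {
  brute <- function(scores, labels) {
    pos <- scores[labels]
    neg <- scores[!labels]
    total <- 0
    for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
    total / (length(pos) * length(neg))
  }
  set.seed(7)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    scores <- sample(1:4, n, replace = TRUE) # heavy ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_identical(roc_auc(scores, labels)$auc, brute(scores, labels))
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))$auc, 0.75)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both outcome classes")
})

test_that("AUC and DeLong interval agree with pROC", {
  set.seed(21)
  scores <- rnorm(400)
  labels <- runif(400) < plogis(scores)
  est <- roc_auc(scores, labels)
  oracle <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE),
                         method = "delong")
  expect_equal(est$auc, as.numeric(oracle[2]))
  expect_equal(est$ci_low, as.numeric(oracle[1]), tolerance = 1e-8)
  expect_equal(est$ci_high, as.numeric(oracle[3]), tolerance = 1e-8)
})

test_that("random scores give chance-level AUC", {
  set.seed(31)
  scores <- rnorm(10000)
  labels <- runif(10000) < 0.3
  est <- roc_auc(scores, labels)
  expect_lt(est$ci_low, 0.5)
  expect_gt(est$ci_high, 0.5)
})

test_that("logistic IRLS solves the score equations and matches glm", {
  set.seed(5)
  x <- cbind(x1 = rnorm(2000), x2 = rexp(2000))
  y <- runif(2000) < plogis(-0.5 + 0.7 * x[, 1] - 0.3 * x[, 2])
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  expect_lt(fit$max_score, 1e-8)
  oracle <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(oracle)), tolerance = 1e-6)
  # score equations on the original scale
  X <- cbind(1, x)
  expect_lt(max(abs(crossprod(X, y - fit$fitted))), 1e-6)
})

test_that("a null predictor yields slope 0 and intercept logit(mean)", {
  set.seed(9)
  x <- matrix(rnorm(2000), ncol = 1)
  y <- runif(2000) < 0.25
  fit <- fit_logistic(x, y)
  expect_lt(abs(fit$coefficients[2]), 3 * fit$se[2])
  expect_equal(unname(fit$coefficients[1]), qlogis(mean(y)), tolerance = 0.2)
})

test_that("separation is flagged, constant responses are rejected", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  fit <- fit_logistic(x, y)
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_error(fit_logistic(x, rep(TRUE, 6)), "constant")
})

test_that("duplicated predictors do not change the fitted probabilities", {
  set.seed(13)
  x <- matrix(rnorm(500), ncol = 1)
  y <- runif(500) < plogis(x[, 1])
  fit1 <- fit_logistic(x, y)
  fit2 <- fit_logistic(cbind(x, x, x), y)
  expect_equal(fit2$fitted, fit1$fitted, tolerance = 1e-8)
})
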