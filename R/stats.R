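# Core estimators used by the validation pipeline. All of them are written
# out from their defining formulas; established library routines are used
# only as independent oracles in the test suite.

#' Labeled contingency table
#'
#' @param counts Matrix (or coercible) of non-negative integer counts.
#' @param row_labels,col_labels Optional axis labels.
#' @return A `contingency_table` (an integer matrix with dimnames).
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("contingency table counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("contingency table total must be > 0", call. = FALSE)
  storage.mode(counts) <- "double"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  structure(counts, class = c("contingency_table", class(counts)))
}

#' Odds ratio for a 2x2 table with Woolf confidence interval
#'
#' Computes OR = (a d)/(b c) for a table with the exposed stratum in row 1
#' and the reference stratum in row 2 (events in column 1). The 95% interval
#' uses the log-OR normal approximation with standard error
#' sqrt(1/a + 1/b + 1/c + 1/d); if any cell is zero, 0.5 is added to every
#' cell first (Haldane-Anscombe) and the estimate is flagged. The p-value is
#' the two-sided Wald z test on the log odds ratio.
#'
#' @param table A 2x2 count matrix.
#' @param conf_level Confidence level (default 0.95).
#' @return An `or_estimate`: list with `or`, `ci_low`, `ci_high`, `p_value`,
#'   `corrected` (zero-cell flag), `method`, and the input table.
#' @export
odds_ratio <- function(table, conf_level = 0.95) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("odds_ratio requires a 2x2 table", call. = FALSE)
  if (any(tab < 0) || sum(tab) == 0) stop("invalid counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("odds ratio undefined: a table margin is zero", call. = FALSE)
  }
  corrected <- any(tab == 0)
  w <- if (corrected) tab + 0.5 else tab
  or <- (w[1, 1] * w[2, 2]) / (w[1, 2] * w[2, 1])
  se <- sqrt(sum(1 / w))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    or = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    p_value = 2 * stats::pnorm(-abs(log(or) / se)),
    corrected = corrected,
    method = "woolf_log_normal",
    table = tab
  ), class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), p = %.4g%s\n", x$or, x$ci_low,
              x$ci_high, x$p_value,
              if (x$corrected) " [zero-cell corrected]" else ""))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic sum((O - E)^2 / E) with df = (r-1)(c-1); with
#' `yates = TRUE` (2x2 only) the continuity correction subtracts 0.5 from
#' each |O - E|, floored at zero.
#'
#' @param table Count matrix.
#' @param yates Apply Yates continuity correction (2x2 tables only).
#' @return A `chi_square_result`: `statistic`, `df`, `p_value`,
#'   `yates_corrected`.
#' @export
chi_square <- function(table, yates = FALSE) {
  tab <- as.matrix(table)
  if (any(tab < 0) || sum(tab) == 0) stop("invalid counts", call. = FALSE)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2x2", call. = FALSE)
  if (yates && !all(dim(tab) == c(2L, 2L))) {
    stop("Yates correction is defined for 2x2 tables only", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    zero <- which(expected == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("zero expected count in cell (%d, %d): empty margin",
                 zero[1L], zero[2L]), call. = FALSE)
  }
  dev <- abs(tab - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(
    statistic = statistic,
    df = df,
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
    yates_corrected = yates
  ), class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("chi-square%s = %.4f, df = %d, p = %.4g\n",
              if (x$yates_corrected) " (Yates)" else "", x$statistic, x$df,
              x$p_value))
  invisible(x)
}

#' Krippendorff's alpha for two ratings per unit
#'
#' Chance-corrected agreement alpha = 1 - Do/De over the coincidence matrix:
#' each unit contributes both ordered pairs of its two ratings, giving
#' coincidences o_ck with category marginals n_c and grand total N = 2 x
#' units. Do = sum(o_ck d(c,k))/N and De = sum(n_c n_k d(c,k))/(N(N-1)) with
#' the difference function d of the chosen metric: nominal d = 1(c != k),
#' ordinal d = (sum of n_g from c to k minus (n_c + n_k)/2)^2, interval
#' d = (x_c - x_k)^2 on the category values.
#'
#' @param a,b Ratings of the two scores/raters, one element per unit, drawn
#'   from a shared (ordered) category set.
#' @param metric One of `"nominal"`, `"ordinal"`, `"interval"`.
#' @param categories Ordered category set; defaults to the sorted union of
#'   the observed labels.
#' @return An `alpha_estimate`: `alpha`, `metric`, `Do`, `De`, `coincidence`,
#'   `n_units`.
#' @export
krippendorff_alpha <- function(a, b, metric = c("nominal", "ordinal", "interval"),
                               categories = NULL) {
  metric <- match.arg(metric)
  if (length(a) != length(b)) stop("ratings must be paired", call. = FALSE)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) < 2L) stop("need at least 2 rated units", call. = FALSE)
  if (is.null(categories)) categories <- sort(unique(c(a, b)))
  fa <- factor(a, levels = categories)
  fb <- factor(b, levels = categories)
  if (anyNA(fa) || anyNA(fb)) stop("rating outside category set", call. = FALSE)

  cross <- table(fa, fb)
  coincidence <- unclass(cross) + t(unclass(cross))
  n_c <- rowSums(coincidence)
  N <- sum(n_c)
  K <- length(categories)

  delta <- switch(metric,
    nominal = 1 - diag(K),
    interval = {
      x <- suppressWarnings(as.numeric(categories))
      if (anyNA(x)) x <- seq_len(K) # fall back to rank scores
      outer(x, x, function(i, j) (i - j)^2)
    },
    ordinal = {
      d <- matrix(0, K, K)
      for (c in seq_len(K)) {
        for (k in seq_len(K)) {
          if (c == k) next
          g <- seq(min(c, k), max(c, k))
          d[c, k] <- (sum(n_c[g]) - (n_c[c] + n_c[k]) / 2)^2
        }
      }
      d
    }
  )

  Do <- sum(coincidence * delta) / N
  De <- sum(outer(n_c, n_c) * delta) / (N * (N - 1))
  if (De == 0) {
    stop("alpha undefined: no expected disagreement (single observed category)",
         call. = FALSE)
  }
  structure(list(
    alpha = 1 - Do / De,
    metric = metric,
    Do = Do,
    De = De,
    coincidence = coincidence,
    n_units = length(a)
  ), class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat(sprintf("Krippendorff alpha (%s) = %.4f  [Do = %.4f, De = %.4f, units = %d]\n",
              x$metric, x$alpha, x$Do, x$De, x$n_units))
  invisible(x)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit. Predictors are standardized internally
#' (coefficients are back-transformed to the original scale); exactly
#' collinear columns are dropped via a pivoted QR, so duplicated predictors
#' leave the fitted probabilities unchanged. Convergence requires the
#' maximum absolute score-equation residual sum(x_i (y_i - p_i)) to fall
#' below `tol`. Complete separation is flagged (diverging standardized
#' coefficients or non-convergence), never silently returned as converged.
#'
#' @param x Numeric predictor matrix (one column per predictor, no
#'   intercept column) or vector.
#' @param y Logical (or 0/1) response.
#' @param tol Score-equation convergence tolerance (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @return A `logistic_model`: `coefficients` (intercept first, NA for
#'   dropped aliased columns), `se`, `fitted`, `converged`, `separation`,
#'   `n_iterations`, `max_score` (largest score residual at exit).
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be boolean/0-1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("response is constant", call. = FALSE)
  if (nrow(x) != length(y)) stop("predictor/response length mismatch", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  keep_sd <- scale > 0
  xs <- sweep(sweep(x[, keep_sd, drop = FALSE], 2L, center[keep_sd]), 2L,
              scale[keep_sd], "/")
  # drop exactly collinear columns
  qrx <- qr(cbind(1, xs))
  keep_qr <- qrx$pivot[seq_len(qrx$rank)]
  keep_qr <- sort(setdiff(keep_qr, 1L)) - 1L
  xs <- xs[, keep_qr, drop = FALSE]
  X <- cbind(`(intercept)` = 1, xs)
  p <- ncol(X)

  beta <- c(stats::qlogis(mean(y)), rep(0, p - 1L))
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  max_score <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    max_score <- max(abs(score))
    if (max_score < tol) {
      converged <- TRUE
      break
    }
    w <- pmax(mu * (1 - mu), 1e-10)
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      separation <- TRUE
      break
    }
    beta <- beta + step
    if (max(abs(beta[-1L])) > 30) { # standardized scale: implies separation
      separation <- TRUE
      break
    }
  }
  if (!converged) separation <- TRUE

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  if (max(abs(y - mu)) < 1e-6) { # perfect fit: the MLE does not exist
    separation <- TRUE
    converged <- FALSE
  }
  # back-transform to original scale
  kept_names <- colnames(xs)
  coef_out <- stats::setNames(rep(NA_real_, ncol(x) + 1L),
                              c("(intercept)", colnames(x)))
  slopes <- beta[-1L] / scale[kept_names]
  coef_out[kept_names] <- slopes
  coef_out["(intercept)"] <- beta[1L] - sum(slopes * center[kept_names])

  se_out <- stats::setNames(rep(NA_real_, ncol(x) + 1L),
                            c("(intercept)", colnames(x)))
  if (converged) {
    Xo <- cbind(1, x[, kept_names, drop = FALSE])
    w <- pmax(mu * (1 - mu), 1e-10)
    cov <- tryCatch(solve(crossprod(Xo * w, Xo)), error = function(e) NULL)
    if (!is.null(cov)) {
      se_out[c("(intercept)", kept_names)] <- sqrt(diag(cov))
    }
  }

  structure(list(
    coefficients = coef_out,
    se = se_out,
    fitted = mu,
    converged = converged,
    separation = separation,
    n_iterations = iter,
    max_score = max_score
  ), class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> %s in %d iterations (max score %.2g)%s\n",
              if (x$converged) "converged" else "did not converge",
              x$n_iterations, x$max_score,
              if (x$separation) " [separation]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC as the Mann-Whitney probability that a random positive scores above a
#' random negative, ties counted 1/2 (computed from midranks). The 95%
#' interval uses the DeLong placement-value variance, truncated to \[0, 1\].
#'
#' @param scores Numeric risk scores.
#' @param labels Logical (or 0/1) outcome labels; both classes must occur.
#' @param conf_level Confidence level (default 0.95).
#' @return An `auc_estimate`: `auc`, `ci_low`, `ci_high`, `se`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must be complete and paired", call. = FALSE)
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r_all <- rank(scores)
  auc <- (sum(r_all[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # DeLong placements via within-class midranks
  r_pos <- rank(scores[labels])
  r_neg <- rank(scores[!labels])
  v10 <- (r_all[labels] - r_pos) / n0        # P(neg < pos_i), ties 1/2
  v01 <- 1 - (r_all[!labels] - r_neg) / n1   # P(pos > neg_j), ties 1/2
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    auc = auc,
    ci_low = max(0, auc - z * se),
    ci_high = min(1, auc + z * se),
    se = se,
    n_pos = n1,
    n_neg = n0
  ), class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f; %d pos / %d neg)\n", x$auc,
              x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}
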