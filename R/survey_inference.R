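#' Complex survey design with replicate weights
#'
#' Holds one calibration weight and R replicate weight sets per participant.
#' Variance of any estimator theta is estimated by the replication rule
#' \deqn{v = f \sum_r (\theta_r - \theta)^2}
#' where theta_r re-computes the estimator under replicate weight set r and f
#' is the variance factor, (R-1)/R by default — the delete-a-group jackknife
#' convention used for national health survey replicate weights.
#'
#' @param participant_id identifiers, length n.
#' @param weight calibration weights, positive.
#' @param rep_weights n x R matrix of replicate weights (non-negative).
#' @param variance_factor multiplier for the replicate sum of squares;
#'   default (R-1)/R.
#' @return object of class "survey_design_rw".
#' @export
survey_design <- function(participant_id, weight, rep_weights,
                          variance_factor = NULL) {
  rep_weights <- as.matrix(rep_weights)
  n <- length(participant_id)
  if (length(weight) != n || nrow(rep_weights) != n)
    stop("weights are not aligned with participant ids")
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("calibration weights must be positive and finite")
  if (any(!is.finite(rep_weights)) || any(rep_weights < 0))
    stop("replicate weights must be non-negative and finite")
  R <- ncol(rep_weights)
  if (R < 2L) stop("at least 2 replicate weight sets are required")
  if (is.null(variance_factor)) variance_factor <- (R - 1) / R
  structure(list(participant_id = as.character(participant_id),
                 weight = as.numeric(weight), rep_weights = rep_weights,
                 variance_factor = variance_factor),
            class = "survey_design_rw")
}

#' @export
print.survey_design_rw <- function(x, ...) {
  cat("Replicate-weight survey design:", length(x$weight), "participants,",
      ncol(x$rep_weights), "replicate weight sets, variance factor",
      signif(x$variance_factor, 4), "\n")
  invisible(x)
}

rep_se <- function(theta, theta_r, variance_factor) {
  sqrt(variance_factor * sum((theta_r - theta)^2))
}

#' Survey-weighted mean with replicate standard error
#'
#' @param x numeric values aligned with the design.
#' @param design a [survey_design()].
#' @return list with estimate and se.
#' @export
weighted_mean <- function(x, design) {
  stopifnot(inherits(design, "survey_design_rw"))
  if (length(x) != length(design$weight)) stop("values not aligned with design")
  if (any(!is.finite(x))) stop("values must be finite")
  est <- sum(design$weight * x) / sum(design$weight)
  theta_r <- apply(design$rep_weights, 2L, function(w) {
    sw <- sum(w)
    if (sw <= 0) stop("a replicate weight set sums to zero")
    sum(w * x) / sw
  })
  list(estimate = est, se = rep_se(est, theta_r, design$variance_factor))
}

#' Survey-weighted proportion
#' @param flag logical vector.
#' @inheritParams weighted_mean
#' @return list with estimate and se.
#' @export
weighted_proportion <- function(flag, design) weighted_mean(as.numeric(flag), design)

glm_family <- function(family) {
  switch(family,
         linear = stats::gaussian(),
         # quasibinomial: identical IRLS point estimates to binomial, without
         # integer-count warnings under fractional survey weights
         logistic = stats::quasibinomial(),
         stop("family must be 'linear' or 'logistic'"))
}

fit_one <- function(X, y, w, fam, start = NULL) {
  stats::glm.fit(X, y, weights = w, family = fam, start = start,
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100L))
}

#' Survey-weighted regression with replicate-weight standard errors
#'
#' Point estimates come from weighted least squares (linear) or weighted
#' maximum likelihood via iteratively reweighted least squares (logistic)
#' under the calibration weights; standard errors re-fit the full model under
#' each replicate weight set and apply the replication variance rule.
#' Confidence intervals are normal-approximation (estimate +/- 1.96 se) and
#' odds ratios are exp(coefficient) per unit of the predictor.
#'
#' @param formula model formula; the outcome may be wrapped with
#'   `log_outcome = TRUE` to model its natural log (used for right-skewed
#'   outcomes such as TAG, glucose, HbA1c, HDL, systolic BP, waist
#'   circumference and BMI).
#' @param data data.frame, no missing values in the model variables
#'   (missingness is handled upstream by exclusion).
#' @param design a [survey_design()] aligned row-for-row with `data`.
#' @param family "linear" or "logistic".
#' @param log_outcome if TRUE, model log(outcome).
#' @return object of class "svyfit_rw": a list with a coefficient table
#'   (term, estimate, se, ci_low, ci_high, p, and odds_ratio columns for
#'   logistic fits), the family and call.
#' @export
fit_survey_glm <- function(formula, data, design,
                           family = c("linear", "logistic"),
                           log_outcome = FALSE) {
  family <- match.arg(family)
  stopifnot(inherits(design, "survey_design_rw"))
  if (nrow(data) != length(design$weight))
    stop("data rows are not aligned with the survey design")
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (log_outcome) {
    if (any(y <= 0)) stop("log transform requires a strictly positive outcome")
    y <- log(y)
  }
  if (family == "logistic") y <- as.numeric(y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(drop, collapse = ", "))
  }
  fam <- glm_family(family)
  # normalise the weight scale: point estimates are scale invariant and the
  # deviance stays O(n)
  w0 <- design$weight / mean(design$weight)
  main <- fit_one(X, y, w0, fam)
  if (!main$converged) {
    worst <- colnames(X)[which.max(abs(main$coefficients))]
    stop("model did not converge (possible perfect separation); ",
         "largest coefficient: ", worst)
  }
  beta <- main$coefficients
  scl <- mean(design$weight)
  brep <- apply(design$rep_weights, 2L, function(w) {
    fit <- fit_one(X, y, w / scl, fam, start = beta)
    fit$coefficients
  })
  if (is.null(dim(brep))) brep <- matrix(brep, nrow = 1L)
  se <- sqrt(design$variance_factor * rowSums((brep - beta)^2))
  z <- beta / se
  tab <- data.frame(term = names(beta), estimate = unname(beta),
                    se = unname(se),
                    ci_low = unname(beta - 1.96 * se),
                    ci_high = unname(beta + 1.96 * se),
                    p = unname(2 * stats::pnorm(-abs(z))),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (family == "logistic") {
    tab$odds_ratio <- exp(tab$estimate)
    tab$or_low <- exp(tab$ci_low)
    tab$or_high <- exp(tab$ci_high)
  }
  structure(list(coefficients = tab, family = family,
                 log_outcome = log_outcome, formula = formula,
                 n = nrow(data), converged = main$converged),
            class = "svyfit_rw")
}

#' @export
print.svyfit_rw <- function(x, ...) {
  cat("Survey-weighted", x$family, "regression",
      if (x$log_outcome) "(log outcome)" else "", "on", x$n, "participants\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Extract one term from a survey fit
#' @param fit an object from [fit_survey_glm()].
#' @param term coefficient name.
#' @return one-row data.frame from the coefficient table.
#' @export
fit_term <- function(fit, term) {
  row <- fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
  if (nrow(row) != 1L) stop("term not found in fit: ", term)
  row
}

#' Linear trend test across score quintiles
#'
#' Tests the ordinal quintile index (treated as numeric 1-5) in a
#' survey-weighted model of the outcome with the stated covariates; the
#' p-value is the normal-approximation test of the quintile slope with
#' replicate-weight standard error.
#'
#' @param outcome numeric outcome values.
#' @param quintile integer quintile membership 1-5.
#' @param design a [survey_design()].
#' @param covariates optional data.frame of adjustment covariates.
#' @param family,log_outcome passed to [fit_survey_glm()].
#' @return list with estimate, se and p for the trend term.
#' @export
trend_test <- function(outcome, quintile, design, covariates = NULL,
                       family = "linear", log_outcome = FALSE) {
  if (length(unique(outcome)) < 2L)
    stop("degenerate trend test: outcome is constant")
  dat <- data.frame(.outcome = outcome, .quintile = as.numeric(quintile))
  rhs <- ".quintile"
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates)
    rhs <- paste(c(".quintile", names(covariates)), collapse = " + ")
  }
  fit <- fit_survey_glm(stats::as.formula(paste(".outcome ~", rhs)), dat,
                        design, family = family, log_outcome = log_outcome)
  row <- fit_term(fit, ".quintile")
  list(estimate = row$estimate, se = row$se, p = row$p)
}

#' Design-based Pearson chi-square test
#'
#' Pearson chi-square on the survey-weighted contingency table (rescaled to
#' the unweighted sample size) with a first-order design-effect correction:
#' the statistic is divided by the Kish design effect 1 + CV^2 of the
#' weights. With equal weights this reduces exactly to the textbook Pearson
#' statistic on the raw counts. Pairwise group comparisons conventionally use
#' the Bonferroni-corrected threshold 0.005 (10 pairwise quintile contrasts).
#'
#' @param var_a,var_b categorical variables (factors or coercible).
#' @param design a [survey_design()].
#' @param design_correction apply the design-effect correction (default TRUE).
#' @return list with statistic, df, p and deff.
#' @export
categorical_test <- function(var_a, var_b, design, design_correction = TRUE) {
  a <- factor(var_a); b <- factor(var_b)
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both variables need at least 2 levels")
  w <- design$weight
  tab <- tapply(w, list(a, b), sum)
  tab[is.na(tab)] <- 0
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("empty row/column collapsed out of the contingency table")
    tab <- tab[!zr, !zc, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L)
      stop("contingency table degenerate after collapsing empty margins")
  }
  n <- length(w)
  counts <- tab / sum(tab) * n
  expected <- outer(rowSums(counts), colSums(counts)) / n
  X2 <- sum((counts - expected)^2 / expected)
  deff <- if (design_correction) 1 + stats::var(w) * (n - 1) / n / mean(w)^2 else 1
  X2 <- X2 / deff
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = X2, df = df, p = stats::pchisq(X2, df, lower.tail = FALSE),
       deff = deff)
}
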