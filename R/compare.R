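#' Covariate-matched predicted normative profile
#'
#' The reference profile for a patient is not the grand mean of the norm
#' group but the scores predicted for a norm-group member with the
#' patient's age, gender and education.  Covariates must be expressed on
#' the norm group's centered scale (see [centering_info()]): subtract the
#' norm group's covariate means, never the patient's own.
#'
#' @param model an `mnc_fit`.
#' @param covariates named list or vector with one value per model
#'   covariate (e.g. `c(age = 7.5, gender = 1, education = 0.3)` on the
#'   centered scale).  Ignored for an intercept-only model.
#' @return numeric vector of length p of predicted test scores.
#' @export
predict_profile <- function(model, covariates = NULL) {
  cv <- numeric(length(model$covariates))
  if (length(model$covariates) > 0L) {
    if (is.null(covariates)) stop("model has covariates; supply values")
    covariates <- unlist(covariates)
    if (!is.null(names(covariates)) &&
        all(model$covariates %in% names(covariates))) {
      cv <- as.numeric(covariates[model$covariates])
    } else if (length(covariates) == length(cv)) {
      cv <- as.numeric(covariates)
    } else {
      stop("covariates must be named or match the model's covariate order")
    }
  }
  drop(model$gamma %*% c(1, cv))
}

#' Adapted Hotelling T-squared for a single profile against norms
#'
#' Computes the normative T-squared statistic
#' \deqn{T^2 = \frac{1}{(n+1)/n}\,\frac{n-p}{(n-1)p}\,
#'   (\hat y - x)' C^{-1} (\hat y - x)}
#' and refers it to the F distribution with `p` numerator and `df2`
#' denominator degrees of freedom.  For norms pooled over studies, `C` is
#' the combined covariance, `n` the total number of norm participants and
#' `df2` the adjusted degrees of freedom ([adjusted_df()]), replacing the
#' classical `n - p`.
#'
#' @param x patient score vector (length p, complete).
#' @param y_hat predicted normative profile (length p).
#' @param C p x p norm-group covariance (positive definite).
#' @param n number of participants in the norm group.
#' @param df2 denominator degrees of freedom.
#' @return list with elements `t2` and `p_value` (two-sided).
#' @export
t2_norm <- function(x, y_hat, C, n, df2) {
  p <- length(x)
  if (any(!is.finite(x))) stop("patient scores must be finite and complete")
  if (n <= p) stop("n must exceed the number of tests")
  if (df2 < 1) stop("df2 must be at least 1")
  d <- y_hat - x
  ch <- tryCatch(chol(C), error = function(e)
    stop("covariance matrix is not positive definite (singular or ",
         "ill-conditioned)", call. = FALSE))
  z <- backsolve(ch, d, transpose = TRUE)
  maha <- sum(z^2)
  t2 <- (n / (n + 1)) * ((n - p) / ((n - 1) * p)) * maha
  list(t2 = t2, p_value = stats::pf(t2, p, df2, lower.tail = FALSE))
}

#' Per-test univariate normative comparisons
#'
#' For each test, the patient's score is compared to the covariate-matched
#' prediction with a normative t statistic
#' \eqn{t_m = (x_m - \hat y_m) / \sqrt{C_{mm}\,(n+1)/n}}, referred to the t
#' distribution with `df2` degrees of freedom.  One-sided p-values take
#' lower scores as the impaired direction.  Significance is flagged both
#' uncorrected at `alpha` and Bonferroni-corrected at `alpha / p`.
#'
#' @inheritParams t2_norm
#' @param alpha per-test significance level (default 0.05).
#' @return data.frame with one row per test: `deviation` (x - y_hat),
#'   `std_deviation`, `t`, `p_one_sided`, `sig_uncorrected`,
#'   `sig_bonferroni`.
#' @export
univariate_comparisons <- function(x, y_hat, C, n, df2, alpha = 0.05) {
  p <- length(x)
  v <- diag(C)
  if (any(v <= 0)) stop("non-positive variance on the diagonal of C")
  dev <- x - y_hat
  tstat <- dev / sqrt(v * (n + 1) / n)
  pval <- stats::pt(tstat, df2)  # lower tail: impairment = low scores
  data.frame(test = seq_len(p),
             deviation = dev,
             std_deviation = dev / sqrt(v),
             t = tstat,
             p_one_sided = pval,
             sig_uncorrected = pval <= alpha,
             sig_bonferroni = pval <= alpha / p)
}

#' Compare a patient profile to covariate-matched multilevel norms
#'
#' Runs the full normative comparison: predicts the patient's normative
#' profile from the fitted model and their covariates, computes the
#' adapted Hotelling T-squared against the combined covariance with
#' adjusted degrees of freedom, applies the one-sided two-criterion
#' decision rule, and reports per-test univariate comparisons with and
#' without Bonferroni correction.
#'
#' The one-sided rule declares a deviation when (1) the sum of the
#' standardized deviations is in the impaired direction (negative, lower
#' scores being worse) and (2) the two-sided p-value does not exceed
#' `alpha_one_sided` (default 0.10, giving an effective one-sided level of
#' 0.05 under the null).
#'
#' @param model an `mnc_fit`.
#' @param scores patient score vector, length p, complete on the modeled
#'   tests.  If the patient completed only a subset of tests, refit the
#'   model to that subset first.
#' @param covariates patient covariates on the norm group's centered scale
#'   (see [predict_profile()]).
#' @param alpha two-sided significance level for the multivariate decision.
#' @param alpha_one_sided p-value criterion of the one-sided rule.
#' @param alpha_univariate per-test level for univariate comparisons.
#' @return an object of class `mnc_comparison`: the statistic, degrees of
#'   freedom, p-value, deviations, decisions, and the univariate table.
#' @export
normative_comparison <- function(model, scores, covariates = NULL,
                                 alpha = 0.05, alpha_one_sided = 0.10,
                                 alpha_univariate = 0.05) {
  p <- model$p
  if (length(scores) != p) {
    stop("patient has ", length(scores), " scores but the model covers ", p,
         " tests; refit the model to the tests the patient completed",
         call. = FALSE)
  }
  y_hat <- predict_profile(model, covariates)
  C <- combined_covariance(model)
  n <- model$n_participants
  df2 <- adjusted_df(model)
  tt <- t2_norm(scores, y_hat, C, n, df2)
  dev <- scores - y_hat
  std_dev <- dev / sqrt(diag(C))
  uni <- univariate_comparisons(scores, y_hat, C, n, df2,
                                alpha = alpha_univariate)
  out <- list(t2 = tt$t2, df1 = p, df2 = df2, p_two_sided = tt$p_value,
              deviations = dev, standardized_deviations = std_dev,
              sum_std_dev = sum(std_dev),
              decision_two_sided = tt$p_value <= alpha,
              decision_one_sided = one_sided_decision(
                sum(std_dev), tt$p_value, alpha_one_sided),
              alpha = alpha, alpha_one_sided = alpha_one_sided,
              univariate = uni,
              any_univariate_uncorrected = any(uni$sig_uncorrected),
              any_univariate_bonferroni = any(uni$sig_bonferroni),
              n = n)
  class(out) <- "mnc_comparison"
  out
}

#' One-sided two-criterion decision rule
#'
#' @param sum_std_dev sum of standardized deviations (x - y_hat scaled by
#'   the norm standard deviations); negative means impairment.
#' @param p_two_sided two-sided p-value of the multivariate comparison.
#' @param alpha_one_sided p-value criterion (default 0.10).
#' @return `TRUE` when the profile deviates in the impaired direction.
#' @export
one_sided_decision <- function(sum_std_dev, p_two_sided,
                               alpha_one_sided = 0.10) {
  (sum_std_dev < 0) && (p_two_sided <= alpha_one_sided)
}

#' @export
print.mnc_comparison <- function(x, digits = 3, ...) {
  cat("Multivariate normative comparison\n")
  pv <- if (x$p_two_sided < 0.001) "p < 0.001" else
    sprintf("p = %.3f", x$p_two_sided)
  cat(sprintf("  T2(%d, %d) = %.2f, %s\n", x$df1, x$df2, x$t2, pv))
  cat(sprintf("  sum of standardized deviations: %.2f\n", x$sum_std_dev))
  cat(sprintf("  one-sided decision (p <= %.2f and negative sum): %s\n",
              x$alpha_one_sided,
              if (x$decision_one_sided) "DEVIATING" else "not deviating"))
  cat(sprintf("  two-sided decision at alpha = %.2f: %s\n", x$alpha,
              if (x$decision_two_sided) "DEVIATING" else "not deviating"))
  cat("Univariate comparisons:\n")
  print(format(x$univariate, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a comparison result to JSON
#'
#' @param result an `mnc_comparison`.
#' @param path output path.
#' @export
write_comparison <- function(result, path) {
  obj <- unclass(result)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
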