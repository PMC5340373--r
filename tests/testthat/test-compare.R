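ref_model <- function(p = 10, between_variance = 5) {
  Sw <- 25 * (0.6 * diag(p) + 0.4 * matrix(1, p, p))
  structure(list(gamma = matrix(c(rep(20, p), rep(-0.125, p),
                                  rep(0.5, p), rep(1.25, p)), p),
                 sigma_within = Sw,
                 sigma_between = rep(between_variance, p),
                 loglik = NA_real_, n_participants = 1500,
                 n_obs = 15000, n_studies = 30,
                 n_fixed_effects = p * 4, p = p,
                 covariates = c("age", "gender", "education"),
                 estimate_between = TRUE, converged = TRUE),
            class = "mnc_fit")
}

test_that("the predicted profile is the covariate-matched linear
           prediction", {
  m <- ref_model(3)
  expect_equal(predict_profile(m, c(age = 0, gender = 0, education = 0)),
               rep(20, 3))
  # age 10, male (+1), education level 1: 20 - 1.25 + 0.5 + 1.25 = 20.5
  expect_equal(predict_profile(m, c(age = 10, gender = 1, education = 1)),
               rep(20.5, 3))
  # order of names must not matter; unnamed values follow model order
  expect_equal(predict_profile(m, c(education = 1, gender = 1, age = 10)),
               predict_profile(m, c(10, 1, 1)))
  expect_error(predict_profile(m, c(age = 1)), "named or match")
  expect_error(predict_profile(m), "supply values")
})

test_that("a patient exactly at the predicted profile gives T2 = 0 and
           p = 1", {
  m <- ref_model(5)
  y_hat <- predict_profile(m, c(age = 3, gender = -1, education = 0.5))
  r <- t2_norm(y_hat, y_hat, combined_covariance(m), m$n_participants,
               adjusted_df(m))
  expect_equal(r$t2, 0)
  expect_equal(r$p_value, 1)
})

test_that("T2 is referred to F(p, df2); a statistic of 4.32 at
           (9, 30902) is significant beyond 0.001", {
  # deterministic reference-tail check
  expect_lt(stats::pf(4.32, 9, 30902, lower.tail = FALSE), 0.001)
  # construct a comparison whose statistic is exactly 4.32
  p <- 9; n <- 1549; df2 <- 30902
  fac <- (n / (n + 1)) * ((n - p) / ((n - 1) * p))
  d <- c(sqrt(4.32 / fac), rep(0, p - 1))
  r <- t2_norm(rep(0, p), d, diag(p), n, df2)
  expect_equal(r$t2, 4.32, tolerance = 1e-12)
  expect_equal(r$p_value, stats::pf(4.32, p, df2, lower.tail = FALSE))
  expect_lt(r$p_value, 0.001)
})

test_that("with a single test T2 reduces to the squared normative t with
           matching two-sided p-value", {
  n <- 200; df2 <- 150; v <- 9
  x <- 14; y_hat <- 20
  r <- t2_norm(x, y_hat, matrix(v, 1, 1), n, df2)
  t_norm <- (x - y_hat) / sqrt(v * (n + 1) / n)
  expect_equal(r$t2, t_norm^2)
  expect_equal(r$p_value, 2 * stats::pt(-abs(t_norm), df2),
               tolerance = 1e-12)
  uni <- univariate_comparisons(x, y_hat, matrix(v, 1, 1), n, df2)
  expect_equal(uni$t, t_norm)
})

test_that("T2 is invariant under invertible linear recombination of the
           tests", {
  set.seed(12)
  p <- 4
  C <- random_spd(p)
  x <- rnorm(p, 20, 3); y_hat <- rep(20, p)
  A <- matrix(rnorm(p * p), p); diag(A) <- diag(A) + 3
  r1 <- t2_norm(x, y_hat, C, 500, 4000)
  r2 <- t2_norm(drop(A %*% x), drop(A %*% y_hat), A %*% C %*% t(A),
                500, 4000)
  expect_equal(r2$t2, r1$t2, tolerance = 1e-10)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-10)
})

test_that("the p-value decreases monotonically as the profile moves away
           from the prediction", {
  m <- ref_model(6)
  C <- combined_covariance(m)
  y_hat <- rep(20, 6)
  dirn <- c(1, -1, 2, 0, 1, -2)
  pv <- vapply(seq(0, 3, by = 0.5), function(s)
    t2_norm(y_hat + s * dirn, y_hat, C, m$n_participants,
            adjusted_df(m))$p_value, 0)
  expect_true(all(diff(pv) < 0))
})

test_that("univariate comparisons use one-sided t tests with Bonferroni
           at alpha / p", {
  p <- 4; n <- 1000; df2 <- 5000
  C <- diag(c(4, 9, 16, 25))
  y_hat <- rep(0, p)
  x <- c(-4, -6, 1, -13)
  uni <- univariate_comparisons(x, y_hat, C, n, df2, alpha = 0.05)
  expect_equal(uni$t, x / sqrt(diag(C) * (n + 1) / n))
  expect_equal(uni$p_one_sided, stats::pt(uni$t, df2))
  expect_equal(uni$sig_uncorrected, uni$p_one_sided <= 0.05)
  expect_equal(uni$sig_bonferroni, uni$p_one_sided <= 0.05 / p)
  # a positive (better-than-predicted) deviation is never flagged
  expect_false(uni$sig_uncorrected[3])
  # standardized deviations do not carry the (n+1)/n factor
  expect_equal(uni$std_deviation, x / sqrt(diag(C)))
})

test_that("the one-sided rule requires both a negative summed deviation
           and a small two-sided p-value", {
  expect_true(one_sided_decision(-0.76, 1e-4))
  expect_true(one_sided_decision(-5, 0.10))
  expect_false(one_sided_decision(-5, 0.101))
  expect_false(one_sided_decision(0.3, 1e-6))
  expect_false(one_sided_decision(0, 1e-6))
  expect_true(one_sided_decision(-0.01, 0.09, alpha_one_sided = 0.10))
  expect_false(one_sided_decision(-0.01, 0.09, alpha_one_sided = 0.05))
})

test_that("normative_comparison assembles the full pipeline
           consistently", {
  m <- ref_model(10)
  cv <- c(age = 10, gender = 1, education = 1)
  scores <- predict_profile(m, cv) - c(rep(8, 3), rep(0, 7))
  r <- normative_comparison(m, scores, cv)
  expect_s3_class(r, "mnc_comparison")
  expect_equal(r$df1, 10)
  expect_equal(r$df2, adjusted_df(m))
  expect_equal(r$t2,
               t2_norm(scores, predict_profile(m, cv),
                       combined_covariance(m), m$n_participants,
                       r$df2)$t2)
  expect_equal(r$sum_std_dev, sum(r$standardized_deviations))
  expect_lt(r$sum_std_dev, 0)
  expect_equal(r$decision_one_sided,
               one_sided_decision(r$sum_std_dev, r$p_two_sided, 0.10))
  expect_equal(nrow(r$univariate), 10)
  expect_error(normative_comparison(m, scores[1:4], cv), "refit")
  out <- capture.output(print(r))
  expect_true(any(grepl("T2\\(10, ", out)))
})

test_that("degenerate comparison inputs fail loudly", {
  m <- ref_model(3)
  cv <- c(age = 0, gender = 0, education = 0)
  expect_error(t2_norm(c(1, NA, 2), rep(0, 3), diag(3), 100, 50),
               "finite")
  expect_error(t2_norm(rep(1, 3), rep(0, 3), matrix(1, 3, 3), 100, 50),
               "positive definite")
  expect_error(t2_norm(rep(1, 3), rep(0, 3), diag(3), 2, 50), "exceed")
  expect_error(univariate_comparisons(rep(1, 3), rep(0, 3),
                                      diag(c(1, 0, 1)), 100, 50),
               "non-positive")
})
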