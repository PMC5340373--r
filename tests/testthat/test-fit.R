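fake_fit <- function(p, K, n_obs, n_participants = 1500,
                     within_variance = 25, within_correlation = 0.4,
                     between_variance = 5,
                     covariates = c("age", "gender", "education")) {
  Sw <- within_variance * ((1 - within_correlation) * diag(p) +
                             within_correlation * matrix(1, p, p))
  structure(list(gamma = matrix(c(rep(20, p), rep(-0.125, p),
                                  rep(0.5, p), rep(1.25, p)), p),
                 sigma_within = Sw,
                 sigma_between = rep(between_variance, p),
                 loglik = NA_real_, n_participants = n_participants,
                 n_obs = n_obs, n_studies = K,
                 n_fixed_effects = p * (1L + length(covariates)),
                 p = p, covariates = covariates,
                 estimate_between = TRUE, converged = TRUE),
            class = "mnc_fit")
}

test_that("a single complete study with no covariates recovers the sample
           mean and the ML (1/n) covariance", {
  set.seed(42)
  p <- 3; n <- 60
  Y <- matrix(rnorm(p * n, 20, 5), n, p)
  df <- data.frame(study = 1, ID = rep(1:n, each = p),
                   age = 0, gender = 1, education = 0,
                   test = rep(1:p, n), score = as.numeric(t(Y)))
  fit <- fit_fiml(norm_dataset(df), covariates = character(0),
                  estimate_between = FALSE,
                  control = fiml_control(reltol = 1e-13))
  expect_equal(unname(fit$gamma[, 1]), colMeans(Y), tolerance = 1e-5)
  ml_cov <- crossprod(sweep(Y, 2, colMeans(Y))) / n
  expect_equal(unname(fit$sigma_within), ml_cov, tolerance = 1e-4)
  expect_equal(unname(fit$sigma_between), rep(0, p))
})

test_that("between-study variance estimates shrink toward zero when the
           generating between-study variance is zero", {
  cfg <- tiny_config(between_variance = 0)
  dat <- simulate_norm_data(cfg, seed = 5)
  fit <- fit_fiml(dat)
  expect_true(fit$converged)
  expect_lt(max(fit$sigma_between), 1)
})

test_that("the fit is equivariant under affine transformation of the
           scores", {
  cfg <- tiny_config(between_variance = 3)
  dat <- simulate_norm_data(cfg, seed = 17)
  fit1 <- fit_fiml(dat)
  a <- 2; cshift <- 5
  df <- as.data.frame(dat)
  df$score <- a * df$score + cshift
  fit2 <- fit_fiml(norm_dataset(df))
  g_expect <- a * fit1$gamma
  g_expect[, 1] <- g_expect[, 1] + cshift
  expect_equal(fit2$gamma, g_expect, tolerance = 1e-3)
  expect_equal(fit2$sigma_within, a^2 * fit1$sigma_within, tolerance = 1e-2)
  expect_equal(fit2$sigma_between, a^2 * fit1$sigma_between,
               tolerance = 0.05)
  expect_equal(fit2$loglik, fit1$loglik - fit1$n_obs * log(a),
               tolerance = 1e-4)
})

test_that("adjusted degrees of freedom follow N_obs - (K + q + 1)", {
  # reference scale: 15000 scores, 30 studies, 40 fixed effects
  expect_equal(adjusted_df(fake_fit(10, 30, 15000)), 14929L)
  # 40% missing at the same scale: 9000 scores
  expect_equal(adjusted_df(fake_fit(10, 30, 9000)), 8929L)
  # small case: 3 tests, 2 studies, 112 scores, q = 12
  expect_equal(adjusted_df(fake_fit(3, 2, 112)), 97L)
  # undefined when the adjusted df does not exceed p
  expect_error(adjusted_df(fake_fit(10, 30, 80)), "undefined")
})

test_that("the combined covariance adds the between-study variances on the
           diagonal and reproduces the reference ICCs", {
  f <- fake_fit(4, 30, 6000)
  C <- combined_covariance(f)
  expect_equal(diag(C), rep(30, 4), ignore_attr = TRUE)
  expect_equal(C[1, 2], 10)  # off-diagonals carry no between-study part
  expect_equal(5 / 30, 0.1667, tolerance = 1e-3)  # reference ICC
  f2 <- fake_fit(4, 30, 6000, between_variance = 17)
  expect_equal(17 / diag(combined_covariance(f2))[1], 0.405,
               tolerance = 1e-3)
})

test_that("a model survives a JSON round-trip with identical comparisons", {
  cfg <- tiny_config()
  dat <- simulate_norm_data(cfg, seed = 3)
  fit <- fit_fiml(dat)
  f <- tempfile(fileext = ".json")
  write_model(fit, f)
  back <- read_model(f)
  expect_equal(back$gamma, fit$gamma)
  expect_equal(back$sigma_within, fit$sigma_within)
  expect_equal(back$sigma_between, fit$sigma_between)
  expect_equal(back$n_obs, fit$n_obs)
  pat <- simulate_patient(cfg, seed = 9)
  r1 <- normative_comparison(fit, pat$scores, pat$covariates)
  r2 <- normative_comparison(back, pat$scores, pat$covariates)
  expect_equal(r2$t2, r1$t2)
  expect_equal(r2$p_two_sided, r1$p_two_sided)
})

test_that("fitting refuses data in which a test pair never co-occurs,
           naming the pair", {
  df <- rbind(
    data.frame(study = 1, ID = rep(1:6, each = 2), age = rnorm(12),
               gender = rep(c(-1, 1), 6), education = rnorm(12),
               test = rep(1:2, 6), score = rnorm(12, 20, 5)),
    data.frame(study = 2, ID = rep(1:6, each = 2), age = rnorm(12),
               gender = rep(c(-1, 1), 6), education = rnorm(12),
               test = rep(c(1, 3), 6), score = rnorm(12, 20, 5)))
  expect_error(fit_fiml(norm_dataset(df)), "2-3")
})

test_that("heterogeneous test sets within a study use the dense path and
           agree with the blocked path on equivalent data", {
  set.seed(31)
  # complete tiny dataset fit via both code paths must agree
  df <- NULL
  for (s in 1:4) df <- rbind(df, random_study_df(3, 8, study = s))
  dat <- norm_dataset(df)
  fit_b <- fit_fiml(dat)
  # drop one score so one participant differs -> dense dispatch
  df2 <- df[-1, ]
  expect_false(attr(mnormcomp:::as_study_blocks(df2), "homogeneous"))
  fit_d <- fit_fiml(norm_dataset(df2), control = fiml_control(maxit = 2000))
  # with one of 96 scores removed the estimates barely move
  expect_lt(max(abs(fit_d$gamma - fit_b$gamma)), 0.5)
  expect_lt(max(abs(diag(fit_d$sigma_within) - diag(fit_b$sigma_within))),
            0.3 * max(diag(fit_b$sigma_within)))
})
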