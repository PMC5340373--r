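#' Simulation configuration
#'
#' Bundles the generative parameters of a synthetic aggregated normative
#' database and the settings of a Monte Carlo condition.  The defaults are
#' the reference condition used throughout the package's simulation
#' studies: 10 tests, 30 studies of 50 participants, test intercepts 20,
#' covariate effects -0.125 (age, per year), 0.5 (gender contrast) and
#' 1.25 (education level), within-study residual variance 25 with
#' equicorrelation 0.4, between-study intercept variance 5 with zero
#' between-study correlation (intraclass correlation 5/30 ~ 0.167).
#'
#' @param p number of tests.
#' @param K number of studies.
#' @param n_per_study participants per study (the mean when `n_sd > 0`).
#' @param n_sd standard deviation of study sizes; 0 gives balanced
#'   studies, otherwise sizes are drawn from Normal(`n_per_study`, `n_sd`),
#'   rounded and floored at 5.
#' @param intercept,age_effect,gender_effect,education_effect fixed
#'   effects, identical for all tests.
#' @param within_variance,within_correlation within-study residual
#'   variance and equicorrelation.
#' @param between_variance,between_correlation between-study intercept
#'   variance per test and correlation across tests (only 0 is supported,
#'   matching the diagonal between-study covariance of the model).
#' @param missing_fraction fraction of test scores missing by design; each
#'   study administers exactly `p * (1 - missing_fraction)` tests (must be
#'   a whole number) under a pair-covering design.
#' @param n_deviations number of tests on which the simulated patient
#'   truly deviates (0 = null patient).
#' @param deviation_sd size of the true deviation in standard deviations
#'   of the total (within + between) variance; deviations are subtracted,
#'   i.e. impairment.
#' @param replications Monte Carlo replicates per condition.
#' @param alpha_one_sided p-value criterion of the one-sided multivariate
#'   rule.
#' @param alpha_univariate per-test level of univariate comparisons.
#' @param estimate_between whether the fitted model estimates
#'   between-study variance (`FALSE` = neglected, fixed at 0).
#' @param patient_covariates `"random"` draws the patient's covariates
#'   from the norm population, `"average"` fixes them at the centered
#'   means.
#' @param age_sd,education_sd population standard deviations of the
#'   (centered) age and education covariates; gender is -1/+1 with equal
#'   probability.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(p = 10L, K = 30L, n_per_study = 50L, n_sd = 0,
                       intercept = 20, age_effect = -0.125,
                       gender_effect = 0.5, education_effect = 1.25,
                       within_variance = 25, within_correlation = 0.4,
                       between_variance = 5, between_correlation = 0,
                       missing_fraction = 0, n_deviations = 0L,
                       deviation_sd = 2, replications = 1000L,
                       alpha_one_sided = 0.10, alpha_univariate = 0.05,
                       estimate_between = TRUE,
                       patient_covariates = c("random", "average"),
                       age_sd = 15, education_sd = 1.5) {
  cfg <- list(p = as.integer(p), K = as.integer(K),
              n_per_study = n_per_study, n_sd = n_sd,
              intercept = intercept, age_effect = age_effect,
              gender_effect = gender_effect,
              education_effect = education_effect,
              within_variance = within_variance,
              within_correlation = within_correlation,
              between_variance = between_variance,
              between_correlation = between_correlation,
              missing_fraction = missing_fraction,
              n_deviations = as.integer(n_deviations),
              deviation_sd = deviation_sd,
              replications = as.integer(replications),
              alpha_one_sided = alpha_one_sided,
              alpha_univariate = alpha_univariate,
              estimate_between = isTRUE(estimate_between),
              patient_covariates = match.arg(patient_covariates),
              age_sd = age_sd, education_sd = education_sd)
  stopifnot(cfg$p >= 1L, cfg$K >= 1L,
            cfg$within_variance >= 0, cfg$between_variance >= 0,
            cfg$within_correlation > -1, cfg$within_correlation < 1,
            cfg$missing_fraction >= 0, cfg$missing_fraction < 1,
            cfg$n_deviations >= 0L, cfg$n_deviations <= cfg$p,
            cfg$replications >= 1L)
  if (cfg$between_correlation != 0) {
    stop("only between_correlation = 0 is supported")
  }
  b <- cfg$p * (1 - cfg$missing_fraction)
  if (abs(b - round(b)) > 1e-8) {
    stop("p * (1 - missing_fraction) must be a whole number of tests")
  }
  class(cfg) <- "sim_config"
  cfg
}

true_gamma <- function(cfg) {
  cbind(rep(cfg$intercept, cfg$p), rep(cfg$age_effect, cfg$p),
        rep(cfg$gender_effect, cfg$p), rep(cfg$education_effect, cfg$p))
}

true_sigma_within <- function(cfg) {
  cfg$within_variance *
    ((1 - cfg$within_correlation) * diag(cfg$p) +
       cfg$within_correlation * matrix(1, cfg$p, cfg$p))
}

#' Planned-missingness design with full pair coverage
#'
#' Assigns each of `K` studies a block of `b = p * (1 - fraction)` tests
#' such that every pair of tests co-occurs in at least one study (required
#' for the unstructured within-study covariance to be estimable), every
#' test is administered somewhere, and the overall fraction of missing
#' scores equals `fraction` exactly.  The assignment is a deterministic
#' greedy pair-covering: each study in turn takes the block covering the
#' most still-uncovered pairs (ties broken toward balanced test usage);
#' once all pairs are covered, remaining studies take the least-used
#' tests.
#'
#' @param p number of tests.
#' @param K number of studies.
#' @param fraction missing fraction in `[0, 1)`.
#' @return a K x p logical matrix; `TRUE` = test administered.
#' @export
make_missing_design <- function(p, K, fraction) {
  if (fraction == 0) return(matrix(TRUE, K, p))
  b <- round(p * (1 - fraction))
  if (b < 2L) stop("each study must administer at least 2 tests")
  need <- choose(p, 2L)
  if (K * choose(b, 2L) < need) {
    stop("infeasible design: ", K, " studies of ", b, " tests cover at ",
         "most ", K * choose(b, 2L), " pairs but ", need, " are required")
  }
  subsets <- utils::combn(p, b)
  pair_ix <- lapply(seq_len(ncol(subsets)), function(j) {
    pr <- utils::combn(subsets[, j], 2L)
    (pr[2L, ] - 1L) * p + pr[1L, ]  # linear indices, i < j
  })
  covered <- rep(FALSE, p * p)
  usage <- integer(p)
  design <- matrix(FALSE, K, p)
  all_done <- FALSE
  for (k in seq_len(K)) {
    if (!all_done) {
      gains <- vapply(pair_ix, function(ix) sum(!covered[ix]), 0L)
      if (max(gains) == 0L) all_done <- TRUE
    }
    if (all_done) {
      S <- order(usage, seq_len(p))[seq_len(b)]
    } else {
      cand <- which(gains == max(gains))
      load <- vapply(cand, function(j) sum(usage[subsets[, j]]), 0L)
      j <- cand[which.min(load)]
      S <- subsets[, j]
      covered[pair_ix[[j]]] <- TRUE
    }
    design[k, S] <- TRUE
    usage[S] <- usage[S] + 1L
  }
  pcov <- crossprod(design)
  if (any(pcov[upper.tri(pcov)] == 0L)) {
    stop("internal error: pair coverage not achieved")  # nocov
  }
  design
}

# Draw the study blocks of one synthetic database.  The caller seeds the
# RNG; the design is deterministic given (p, K, fraction).
r_norm_blocks <- function(cfg, design) {
  G <- true_gamma(cfg)
  cholSw <- chol(true_sigma_within(cfg))
  sdb <- sqrt(cfg$between_variance)
  blocks <- vector("list", cfg$K)
  for (k in seq_len(cfg$K)) {
    n <- if (cfg$n_sd > 0) {
      max(5L, as.integer(round(stats::rnorm(1L, cfg$n_per_study, cfg$n_sd))))
    } else as.integer(cfg$n_per_study)
    S <- which(design[k, ])
    X <- cbind(1,
               stats::rnorm(n, 0, cfg$age_sd),
               sample(c(-1, 1), n, replace = TRUE),
               stats::rnorm(n, 0, cfg$education_sd))
    nu <- stats::rnorm(cfg$p, 0, sdb)
    eps <- matrix(stats::rnorm(n * cfg$p), n, cfg$p) %*% cholSw
    Y <- X %*% t(G[S, , drop = FALSE]) +
      matrix(nu[S], n, length(S), byrow = TRUE) +
      eps[, S, drop = FALSE]
    blocks[[k]] <- list(study = k, S = S, Y = Y, X = X)
  }
  blocks
}

blocks_to_long <- function(blocks) {
  pieces <- lapply(blocks, function(b) {
    n <- nrow(b$Y)
    bt <- length(b$S)
    data.frame(study = b$study,
               ID = rep(seq_len(n), each = bt),
               age = rep(b$X[, 2L], each = bt),
               gender = rep(b$X[, 3L], each = bt),
               education = rep(b$X[, 4L], each = bt),
               test = rep(b$S, times = n),
               score = as.numeric(t(b$Y)))
  })
  do.call(rbind, pieces)
}

#' Simulate an aggregated normative database
#'
#' Generates a long-format normative dataset from the three-level model:
#' study intercept deviations per test (independent across tests),
#' equicorrelated participant residual vectors, linear covariate effects,
#' and a planned-missingness design in which every study administers the
#' same number of tests and all pairs co-occur.  Covariates are generated
#' on the centered scale (age and education mean 0, gender -1/+1).
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return a `norm_dataset`.
#' @export
simulate_norm_data <- function(config, seed = 1L) {
  set.seed(seed)
  design <- make_missing_design(config$p, config$K, config$missing_fraction)
  blocks <- r_norm_blocks(config, design)
  out <- norm_dataset(blocks_to_long(blocks))
  attr(out, "centering") <- list(age_mean = 0, education_mean = 0,
                                 gender_coding = "contrast (-1, +1)")
  out
}

#' Simulate a patient profile
#'
#' Draws a patient from the same population as the norm group: fresh
#' covariates and a residual vector with the combined (within + between)
#' covariance, since a new patient belongs to no norm study.  When
#' `n_deviations > 0`, `deviation_sd` standard deviations of the total
#' variance are subtracted from the first `n_deviations` test scores
#' (deviations are impairments, hence negative).
#'
#' @param config a [sim_config()].
#' @param n_deviations overrides `config$n_deviations` when given.
#' @param seed integer RNG seed (omit to continue the current RNG stream).
#' @return a list with `covariates` (named, centered scale), `scores`
#'   (length p) and `n_deviations`.
#' @export
simulate_patient <- function(config, n_deviations = config$n_deviations,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cv <- if (config$patient_covariates == "average") {
    c(age = 0, gender = 0, education = 0)
  } else {
    c(age = stats::rnorm(1L, 0, config$age_sd),
      gender = sample(c(-1, 1), 1L),
      education = stats::rnorm(1L, 0, config$education_sd))
  }
  G <- true_gamma(config)
  e <- drop(stats::rnorm(config$p) %*% chol(true_sigma_within(config))) +
    stats::rnorm(config$p, 0, sqrt(config$between_variance))
  x <- drop(G %*% c(1, cv)) + e
  if (n_deviations > 0L) {
    shift <- config$deviation_sd *
      sqrt(config$within_variance + config$between_variance)
    x[seq_len(n_deviations)] <- x[seq_len(n_deviations)] - shift
  }
  list(covariates = cv, scores = x, n_deviations = as.integer(n_deviations))
}

# Deterministic per-replicate seed derived from the master seed.
replicate_seed <- function(master, r) {
  (as.numeric(master) %% 2147483587 + 104729 * as.numeric(r)) %% 2147483587
}

# Moment-based starting values computed from study blocks.
start_from_blocks <- function(blocks, p, c1) {
  XtX <- array(0, c(c1, c1, p))
  Xty <- matrix(0, c1, p)
  for (b in blocks) {
    cx <- crossprod(b$X)
    cy <- crossprod(b$X, b$Y)
    for (j in seq_along(b$S)) {
      m <- b$S[j]
      XtX[, , m] <- XtX[, , m] + cx
      Xty[, m] <- Xty[, m] + cy[, j]
    }
  }
  gamma0 <- matrix(0, p, c1)
  for (m in seq_len(p)) {
    gamma0[m, ] <- tryCatch(solve(XtX[, , m], Xty[, m]),
                            error = function(e) rep(0, c1))
  }
  Ssum <- matrix(0, p, p)
  cnt <- matrix(0, p, p)
  means_by_test <- vector("list", p)
  for (b in blocks) {
    R <- b$Y - b$X %*% t(gamma0[b$S, , drop = FALSE])
    rbar <- colMeans(R)
    Rc <- sweep(R, 2L, rbar)
    Ssum[b$S, b$S] <- Ssum[b$S, b$S] + crossprod(Rc)
    cnt[b$S, b$S] <- cnt[b$S, b$S] + nrow(R) - 1
    for (j in seq_along(b$S)) {
      m <- b$S[j]
      means_by_test[[m]] <- c(means_by_test[[m]], rbar[j])
    }
  }
  Sw0 <- Ssum / pmax(cnt, 1)
  sb0 <- vapply(means_by_test, function(v)
    if (length(v) > 1L) max(stats::var(v), 1e-4) else 1e-2, 0)
  ev <- eigen(Sw0, symmetric = TRUE)
  fl <- max(ev$values) * 1e-4
  if (min(ev$values) < fl) {
    Sw0 <- ev$vectors %*% diag(pmax(ev$values, fl), p) %*% t(ev$vectors)
  }
  list(gamma = gamma0, sigma_within = Sw0, sigma_between = sb0)
}

# One full Monte Carlo replicate: simulate a database, fit it, simulate a
# patient, run the comparison.  Returns a one-row data.frame of flags.
one_replicate <- function(cfg, design, control, rseed) {
  set.seed(rseed)
  blocks <- r_norm_blocks(cfg, design)
  c1 <- 4L
  st <- start_from_blocks(blocks, cfg$p, c1)
  stats_list <- lapply(blocks, block_stats)
  fit <- optimize_blocked(stats_list, cfg$p, c1, cfg$estimate_between,
                          control, st)
  pat <- simulate_patient(cfg)
  if (!fit$converged) {
    return(data.frame(converged = FALSE, multivariate = NA,
                      uni_any = NA, uni_bonf = NA,
                      p_two_sided = NA_real_, sum_std_dev = NA_real_))
  }
  C <- fit$sigma_within + diag(fit$sigma_between, cfg$p)
  n <- sum(vapply(blocks, function(b) nrow(b$Y), 0))
  n_obs <- sum(vapply(blocks, function(b) length(b$Y), 0))
  df2 <- n_obs - (cfg$K + cfg$p * c1 + 1)
  y_hat <- drop(fit$gamma %*% c(1, pat$covariates))
  tt <- t2_norm(pat$scores, y_hat, C, n, df2)
  std_dev <- (pat$scores - y_hat) / sqrt(diag(C))
  uni <- univariate_comparisons(pat$scores, y_hat, C, n, df2,
                                alpha = cfg$alpha_univariate)
  data.frame(
    converged = TRUE,
    multivariate = one_sided_decision(sum(std_dev), tt$p_value,
                                      cfg$alpha_one_sided),
    uni_any = any(uni$sig_uncorrected),
    uni_bonf = any(uni$sig_bonferroni),
    p_two_sided = tt$p_value,
    sum_std_dev = sum(std_dev))
}

# Shared optimizer core over blocked sufficient statistics (also used by
# fit_fiml); returns gamma, covariances, loglik, convergence.
optimize_blocked <- function(stats_list, p, c1, estimate_between, control,
                             start) {
  theta0 <- pack_theta(start$sigma_within, start$sigma_between,
                       estimate_between)
  cache <- new.env(parent = emptyenv())
  evalpt <- function(theta) {
    if (!identical(theta, cache$theta)) {
      r <- mnc_profiled_nll(theta, stats_list, p, c1, estimate_between, TRUE)
      if (!is.finite(r$nll)) {
        r <- list(nll = 1e12, grad = rep(0, length(theta)),
                  gamma = matrix(0, p, c1))
      }
      cache$theta <- theta
      cache$res <- r
    }
    cache$res
  }
  factr <- control$reltol / .Machine$double.eps
  best <- NULL
  n_restarts <- 0L
  theta_try <- theta0
  repeat {
    opt <- stats::optim(theta_try, fn = function(t) evalpt(t)$nll,
                        gr = function(t) evalpt(t)$grad,
                        method = "L-BFGS-B",
                        lower = -control$bound, upper = control$bound,
                        control = list(maxit = control$maxit, factr = factr))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0L || n_restarts >= control$restarts) break
    n_restarts <- n_restarts + 1L
    theta_try <- best$par + stats::rnorm(length(theta0), 0, control$jitter)
  }
  pars <- unpack_theta(best$par, p, estimate_between)
  fin <- mnc_profiled_nll(best$par, stats_list, p, c1, estimate_between,
                          FALSE)
  list(gamma = fin$gamma, sigma_within = pars$sigma_within,
       sigma_between = pars$sigma_between, loglik = -best$value,
       converged = best$convergence == 0L, n_restarts = n_restarts)
}

#' Run one Monte Carlo condition
#'
#' For each replicate: simulate a normative database, fit the three-level
#' model by FIML, simulate one patient from the same population, and apply
#' the one-sided multivariate rule and the one-sided univariate rules
#' (uncorrected and Bonferroni).  The reported rate is a false-positive
#' rate when `config$n_deviations == 0` and a sensitivity otherwise.
#' Replicate seeds are derived deterministically from `seed`, so results
#' are reproducible and independent of `cores`.
#'
#' @param config a [sim_config()].
#' @param seed master RNG seed.
#' @param replications overrides `config$replications` when given.
#' @param control optimizer control ([fiml_control()]).
#' @param cores number of worker processes (forked; results identical to
#'   sequential execution).
#' @return an object of class `mnc_simresult`: per-method rates with
#'   Clopper-Pearson 95% confidence intervals, the per-replicate flag
#'   table, and convergence-failure counts.
#' @export
run_condition <- function(config, seed = 1L,
                          replications = config$replications,
                          control = fiml_control(), cores = 1L) {
  design <- make_missing_design(config$p, config$K,
                                config$missing_fraction)
  reps <- seq_len(replications)
  worker <- function(r) one_replicate(config, design, control,
                                      replicate_seed(seed, r))
  res <- if (cores > 1L) {
    parallel::mclapply(reps, worker, mc.cores = cores)
  } else {
    lapply(reps, worker)
  }
  tab <- do.call(rbind, res)
  ok <- tab$converged
  n_fail <- sum(!ok)
  rate_ci <- function(x) {
    x <- x[!is.na(x)]
    k <- sum(x)
    m <- length(x)
    lo <- if (k == 0L) 0 else stats::qbeta(0.025, k, m - k + 1)
    hi <- if (k == m) 1 else stats::qbeta(0.975, k + 1, m - k)
    c(rate = k / m, lower = lo, upper = hi, n = m)
  }
  rates <- rbind(multivariate = rate_ci(tab$multivariate),
                 univariate_uncorrected = rate_ci(tab$uni_any),
                 univariate_bonferroni = rate_ci(tab$uni_bonf))
  out <- list(config = config, seed = seed, replications = replications,
              n_converged = sum(ok), n_failed = n_fail,
              unreliable = n_fail > 0.1 * replications,
              rates = as.data.frame(rates),
              replicates = tab)
  class(out) <- "mnc_simresult"
  out
}

#' @export
print.mnc_simresult <- function(x, ...) {
  kind <- if (x$config$n_deviations == 0L) "false-positive rate" else
    sprintf("sensitivity (%d true deviations)", x$config$n_deviations)
  cat(sprintf("Monte Carlo condition: %s over %d replicates (%d failed)\n",
              kind, x$replications, x$n_failed))
  cat(sprintf("  p = %d tests, K = %d studies, %.0f%% missing, between ",
              x$config$p, x$config$K, 100 * x$config$missing_fraction))
  cat(sprintf("variance %s\n",
              if (x$config$estimate_between) "estimated" else "neglected"))
  print(round(x$rates, 4))
  if (x$unreliable) cat("WARNING: >10% non-convergence; condition flagged",
                        "unreliable\n")
  invisible(x)
}
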