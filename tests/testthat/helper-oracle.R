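# Independent brute-force oracle for the study log-likelihood: assemble
# the full joint covariance of one study's stacked score vector with
# explicit elementwise loops and evaluate the multivariate normal
# log-density directly.  Deliberately shares no code with the package's
# blocked or dense evaluators.
oracle_study_loglik <- function(gamma, W, B, study_df,
                                covariates = c("age", "gender",
                                               "education")) {
  ids <- unique(study_df$ID)
  r <- c()
  S <- c()
  part <- c()
  for (i in seq_along(ids)) {
    d <- study_df[study_df$ID == ids[i], , drop = FALSE]
    d <- d[order(d$test), , drop = FALSE]
    cvec <- c(1, as.numeric(d[1L, covariates]))
    r <- c(r, d$score - drop(gamma[d$test, , drop = FALSE] %*% cvec))
    S <- c(S, d$test)
    part <- c(part, rep(i, nrow(d)))
  }
  n <- length(r)
  V <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      v <- 0
      if (part[a] == part[b]) v <- v + W[S[a], S[b]]
      if (S[a] == S[b]) v <- v + B[S[a]]
      V[a, b] <- v
    }
  }
  -0.5 * (as.numeric(determinant(V)$modulus) +
            drop(t(r) %*% solve(V) %*% r) + n * log(2 * pi))
}

# Random positive-definite covariance of dimension p.
random_spd <- function(p) {
  A <- matrix(stats::rnorm(p * p), p)
  crossprod(A) + diag(p)
}

# Small random long-format study with optional participant-level
# missingness (each participant drops a random test with prob drop_prob).
random_study_df <- function(p, n, drop_prob = 0, study = 1L) {
  rows <- NULL
  for (i in seq_len(n)) {
    tests <- seq_len(p)
    if (drop_prob > 0 && p > 1L) {
      keep <- stats::runif(p) >= drop_prob
      if (!any(keep)) keep[sample(p, 1L)] <- TRUE
      tests <- tests[keep]
    }
    rows <- rbind(rows, data.frame(
      study = study, ID = i,
      age = stats::rnorm(1, 0, 10),
      gender = sample(c(-1, 1), 1L),
      education = stats::rnorm(1, 0, 1.5),
      test = tests, score = stats::rnorm(length(tests), 20, 5)))
  }
  rows
}

# Tiny reference condition used by several tests: cheap to fit but with
# the full three-level structure.
tiny_config <- function(...) {
  args <- list(p = 4L, K = 8L, n_per_study = 20L, replications = 10L)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}
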