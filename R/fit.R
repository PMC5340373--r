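#' @useDynLib mnormcomp, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- internal: study blocks and sufficient statistics ------------------

# Split a long dataset into per-study blocks.  When all participants in a
# study completed the same test set ("blocked" layout, the rule in
# planned-missingness designs), a study reduces to a score matrix Y (n x b),
# a covariate design X (n x c1) and the observed test set S; otherwise the
# participant-level rows are kept for dense likelihood assembly.
as_study_blocks <- function(x, covariates = c("age", "gender", "education")) {
  df <- as.data.frame(x)
  p <- max(df$test)
  out <- list()
  homogeneous <- TRUE
  for (s in unique(df$study)) {
    d <- df[df$study == s, , drop = FALSE]
    ids <- unique(d$ID)
    sets <- lapply(ids, function(i) sort(d$test[d$ID == i]))
    same <- length(unique(vapply(sets, paste, "", collapse = ","))) == 1L
    if (same) {
      S <- sets[[1L]]
      n <- length(ids)
      Y <- matrix(NA_real_, n, length(S))
      X <- matrix(NA_real_, n, 1L + length(covariates))
      for (j in seq_along(ids)) {
        di <- d[d$ID == ids[j], , drop = FALSE]
        di <- di[order(di$test), , drop = FALSE]
        Y[j, ] <- di$score
        X[j, ] <- c(1, as.numeric(di[1L, covariates]))
      }
      out[[length(out) + 1L]] <- list(study = s, S = S, Y = Y, X = X)
    } else {
      homogeneous <- FALSE
      parts <- lapply(ids, function(i) {
        di <- d[d$ID == i, , drop = FALSE]
        di <- di[order(di$test), , drop = FALSE]
        list(S = di$test, y = di$score,
             c = c(1, as.numeric(di[1L, covariates])))
      })
      out[[length(out) + 1L]] <- list(study = s, participants = parts)
    }
  }
  structure(out, p = p, homogeneous = homogeneous,
            covariates = covariates)
}

# Centered sufficient statistics of one blocked study, as consumed by the
# compiled likelihood.
block_stats <- function(b) {
  n <- nrow(b$Y)
  ybar <- colMeans(b$Y)
  cbar <- colMeans(b$X)
  Yc <- sweep(b$Y, 2L, ybar)
  Cc <- sweep(b$X, 2L, cbar)
  list(S = as.integer(b$S - 1L), n = as.numeric(n),
       ybar = ybar, cbar = cbar,
       YtYc = crossprod(Yc), YtCc = crossprod(Yc, Cc), CtCc = crossprod(Cc))
}

# ---- study log-likelihood (reference implementation) -------------------

#' Log-likelihood contribution of a single study
#'
#' Evaluates the multivariate-normal log-density of one study's stacked
#' score vector at given parameter values.  Within a study, two scores of
#' the same participant covary through the within-study covariance, and any
#' two scores on the same test (same or different participants) share the
#' study's intercept deviation, contributing the between-study variance of
#' that test.  When every participant in the study completed the same test
#' set, the density factorizes over the participant mean and the orthogonal
#' within-study contrasts (`method = "blocked"`); `method = "dense"`
#' assembles the full joint covariance and handles participant-level
#' missingness.
#'
#' @param gamma p x c1 matrix of fixed effects (intercept column first).
#' @param sigma_within p x p within-study covariance matrix.
#' @param sigma_between length-p vector of between-study variances.
#' @param study a data.frame with one study's long-format rows.
#' @param covariates covariate column names, in the order of the non-
#'   intercept columns of `gamma`.
#' @param method `"auto"` (blocked when possible), `"blocked"`, or
#'   `"dense"`.
#' @return the study's log-likelihood (a scalar).
#' @export
study_loglik <- function(gamma, sigma_within, sigma_between, study,
                         covariates = c("age", "gender", "education"),
                         method = c("auto", "blocked", "dense")) {
  method <- match.arg(method)
  blocks <- as_study_blocks(study, covariates)
  if (length(blocks) != 1L) stop("'study' must contain a single study")
  b <- blocks[[1L]]
  blocked_ok <- is.null(b$participants)
  if (method == "blocked" && !blocked_ok) {
    stop("participants differ in observed tests; use method = \"dense\"")
  }
  use_blocked <- blocked_ok && method != "dense"
  if (use_blocked) {
    S <- b$S
    n <- nrow(b$Y)
    W <- sigma_within[S, S, drop = FALSE]
    M <- W + n * diag(sigma_between[S], nrow = length(S))
    R <- b$Y - b$X %*% t(gamma[S, , drop = FALSE])
    rbar <- colMeans(R)
    A <- crossprod(sweep(R, 2L, rbar))
    ok <- tryCatch({cw <- chol(W); cm <- chol(M); TRUE},
                   error = function(e) FALSE)
    if (!ok) return(-Inf)
    ldW <- 2 * sum(log(diag(cw)))
    ldM <- 2 * sum(log(diag(cm)))
    Winv <- chol2inv(cw)
    Minv <- chol2inv(cm)
    -0.5 * ((n - 1) * ldW + ldM + sum(Winv * A) +
              n * drop(crossprod(rbar, Minv %*% rbar)) +
              n * length(S) * log(2 * pi))
  } else {
    parts <- b$participants
    if (is.null(parts)) {  # blocked layout, dense evaluation requested
      parts <- lapply(seq_len(nrow(b$Y)), function(i)
        list(S = b$S, y = b$Y[i, ], c = b$X[i, ]))
    }
    sizes <- vapply(parts, function(q) length(q$S), 0L)
    off <- cumsum(c(0L, sizes))
    tot <- sum(sizes)
    V <- matrix(0, tot, tot)
    r <- numeric(tot)
    for (i in seq_along(parts)) {
      qi <- parts[[i]]
      ii <- off[i] + seq_along(qi$S)
      r[ii] <- qi$y - drop(gamma[qi$S, , drop = FALSE] %*% qi$c)
      V[ii, ii] <- sigma_within[qi$S, qi$S, drop = FALSE]
      for (j in seq_along(parts)) {
        qj <- parts[[j]]
        jj <- off[j] + seq_along(qj$S)
        shared <- outer(qi$S, qj$S, "==")
        V[ii, jj] <- V[ii, jj] +
          shared * sigma_between[qi$S][row(shared)]
      }
    }
    cv <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cv)) return(-Inf)
    z <- backsolve(cv, r, transpose = TRUE)
    -0.5 * (2 * sum(log(diag(cv))) + sum(z^2) + tot * log(2 * pi))
  }
}

# ---- starting values ---------------------------------------------------

start_values <- function(x, covariates, p, estimate_between) {
  df <- as.data.frame(x)
  c1 <- 1L + length(covariates)
  gamma0 <- matrix(0, p, c1)
  resid <- numeric(nrow(df))
  for (m in seq_len(p)) {
    rows <- df$test == m
    X <- cbind(1, as.matrix(df[rows, covariates, drop = FALSE]))
    fit <- stats::lm.fit(X, df$score[rows])
    gamma0[m, ] <- fit$coefficients
    resid[rows] <- fit$residuals
  }
  gamma0[!is.finite(gamma0)] <- 0
  pid <- paste(df$study, df$ID, sep = "\r")
  wide <- matrix(NA_real_, length(unique(pid)), p)
  rownames(wide) <- unique(pid)
  wide[cbind(match(pid, rownames(wide)), df$test)] <- resid
  Sw0 <- stats::cov(wide, use = "pairwise.complete.obs")
  Sw0[!is.finite(Sw0)] <- 0
  # between-study variance of per-study mean residuals, per test
  sb0 <- rep(1e-2, p)
  if (estimate_between) {
    for (m in seq_len(p)) {
      rows <- df$test == m
      mns <- tapply(resid[rows], df$study[rows], mean)
      if (length(mns) > 1L) sb0[m] <- max(stats::var(mns), 1e-4)
    }
    diag(Sw0) <- pmax(diag(Sw0) - sb0, 0.1 * diag(Sw0), 1e-3)
  }
  # repair to positive definite
  ev <- eigen(Sw0, symmetric = TRUE)
  floor_ev <- max(ev$values) * 1e-4
  if (min(ev$values) < floor_ev) {
    Sw0 <- ev$vectors %*% diag(pmax(ev$values, floor_ev), p) %*% t(ev$vectors)
  }
  list(gamma = gamma0, sigma_within = Sw0, sigma_between = sb0)
}

pack_theta <- function(Sw, sb, estimate_between) {
  L <- t(chol(Sw))
  p <- nrow(L)
  th <- numeric(0)
  for (j in seq_len(p)) {
    v <- L[j:p, j]
    v[1L] <- log(v[1L])
    th <- c(th, v)
  }
  if (estimate_between) th <- c(th, log(pmax(sb, 1e-8)))
  th
}

unpack_theta <- function(theta, p, estimate_between) {
  L <- matrix(0, p, p)
  k <- 1L
  for (j in seq_len(p)) for (i in j:p) {
    L[i, j] <- if (i == j) exp(theta[k]) else theta[k]
    k <- k + 1L
  }
  sb <- if (estimate_between) exp(theta[k - 1L + seq_len(p)]) else rep(0, p)
  list(sigma_within = L %*% t(L), sigma_between = sb, L = L)
}

# ---- fitting -----------------------------------------------------------

#' Control parameters for FIML fitting
#'
#' @param reltol relative log-likelihood convergence tolerance.
#' @param maxit maximum optimizer iterations.
#' @param restarts number of jittered restarts attempted on
#'   non-convergence.
#' @param jitter standard deviation of the restart jitter on the working
#'   parameter scale.
#' @param bound box bound (absolute value) on working parameters; the
#'   working scale is log-Cholesky for the within-study covariance and log
#'   for the between-study variances, so the default is far outside any
#'   plausible estimate.
#' @export
fiml_control <- function(reltol = 1e-8, maxit = 1000L, restarts = 3L,
                         jitter = 0.1, bound = 20) {
  list(reltol = reltol, maxit = maxit, restarts = restarts,
       jitter = jitter, bound = bound)
}

#' Fit the three-level normative model by full-information maximum
#' likelihood
#'
#' Estimates, for each test, an intercept and covariate slopes (fixed
#' effects shared across studies), an unstructured within-study residual
#' covariance, and a diagonal between-study covariance of study-level
#' intercept deviations.  All available scores contribute; tests a study
#' never administered are handled by restricting each study's likelihood to
#' its observed test set (valid because the missingness is by design, hence
#' ignorable).  Estimability of the full within-study covariance requires
#' every pair of tests to co-occur in at least one study
#' ([pair_coverage()]).
#'
#' @param x a `norm_dataset`, with covariates already centered
#'   ([center_covariates()]).
#' @param covariates covariate column names to include as fixed-effect
#'   slopes; may be `character(0)` for an intercept-only model.
#' @param estimate_between if `FALSE`, the between-study variances are
#'   fixed at zero rather than estimated.
#' @param control a list from [fiml_control()].
#' @param start optional starting values (list with `gamma`,
#'   `sigma_within`, `sigma_between`).
#' @return an object of class `mnc_fit` with components `gamma`
#'   (p x (1 + number of covariates) fixed-effect matrix), `sigma_within`,
#'   `sigma_between`, `loglik`, bookkeeping sizes (`n_participants`,
#'   `n_obs`, `n_studies`, `n_fixed_effects`) and a `converged` flag.
#' @seealso [adjusted_df()], [combined_covariance()],
#'   [normative_comparison()]
#' @export
fit_fiml <- function(x, covariates = c("age", "gender", "education"),
                     estimate_between = TRUE, control = fiml_control(),
                     start = NULL) {
  d <- dim_norms(x)
  p <- d$p
  pc <- pair_coverage(x)
  unc <- attr(pc, "uncovered")
  if (nrow(unc) > 0L) {
    stop("within-study covariance not estimable: test pair(s) never ",
         "administered together: ",
         paste(apply(unc, 1L, paste, collapse = "-"), collapse = ", "),
         call. = FALSE)
  }
  blocks <- as_study_blocks(x, covariates)
  c1 <- 1L + length(covariates)
  if (is.null(start)) start <- start_values(x, covariates, p, estimate_between)

  if (attr(blocks, "homogeneous")) {
    res <- fit_blocked(blocks, p, c1, estimate_between, control, start)
  } else {
    res <- fit_dense(blocks, p, c1, estimate_between, control, start,
                     covariates, x)
  }

  cn <- c("(Intercept)", covariates)
  dimnames(res$gamma) <- list(paste0("test", seq_len(p)), cn)
  dimnames(res$sigma_within) <- list(paste0("test", seq_len(p)),
                                     paste0("test", seq_len(p)))
  names(res$sigma_between) <- paste0("test", seq_len(p))
  out <- list(gamma = res$gamma,
              sigma_within = res$sigma_within,
              sigma_between = res$sigma_between,
              loglik = res$loglik,
              n_participants = d$N, n_obs = d$N_obs, n_studies = d$K,
              n_fixed_effects = p * c1,
              p = p, covariates = covariates,
              estimate_between = estimate_between,
              converged = res$converged, n_restarts = res$n_restarts,
              centering = attr(x, "centering"),
              test_names = attr(x, "test_names"),
              call = match.call())
  class(out) <- "mnc_fit"
  if (!out$converged) {
    warning("FIML fit did not converge after ", control$restarts,
            " restart(s); best parameters returned", call. = FALSE)
  }
  out
}

fit_blocked <- function(blocks, p, c1, estimate_between, control, start) {
  stats_list <- lapply(blocks, block_stats)
  optimize_blocked(stats_list, p, c1, estimate_between, control, start)
}

# Dense-assembly fallback for studies whose participants observed
# different test sets; feasible for small databases only.
fit_dense <- function(blocks, p, c1, estimate_between, control, start,
                      covariates, x) {
  df <- as.data.frame(x)
  per_study <- lapply(unique(df$study),
                      function(s) df[df$study == s, , drop = FALSE])
  nL <- p * (p + 1L) / 2L
  theta0 <- c(as.numeric(start$gamma),
              pack_theta(start$sigma_within, start$sigma_between,
                         estimate_between))
  obj <- function(th) {
    gamma <- matrix(th[seq_len(p * c1)], p, c1)
    pars <- unpack_theta(th[-seq_len(p * c1)], p, estimate_between)
    ll <- sum(vapply(per_study, function(st)
      study_loglik(gamma, pars$sigma_within, pars$sigma_between, st,
                   covariates, method = "dense"), 0))
    if (!is.finite(ll)) 1e12 else -ll
  }
  opt <- stats::optim(theta0, obj, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  gamma <- matrix(opt$par[seq_len(p * c1)], p, c1)
  pars <- unpack_theta(opt$par[-seq_len(p * c1)], p, estimate_between)
  list(gamma = gamma, sigma_within = pars$sigma_within,
       sigma_between = pars$sigma_between, loglik = -opt$value,
       converged = opt$convergence == 0L, n_restarts = 0L)
}

# ---- fitted-model accessors -------------------------------------------

#' Denominator degrees of freedom for normative comparisons
#'
#' With nested and missing data the classical n - p denominator is not
#' appropriate; the convention used here is
#' `N_obs - (K + q + 1)`, the number of score observations minus the number
#' of studies, the number of estimated fixed effects and one.
#'
#' @param model an `mnc_fit`.
#' @return an integer degrees-of-freedom value.
#' @export
adjusted_df <- function(model) {
  df2 <- model$n_obs - (model$n_studies + model$n_fixed_effects + 1L)
  if (df2 <= model$p) {
    stop("adjusted df (", df2, ") does not exceed the number of tests (",
         model$p, "); the comparison F distribution is undefined",
         call. = FALSE)
  }
  as.integer(df2)
}

#' Combined norm-group covariance
#'
#' The covariance against which a new patient is compared is the sum of the
#' within-study covariance and the (diagonal) between-study covariance,
#' since a new patient is not a member of any norm study.
#'
#' @param model an `mnc_fit`.
#' @return a p x p symmetric positive-definite matrix.
#' @export
combined_covariance <- function(model) {
  model$sigma_within + diag(model$sigma_between, nrow = model$p)
}

#' @export
logLik.mnc_fit <- function(object, ...) {
  structure(object$loglik,
            df = object$n_fixed_effects + object$p * (object$p + 1) / 2 +
              if (object$estimate_between) object$p else 0L,
            class = "logLik")
}

#' @export
coef.mnc_fit <- function(object, ...) object$gamma

#' @export
print.mnc_fit <- function(x, ...) {
  cat("Multilevel normative model (FIML)\n")
  cat(sprintf("  %d tests, %d studies, %d participants, %d scores\n",
              x$p, x$n_studies, x$n_participants, x$n_obs))
  cat(sprintf("  log-likelihood %.2f  (converged: %s)\n", x$loglik,
              x$converged))
  cat("Fixed effects:\n")
  print(round(x$gamma, 4))
  cat("Between-study variances:\n")
  print(round(x$sigma_between, 4))
  cat("Within-study covariance (diagonal):\n")
  print(round(diag(x$sigma_within), 4))
  invisible(x)
}

# ---- serialization -----------------------------------------------------

#' Write a fitted model to JSON
#'
#' @param model an `mnc_fit`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  p <- model$p
  lt <- model$sigma_within[lower.tri(model$sigma_within, diag = TRUE)]
  obj <- list(package = "mnormcomp",
              version = as.character(utils::packageVersion("mnormcomp")),
              p = p, covariates = model$covariates,
              gamma = model$gamma,
              sigma_within_lower = lt,
              sigma_between = unname(model$sigma_between),
              loglik = model$loglik,
              n_participants = model$n_participants,
              n_obs = model$n_obs, n_studies = model$n_studies,
              n_fixed_effects = model$n_fixed_effects,
              estimate_between = model$estimate_between,
              converged = model$converged,
              centering = model$centering,
              test_names = model$test_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path path written by [write_model()].
#' @return an `mnc_fit`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$p
  Sw <- matrix(0, p, p)
  Sw[lower.tri(Sw, diag = TRUE)] <- obj$sigma_within_lower
  Sw <- Sw + t(Sw) - diag(diag(Sw), p)
  gamma <- matrix(as.numeric(obj$gamma), p)
  cn <- c("(Intercept)", obj$covariates)
  dimnames(gamma) <- list(paste0("test", seq_len(p)), cn)
  dimnames(Sw) <- list(paste0("test", seq_len(p)), paste0("test", seq_len(p)))
  sb <- as.numeric(obj$sigma_between)
  names(sb) <- paste0("test", seq_len(p))
  out <- list(gamma = gamma, sigma_within = Sw, sigma_between = sb,
              loglik = obj$loglik,
              n_participants = obj$n_participants, n_obs = obj$n_obs,
              n_studies = obj$n_studies,
              n_fixed_effects = obj$n_fixed_effects,
              p = p, covariates = obj$covariates,
              estimate_between = obj$estimate_between,
              converged = obj$converged,
              centering = obj$centering,
              test_names = obj$test_names,
              call = NULL)
  class(out) <- "mnc_fit"
  out
}
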