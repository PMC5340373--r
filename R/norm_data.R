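#' Construct a long-format normative dataset
#'
#' A normative dataset holds one row per test score, with the study and
#' participant identifiers that define the nesting structure and the
#' participant-level background variables (age, gender, education) used for
#' regression-based norms.  Scores that a study never collected are simply
#' absent: the long format carries no explicit missing values.
#'
#' @param data a data.frame with columns `study`, `ID`, `age`, `gender`,
#'   `education`, `test`, `score`.  `test` must be coercible to consecutive
#'   integer test indices starting at 1; `gender` is either already a
#'   -1/+1 contrast code or a two-level factor/character (see
#'   [center_covariates()]).
#' @param test_names optional character vector mapping test index to a
#'   human-readable test name.
#' @param validate check structural invariants (default `TRUE`).
#' @return an object of class `norm_dataset` (a data.frame), with the
#'   derived sizes available through [dim_norms()].
#' @seealso [read_norm_long()], [center_covariates()], [pair_coverage()]
#' @export
norm_dataset <- function(data, test_names = NULL, validate = TRUE) {
  req <- c("study", "ID", "age", "gender", "education", "test", "score")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0L) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)[req]
  if (validate && nrow(data) == 0L) {
    stop("dataset has no score rows", call. = FALSE)
  }
  if (!is.numeric(data$score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(data$score)))))
    stop("non-numeric score value(s) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  data$test <- as.integer(data$test)
  if (validate) {
    if (nrow(data) == 0L) stop("dataset has no score rows", call. = FALSE)
    if (any(!is.finite(data$score))) {
      stop("non-finite score value(s) at row(s): ",
           paste(utils::head(which(!is.finite(data$score)), 5L),
                 collapse = ", "), call. = FALSE)
    }
    if (any(is.na(data$test)) || any(data$test < 1L)) {
      stop("test indices must be positive integers (1-based)", call. = FALSE)
    }
    key <- paste(data$study, data$ID, data$test, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1L]
      stop("duplicate (study, participant, test) combination: ",
           gsub("\r", " / ", d), call. = FALSE)
    }
  }
  structure(data,
            test_names = test_names,
            class = c("norm_dataset", "data.frame"))
}

#' Dataset dimensions
#'
#' @param x a `norm_dataset`.
#' @return a list with `p` (number of tests), `K` (number of studies),
#'   `N` (number of distinct participants), and `N_obs` (number of score
#'   rows).
#' @export
dim_norms <- function(x) {
  list(p = max(x$test),
       K = length(unique(x$study)),
       N = length(unique(paste(x$study, x$ID, sep = "\r"))),
       N_obs = nrow(x))
}

#' @export
print.norm_dataset <- function(x, ...) {
  d <- dim_norms(x)
  cat(sprintf(
    "Normative dataset: %d tests, %d studies, %d participants, %d scores\n",
    d$p, d$K, d$N, d$N_obs))
  ci <- attr(x, "centering")
  if (!is.null(ci)) {
    cat(sprintf("Covariates centered (age mean %.3f, education mean %.3f)\n",
                ci$age_mean, ci$education_mean))
  }
  NextMethod()
}

#' Read a long-format normative data file
#'
#' Reads a delimited text file with one row per test score (header columns
#' `study, ID, age, gender, education, test, score`; names configurable via
#' `col_names`).
#'
#' @param path file path.
#' @param sep field separator; `","` for CSV (default), `"\t"` for TSV.
#' @param col_names named character vector mapping the canonical column
#'   names to the names used in the file, e.g.
#'   `c(study = "study_id", score = "value")`.
#' @inheritParams norm_dataset
#' @return a `norm_dataset`.
#' @export
read_norm_long <- function(path, sep = ",", col_names = NULL,
                           test_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!is.null(col_names)) {
    for (canon in names(col_names)) {
      i <- match(col_names[[canon]], names(df))
      if (!is.na(i)) names(df)[i] <- canon
    }
  }
  norm_dataset(df, test_names = test_names)
}

#' Write a normative dataset in canonical long format
#'
#' Rows are sorted by study, participant and test, so that
#' `write_norm_long()` followed by [read_norm_long()] round-trips to the
#' same canonical form.
#'
#' @param x a `norm_dataset`.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_norm_long <- function(x, path, sep = ",") {
  o <- order(x$study, x$ID, x$test)
  utils::write.table(as.data.frame(x)[o, ], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Center covariates on the norm-group mean
#'
#' Age and education are centered on their participant-level means (each
#' participant counted once, however many scores they contribute) so that
#' model intercepts refer to the average participant; gender is mapped to a
#' -1/+1 contrast code.  Rows with a missing covariate are dropped listwise
#' with a message reporting the count.  The operation is idempotent, and a
#' patient's covariates must later be centered with the same
#' [centering_info()], never re-centered on their own.
#'
#' @param x a `norm_dataset`.
#' @param gender_map optional character vector of length 2 giving the levels
#'   mapped to -1 and +1 respectively; by default the sorted levels map to
#'   (-1, +1).
#' @return the dataset with centered covariates; the applied centering is
#'   stored as an attribute and returned by [centering_info()].
#' @export
center_covariates <- function(x, gender_map = NULL) {
  df <- as.data.frame(x)
  has_na <- !stats::complete.cases(df[c("age", "gender", "education")])
  if (any(has_na)) {
    message(sum(has_na), " row(s) dropped listwise (missing covariate)")
    df <- df[!has_na, , drop = FALSE]
  }
  g <- df$gender
  if (!is.numeric(g) || !all(g %in% c(-1, 1))) {
    lev <- sort(unique(as.character(g)))
    if (!is.null(gender_map)) lev <- gender_map
    if (length(lev) != 2L || !all(as.character(g) %in% lev)) {
      stop("gender is not codable to two levels", call. = FALSE)
    }
    df$gender <- ifelse(as.character(g) == lev[1L], -1, 1)
  }
  pid <- paste(df$study, df$ID, sep = "\r")
  first <- !duplicated(pid)
  age_mean <- mean(df$age[first])
  edu_mean <- mean(df$education[first])
  df$age <- df$age - age_mean
  df$education <- df$education - edu_mean
  out <- norm_dataset(df, test_names = attr(x, "test_names"),
                      validate = FALSE)
  prev <- attr(x, "centering")
  attr(out, "centering") <- list(
    age_mean = age_mean + if (is.null(prev)) 0 else prev$age_mean,
    education_mean = edu_mean + if (is.null(prev)) 0 else prev$education_mean,
    gender_coding = "contrast (-1, +1)")
  out
}

#' Centering information of a dataset or fitted model
#'
#' @param x a `norm_dataset` processed by [center_covariates()], or a
#'   fitted model.
#' @return a list with `age_mean`, `education_mean` and `gender_coding`,
#'   or `NULL` if covariates were never centered.
#' @export
centering_info <- function(x) attr(x, "centering")

#' Study co-occurrence counts for every pair of tests
#'
#' The within-study covariance between two tests is only estimable if at
#' least one study administered both.  This returns the p x p matrix whose
#' (i, j) entry counts the studies administering both test i and test j
#' (diagonal: studies administering test i), and flags uncovered pairs.
#'
#' @param x a `norm_dataset`.
#' @return an integer matrix of class `pair_coverage` with attribute
#'   `uncovered`, a two-column matrix listing pairs with zero coverage.
#' @export
pair_coverage <- function(x) {
  p <- max(x$test)
  studies <- unique(x$study)
  M <- matrix(0L, p, p)
  for (s in studies) {
    tests <- sort(unique(x$test[x$study == s]))
    M[tests, tests] <- M[tests, tests] + 1L
  }
  unc <- which(upper.tri(M) & M == 0L, arr.ind = TRUE)
  structure(M, uncovered = unc, class = c("pair_coverage", "matrix"))
}

#' @export
print.pair_coverage <- function(x, ...) {
  cat("Pair coverage (studies administering both tests):\n")
  print(unclass(structure(x, uncovered = NULL)))
  unc <- attr(x, "uncovered")
  if (nrow(unc) > 0L) {
    cat("WARNING: uncovered pair(s): ",
        paste(apply(unc, 1L, paste, collapse = "-"), collapse = ", "), "\n")
  } else {
    cat("All pairs co-occur in at least one study.\n")
  }
  invisible(x)
}
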