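#' Mark a data frame as a patient cohort
#'
#' A cohort is a tibble with one row per patient: candidate predictor
#' columns (all numeric; a column containing only 0 and 1 is treated as
#' intrinsically dichotomous, anything else as continuous) plus one binary
#' outcome column (1 = adverse event / morbid, 0 = normal). `as_cohort()`
#' validates the table and records which column is the outcome so that
#' downstream verbs need not be told again.
#'
#' @param data A data frame of numeric columns.
#' @param outcome Name of the binary outcome column.
#' @return A `cohort` tibble (the input with outcome metadata attached).
#' @examples
#' df <- data.frame(age = c(60, 72, 55), morbidity = c(0, 1, 0))
#' as_cohort(df, outcome = "morbidity")
#' @export
as_cohort <- function(data, outcome = "outcome") {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  if (nrow(data) == 0L) stop("cohort is empty: no patient rows", call. = FALSE)
  if (!is.character(outcome) || length(outcome) != 1L) {
    stop("`outcome` must be a single column name", call. = FALSE)
  }
  if (!outcome %in% names(data)) {
    stop(sprintf("outcome column '%s' not found in the table", outcome), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  not_num <- names(data)[!vapply(data, is.numeric, logical(1))]
  if (length(not_num)) {
    stop(sprintf("non-numeric column(s): %s", paste(not_num, collapse = ", ")),
         call. = FALSE)
  }
  y <- data[[outcome]]
  bad <- which(is.na(y) | !(y %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf(
      "outcome column '%s' must contain only 0/1; offending row(s): %s",
      outcome, paste(head(bad, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  structure(data,
            outcome = outcome,
            class = c("cohort", setdiff(class(tibble::tibble()), "cohort")))
}

#' @export
print.cohort <- function(x, ...) {
  y <- outcome_vector(x)
  cat(sprintf("# A cohort: %d patients, %d candidate variables, outcome '%s' (%.1f%% morbid)\n",
              nrow(x), length(predictor_names(x)), outcome_name(x), 100 * mean(y)))
  NextMethod()
}

#' Cohort accessors
#'
#' @param cohort A [as_cohort()] object.
#' @return `outcome_name()` the outcome column name; `outcome_vector()` the
#'   0/1 outcome; `predictor_names()` the candidate variable names;
#'   `variable_types()` a tibble with columns `variable` and
#'   `type` (`"dichotomous"` or `"continuous"`).
#' @export
outcome_name <- function(cohort) {
  nm <- attr(cohort, "outcome")
  if (is.null(nm)) stop("not a cohort: use as_cohort() first", call. = FALSE)
  nm
}

#' @rdname outcome_name
#' @export
outcome_vector <- function(cohort) cohort[[outcome_name(cohort)]]

#' @rdname outcome_name
#' @export
predictor_names <- function(cohort) setdiff(names(cohort), outcome_name(cohort))

#' @rdname outcome_name
#' @export
variable_types <- function(cohort) {
  vars <- predictor_names(cohort)
  tibble::tibble(
    variable = vars,
    type = vapply(vars, function(v) {
      if (is_dichotomous(cohort[[v]])) "dichotomous" else "continuous"
    }, character(1), USE.NAMES = FALSE)
  )
}

is_dichotomous <- function(x) {
  x <- x[!is.na(x)]
  length(x) > 0L && all(x %in% c(0, 1))
}

#' Read a cohort table from CSV
#'
#' Reads a comma-delimited, UTF-8 file with a header row. Empty cells (and
#' literal `NA`) are treated as missing; any other non-numeric cell is an
#' error that names the offending row and column.
#'
#' @param path Path to the CSV file.
#' @param outcome_column Name of the binary outcome column.
#' @return A validated [as_cohort()] tibble.
#' @export
read_cohort <- function(path, outcome_column = "outcome") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  if (nrow(raw) == 0L) stop("empty table: no data rows", call. = FALSE)
  parsed <- purrr::imap(raw, function(x, nm) {
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   x[bad[1L]], nm, bad[1L]), call. = FALSE)
    }
    num
  })
  as_cohort(tibble::as_tibble(parsed), outcome = outcome_column)
}

#' Stratified train/test split with equal outcome prevalence
#'
#' Morbid and normal patients are allocated to the training set independently
#' at the given fraction, so the two halves have (as nearly as integer counts
#' allow) the same percentage of adverse outcomes. When a stratum has an odd
#' count the larger half goes to training. The split is deterministic for a
#' given seed.
#'
#' @param cohort A [as_cohort()] object with both outcome classes present.
#' @param fraction Fraction of each stratum assigned to training, in (0,1).
#' @param seed Integer seed controlling the random allocation.
#' @return A list with elements `train` and `test`, both cohorts.
#' @export
stratified_split <- function(cohort, fraction = 0.5, seed = 1L) {
  cohort <- if (inherits(cohort, "cohort")) cohort else as_cohort(cohort)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  y <- outcome_vector(cohort)
  strata <- list(morbid = which(y == 1), normal = which(y == 0))
  if (any(lengths(strata) == 0L)) {
    stop("both outcome classes must be present to split", call. = FALSE)
  }
  # round half away from zero so the larger half of an odd stratum trains
  n_take <- vapply(strata, function(i) floor(fraction * length(i) + 0.5), numeric(1))
  if (any(n_take == 0) || any(n_take == lengths(strata))) {
    stop("fraction yields an empty stratum in train or test", call. = FALSE)
  }
  take <- withr::with_seed(seed, {
    unlist(purrr::map2(strata, n_take, function(idx, k) idx[sample.int(length(idx), k)]),
           use.names = FALSE)
  })
  take <- sort(take)
  rest <- setdiff(seq_len(nrow(cohort)), take)
  list(
    train = as_cohort(cohort[take, , drop = FALSE], outcome_name(cohort)),
    test  = as_cohort(cohort[rest, , drop = FALSE], outcome_name(cohort))
  )
}

#' Check train/test comparability variable by variable
#'
#' For every candidate variable, tests whether its distribution differs
#' between the training and testing cohorts: Fisher's exact test for
#' dichotomous variables, and for continuous variables a two-sample z-test
#' when a Shapiro-Wilk check (at `shapiro_alpha`) passes in both sets, else
#' the Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param train,test Cohorts sharing an identical column schema.
#' @param alpha Significance level for flagging a variable.
#' @param shapiro_alpha Level of the per-set normality check.
#' @return A tibble with columns `variable`, `test`
#'   (`"fisher-exact"`, `"z-test"` or `"mann-whitney"`), `p_value`,
#'   `significant`.
#' @export
balance_report <- function(train, test, alpha = 0.05, shapiro_alpha = 0.05) {
  train <- if (inherits(train, "cohort")) train else as_cohort(train)
  test <- if (inherits(test, "cohort")) test else as_cohort(test, outcome_name(train))
  tt <- variable_types(train)
  ts <- variable_types(test)
  if (!identical(tt$variable, ts$variable)) {
    stop("schema mismatch: train and test have different variables", call. = FALSE)
  }
  rows <- purrr::pmap(tt, function(variable, type) {
    x <- train[[variable]]; x <- x[!is.na(x)]
    z <- test[[variable]]; z <- z[!is.na(z)]
    if (type == "dichotomous" || is_dichotomous(c(x, z))) {
      m <- rbind(c(sum(x == 1), sum(x == 0)),
                 c(sum(z == 1), sum(z == 0)))
      p <- stats::fisher.test(m)$p.value
      used <- "fisher-exact"
    } else if (shapiro_p(x) > shapiro_alpha && shapiro_p(z) > shapiro_alpha) {
      p <- two_sample_z_p(x, z)
      used <- "z-test"
    } else {
      p <- mann_whitney_p(x, z)
      used <- "mann-whitney"
    }
    tibble::tibble(variable = variable, test = used, p_value = p,
                   significant = p < alpha)
  })
  dplyr::bind_rows(rows)
}

# Shapiro-Wilk p-value with the test's size limits handled deterministically:
# <3 values or a constant sample count as non-normal; >5000 values are
# thinned to an even grid of 5000 order statistics.
shapiro_p <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(unique(x)) < 2L) return(0)
  if (length(x) > 5000L) {
    x <- sort(x)[round(seq(1L, length(x), length.out = 5000L))]
  }
  stats::shapiro.test(x)$p.value
}

two_sample_z_p <- function(x, z) {
  se2 <- stats::var(x) / length(x) + stats::var(z) / length(z)
  if (se2 == 0) return(as.numeric(mean(x) == mean(z)))
  2 * stats::pnorm(-abs((mean(x) - mean(z)) / sqrt(se2)))
}

mann_whitney_p <- function(x, z) {
  if (length(unique(c(x, z))) < 2L) return(1)
  stats::wilcox.test(x, z, exact = FALSE, correct = FALSE)$p.value
}
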