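#' Additive integer scoring model
#'
#' An additive scoring system assigns each patient the integer
#' `s = sum_i lambda_i * s_i`, where `s_i` is the integer weight of the i-th
#' selected binary predictor and `lambda_i` is 1 when the patient lies on
#' the risk side of that predictor's cutoff (or risk level) and 0 otherwise.
#'
#' @param entries A data frame with one row per distinct predictor and
#'   columns `variable`, `cutoff`, `direction`, `risk_level`, `weight`
#'   (positive integers). Typically rows of a [screen_predictors()] table
#'   plus a weight.
#' @return A `score_model` object.
#' @seealso [compute_score()], [forward_select()]
#' @export
score_model <- function(entries) {
  req <- c("variable", "cutoff", "direction", "risk_level", "weight")
  if (!is.data.frame(entries) || !all(req %in% names(entries))) {
    stop(sprintf("`entries` must have columns %s", paste(req, collapse = ", ")),
         call. = FALSE)
  }
  entries <- tibble::as_tibble(entries)[, req]
  if (nrow(entries) == 0L) stop("a score model needs at least one predictor", call. = FALSE)
  if (anyDuplicated(entries$variable)) {
    stop("each predictor may appear only once; re-entries increment its weight",
         call. = FALSE)
  }
  w <- entries$weight
  if (any(is.na(w)) || any(w < 1) || any(w != round(w))) {
    stop("weights must be integers >= 1", call. = FALSE)
  }
  entries$weight <- as.integer(w)
  structure(list(entries = entries), class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("# Integer scoring model: %d predictors, maximum score %d\n",
              n_predictors(x), max_score(x)))
  print(x$entries)
  invisible(x)
}

#' @rdname score_model
#' @param model A `score_model`.
#' @export
max_score <- function(model) sum(model$entries$weight)

#' @rdname score_model
#' @export
n_predictors <- function(model) nrow(model$entries)

#' @export
tidy.score_model <- function(x, ...) x$entries

#' @export
glance.score_model <- function(x, ...) {
  tibble::tibble(d = n_predictors(x), max_score = max_score(x))
}

#' Score patients with a model
#'
#' Evaluates `sum_i lambda_i * s_i` for every row of `data`. Every model
#' predictor must be present and non-missing; a missing value is an error
#' naming the predictor and row, because the score is undefined without all
#' indicator terms.
#'
#' @param model A [score_model()].
#' @param data A data frame (or cohort) of raw predictor values.
#' @return An integer vector of scores in `[0, max_score(model)]`.
#' @export
compute_score <- function(model, data) {
  stopifnot(inherits(model, "score_model"))
  score <- numeric(nrow(data))
  for (i in seq_len(nrow(model$entries))) {
    e <- model$entries[i, ]
    if (!e$variable %in% names(data)) {
      stop(sprintf("predictor '%s' is missing from the data", e$variable),
           call. = FALSE)
    }
    v <- data[[e$variable]]
    if (anyNA(v)) {
      stop(sprintf("missing value for predictor '%s' (row %d): score undefined",
                   e$variable, which(is.na(v))[1L]), call. = FALSE)
    }
    score <- score + e$weight * risk_indicator_values(v, e$direction, e$cutoff, e$risk_level)
  }
  as.integer(score)
}

#' Rank-based AUC of a (possibly tied) score
#'
#' The probability that a randomly chosen morbid patient outscores a
#' randomly chosen normal one, with ties counted one half (the Mann-Whitney
#' form, equal to the trapezoidal area under the empirical ROC curve).
#'
#' @param scores Numeric scores.
#' @param outcome 0/1 outcome of the same length, both classes present.
#' @return AUC in `[0, 1]`.
#' @examples
#' rank_auc(c(1, 1, 2, 2), c(0, 0, 1, 1))
#' @export
rank_auc <- function(scores, outcome) {
  if (anyNA(scores) || anyNA(outcome)) stop("missing values in scores or outcome", call. = FALSE)
  if (length(scores) != length(outcome)) stop("length mismatch", call. = FALSE)
  if (!all(outcome %in% c(0, 1)) || length(unique(outcome)) < 2L) {
    stop("outcome must contain both classes (0 and 1)", call. = FALSE)
  }
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  r <- rank(scores)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Forward stepwise selection maximizing AUC, with re-entry
#'
#' Step 1 enters the screened candidate with the highest single-variable
#' training AUC. Every later step evaluates all candidates, including those
#' already in the model (whose integer weight would grow by 1), and applies
#' the action giving the highest training AUC. Selection stops when the
#' cumulative AUC gain over `window` consecutive steps falls below
#' `min_cum_increment`, or as soon as no action strictly improves the
#' training AUC. A test cohort, if supplied, is scored at every step for
#' audit only -- it never influences selection.
#'
#' Ties between equally good actions prefer entering a new variable over
#' incrementing a weight, then the alphabetically first variable.
#'
#' @param train Training [as_cohort()].
#' @param candidates A [screen_predictors()] table; only rows with
#'   `passed == TRUE` are used.
#' @param window Number of consecutive steps over which the cumulative AUC
#'   increment is assessed (default 5).
#' @param min_cum_increment Minimum cumulative AUC gain (absolute AUC units)
#'   over the window (default 0.01, i.e. 1%).
#' @param test Optional testing cohort.
#' @return A `forward_selection` object: `trace` (tibble with `step`,
#'   `action`, `variable`, `train_auc`, `test_auc`), `models` (the
#'   [score_model()] after each step), `model` (final step), `stop_step`,
#'   `stop_reason`.
#' @export
forward_select <- function(train, candidates, window = 5L,
                           min_cum_increment = 0.01, test = NULL) {
  train <- if (inherits(train, "cohort")) train else as_cohort(train)
  cand <- tibble::as_tibble(candidates)
  if ("passed" %in% names(cand)) cand <- cand[cand$passed %in% TRUE, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no screen-passing candidates", call. = FALSE)

  y <- outcome_vector(train)
  vars <- cand$variable
  L <- indicator_matrix(train, cand)
  cc <- stats::complete.cases(L)
  if (!all(cc)) {
    warning(sprintf("%d row(s) with missing candidate values dropped from training",
                    sum(!cc)))
    L <- L[cc, , drop = FALSE]; y <- y[cc]
  }
  if (length(unique(y)) < 2L) stop("training outcome has a single class", call. = FALSE)

  have_test <- !is.null(test)
  if (have_test) {
    test <- if (inherits(test, "cohort")) test else as_cohort(test, outcome_name(train))
    Lt <- indicator_matrix(test, cand)
    cct <- stats::complete.cases(Lt)
    if (!all(cct)) {
      warning(sprintf("%d row(s) with missing candidate values dropped from testing",
                      sum(!cct)))
      Lt <- Lt[cct, , drop = FALSE]
    }
    yt <- outcome_vector(test)[cct]
    tscore <- numeric(nrow(Lt))
  }

  p <- length(vars)
  weights <- stats::setNames(integer(p), vars)
  entry_order <- character(0)
  score <- numeric(nrow(L))
  prev_auc <- 0.5
  auc_hist <- numeric(0)
  trace <- list(); models <- list()
  stop_reason <- NA_character_
  step <- 0L
  repeat {
    step <- step + 1L
    aucs <- vapply(seq_len(p), function(j) rank_auc(score + L[, j], y), numeric(1))
    best <- max(aucs)
    if (best - prev_auc <= 1e-12) {
      step <- step - 1L
      stop_reason <- "no-improvement"
      break
    }
    tied <- which(best - aucs < 1e-12)
    fresh <- tied[weights[tied] == 0L]
    pool <- if (length(fresh)) fresh else tied
    j <- pool[order(vars[pool])][1L]
    action <- if (weights[j] == 0L) "enter" else "increment-weight"
    if (weights[j] == 0L) entry_order <- c(entry_order, vars[j])
    weights[j] <- weights[j] + 1L
    score <- score + L[, j]
    train_auc <- aucs[j]
    test_auc <- NA_real_
    if (have_test) {
      tscore <- tscore + Lt[, j]
      test_auc <- rank_auc(tscore, yt)
    }
    sel <- match(entry_order, cand$variable)
    models[[step]] <- score_model(dplyr::mutate(
      cand[sel, c("variable", "cutoff", "direction", "risk_level")],
      weight = as.integer(weights[entry_order])
    ))
    trace[[step]] <- tibble::tibble(step = step, action = action,
                                    variable = vars[j],
                                    train_auc = train_auc, test_auc = test_auc)
    prev_auc <- train_auc
    auc_hist[step] <- train_auc
    if (step > window && auc_hist[step] - auc_hist[step - window] < min_cum_increment) {
      stop_reason <- "window"
      break
    }
  }
  if (step == 0L) stop("no candidate improves on AUC 0.5: nothing to select", call. = FALSE)
  structure(list(trace = dplyr::bind_rows(trace), models = models,
                 model = models[[step]], stop_step = step,
                 stop_reason = stop_reason,
                 window = window, min_cum_increment = min_cum_increment),
            class = "forward_selection")
}

indicator_matrix <- function(cohort, cand) {
  m <- vapply(seq_len(nrow(cand)), function(i) {
    e <- cand[i, ]
    v <- cohort[[e$variable]]
    if (is.null(v)) stop(sprintf("candidate '%s' missing from cohort", e$variable),
                         call. = FALSE)
    risk_indicator_values(v, e$direction, e$cutoff, e$risk_level)
  }, numeric(nrow(cohort)))
  matrix(m, nrow = nrow(cohort), dimnames = list(NULL, cand$variable))
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf("# Forward AUC selection: %d steps, stopped by %s rule\n",
              x$stop_step, x$stop_reason))
  print(x$trace)
  invisible(x)
}

#' @export
tidy.forward_selection <- function(x, ...) x$trace

#' @export
glance.forward_selection <- function(x, ...) {
  tibble::tibble(
    steps = x$stop_step,
    stop_reason = x$stop_reason,
    n_predictors = n_predictors(x$model),
    max_score = max_score(x$model),
    train_auc = x$trace$train_auc[x$stop_step],
    test_auc = x$trace$test_auc[x$stop_step]
  )
}

#' Pick the step with the best held-out discrimination
#'
#' The soft stopping rule deliberately lets selection run past the point
#' where generalization peaks; the conclusive choice of a step is made on
#' the testing data. This helper returns the earliest step attaining the
#' maximum test AUC (or train AUC when no test cohort was recorded).
#'
#' @param selection A [forward_select()] result.
#' @return The step index (use `selection$models[[best_step(selection)]]`).
#' @export
best_step <- function(selection) {
  stopifnot(inherits(selection, "forward_selection"))
  a <- selection$trace$test_auc
  if (all(is.na(a))) a <- selection$trace$train_auc
  which(a > max(a, na.rm = TRUE) - 1e-12)[1L]
}
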