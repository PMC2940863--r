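#' ROC cutoff closest to the upper-left corner
#'
#' Scans every candidate cutoff (midpoints between consecutive sorted
#' distinct values) in both risk directions and returns the dichotomization
#' whose (sensitivity, specificity) point minimizes the squared Euclidean
#' distance to the perfect corner (1, 1). Ties are broken in favor of higher
#' sensitivity, then the lower cutoff, then the `at-or-above` direction.
#'
#' @param values Numeric predictor values (at least two distinct).
#' @param outcome 0/1 outcome of the same length, both classes present.
#' @return A list with `cutoff`, `direction` (`"at-or-above"` means values
#'   >= cutoff are risk-positive, `"below"` means values < cutoff are),
#'   `sensitivity` and `specificity`.
#' @examples
#' closest_corner_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
closest_corner_cutoff <- function(values, outcome) {
  keep <- !is.na(values) & !is.na(outcome)
  values <- values[keep]; y <- outcome[keep]
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L) {
    stop("outcome must contain both classes (0 and 1)", call. = FALSE)
  }
  dv <- sort(unique(values))
  if (length(dv) < 2L) stop("no ROC curve: variable is constant", call. = FALSE)
  k <- length(dv)
  tb <- table(factor(values, levels = dv), factor(y, levels = c(0, 1)))
  cnt0 <- as.numeric(tb[, 1L]); cnt1 <- as.numeric(tb[, 2L])
  n0 <- sum(cnt0); n1 <- sum(cnt1)
  cum0 <- cumsum(cnt0)[-k]; cum1 <- cumsum(cnt1)[-k]
  cand <- tibble::tibble(
    cutoff = rep((dv[-1L] + dv[-k]) / 2, 2L),
    direction = rep(c("at-or-above", "below"), each = k - 1L),
    sensitivity = c((n1 - cum1) / n1, cum1 / n1),
    specificity = c(cum0 / n0, (n0 - cum0) / n0)
  )
  cand$d2 <- (1 - cand$sensitivity)^2 + (1 - cand$specificity)^2
  best <- cand[cand$d2 - min(cand$d2) < 1e-12, , drop = FALSE]
  best <- best[best$sensitivity > max(best$sensitivity) - 1e-12, , drop = FALSE]
  best <- best[order(best$cutoff, best$direction), , drop = FALSE]
  as.list(best[1L, c("cutoff", "direction", "sensitivity", "specificity")])
}

#' Odds ratio with Woolf (logit) confidence interval
#'
#' For the 2x2 table of an exposure against a binary outcome, computes
#' OR = (a d)/(b c) and the Woolf interval
#' exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). If any cell is zero the
#' Haldane-Anscombe correction (+0.5 to all four cells) is applied first.
#'
#' @param exposed_morbid,exposed_normal,unexposed_morbid,unexposed_normal
#'   Non-negative cell counts (a, b, c, d).
#' @param level Confidence level, default 0.95.
#' @return A list with `odds_ratio`, `low`, `high`, and `corrected` (whether
#'   the zero-cell correction was applied).
#' @examples
#' odds_ratio_ci(20, 5, 10, 15)
#' @export
odds_ratio_ci <- function(exposed_morbid, exposed_normal,
                          unexposed_morbid, unexposed_normal, level = 0.95) {
  cells <- c(exposed_morbid, exposed_normal, unexposed_morbid, unexposed_normal)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  if (sum(cells) < 1) stop("all-zero 2x2 table", call. = FALSE)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(odds_ratio = or,
       low = exp(log(or) - z * se),
       high = exp(log(or) + z * se),
       corrected = corrected)
}

#' Dichotomize and screen candidate predictors
#'
#' Converts every candidate variable of a training cohort into an oriented
#' binary risk indicator and screens it. Continuous variables are cut at the
#' ROC corner-closest point ([closest_corner_cutoff()]); intrinsically
#' dichotomous variables are oriented so that the risk-positive level codes
#' 1 (the level with odds ratio >= 1). A predictor passes the screen when
#' the lower bound of the 95% Woolf CI of its odds ratio exceeds 1.
#' Constant columns are reported as screened out, not an error.
#'
#' @param train A training [as_cohort()].
#' @param level Confidence level of the odds-ratio screen.
#' @return A `predictor_screen` tibble with one row per candidate variable:
#'   `variable`, `type`, `cutoff`, `direction`, `risk_level`, `n_used`,
#'   `sensitivity`, `specificity`, `odds_ratio`, `or_low`, `or_high`,
#'   `passed`, `reason`.
#' @export
screen_predictors <- function(train, level = 0.95) {
  train <- if (inherits(train, "cohort")) train else as_cohort(train)
  y_all <- outcome_vector(train)
  types <- variable_types(train)
  rows <- purrr::pmap(types, function(variable, type) {
    v <- train[[variable]]
    keep <- !is.na(v)
    v <- v[keep]; y <- y_all[keep]
    out <- tibble::tibble(
      variable = variable, type = type,
      cutoff = NA_real_, direction = NA_character_, risk_level = NA_real_,
      n_used = length(v), sensitivity = NA_real_, specificity = NA_real_,
      odds_ratio = NA_real_, or_low = NA_real_, or_high = NA_real_,
      passed = FALSE, reason = NA_character_
    )
    if (length(unique(v)) < 2L) {
      out$reason <- "constant"
      return(out)
    }
    if (length(unique(y)) < 2L) {
      out$reason <- "single-class-outcome"
      return(out)
    }
    if (type == "dichotomous") {
      ind <- v
      ct <- xtab2(ind, y)
      or0 <- odds_ratio_ci(ct["a"], ct["b"], ct["c"], ct["d"], level)
      risk_level <- 1
      if (or0$odds_ratio < 1) {        # flip: absence is the risk-positive level
        ind <- 1 - ind
        risk_level <- 0
        ct <- xtab2(ind, y)
      }
      out$direction <- "intrinsic"
      out$risk_level <- risk_level
    } else {
      cc <- closest_corner_cutoff(v, y)
      ind <- risk_indicator_values(v, cc$direction, cc$cutoff, NA)
      ct <- xtab2(ind, y)
      out$cutoff <- cc$cutoff
      out$direction <- cc$direction
    }
    or <- odds_ratio_ci(ct[["a"]], ct[["b"]], ct[["c"]], ct[["d"]], level)
    out$sensitivity <- ct[["a"]] / (ct[["a"]] + ct[["c"]])
    out$specificity <- ct[["d"]] / (ct[["b"]] + ct[["d"]])
    out$odds_ratio <- or$odds_ratio
    out$or_low <- or$low
    out$or_high <- or$high
    out$passed <- or$low > 1
    if (!out$passed) out$reason <- "or-not-significant"
    out
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("predictor_screen", class(res))
  res
}

# 2x2 counts of an oriented indicator against the outcome
xtab2 <- function(ind, y) {
  c(a = sum(ind == 1 & y == 1), b = sum(ind == 1 & y == 0),
    c = sum(ind == 0 & y == 1), d = sum(ind == 0 & y == 0))
}

# lambda_i: is a raw value on the risk side of a predictor's rule?
risk_indicator_values <- function(v, direction, cutoff, risk_level) {
  switch(direction,
    "at-or-above" = as.numeric(v >= cutoff),
    "below"       = as.numeric(v < cutoff),
    "intrinsic"   = as.numeric(v == risk_level),
    stop(sprintf("unknown direction '%s'", direction), call. = FALSE)
  )
}
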