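#' Nearest-rank empirical quantile
#'
#' Returns the element of rank `ceiling(alpha * n)` of the sorted values
#' (clamped to `[1, n]`), so interval endpoints are always actual bootstrap
#' replicates.
#'
#' @param x Numeric values.
#' @param alpha Probability level(s) in (0, 1).
#' @return Elements of `x`, one per level.
#' @export
rank_quantile <- function(x, alpha) {
  x <- sort(x)
  n <- length(x)
  # the fuzz absorbs floating-point error in alpha * n (e.g. 0.025 * 1000 is
  # slightly above 25 in double arithmetic); it is far below any rank step
  x[pmin(pmax(ceiling(alpha * n - 1e-8), 1L), n)]
}

#' Simple percentile bootstrap interval
#'
#' The empirical `(1-level)/2` and `1-(1-level)/2` quantiles of the
#' bootstrap replicate statistics, under the nearest-rank rule
#' ([rank_quantile()]). At least 40 effective replicates are required so
#' that the 2.5th-percentile rank is defined.
#'
#' @param estimates Numeric vector of bootstrap replicate statistics
#'   (non-finite replicates are dropped).
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' percentile_interval((1:1000) / 1000)  # c(0.025, 0.975)
#' @export
percentile_interval <- function(estimates, level = 0.95) {
  estimates <- estimates[is.finite(estimates)]
  if (length(estimates) < 40L) {
    stop("fewer than 40 effective replicates: interval ranks undefined", call. = FALSE)
  }
  a <- (1 - level) / 2
  q <- rank_quantile(estimates, c(a, 1 - a))
  c(low = q[1L], high = q[2L])
}

#' BCa-adjusted percentile levels
#'
#' Maps the nominal tail levels of a `level` confidence interval through the
#' bias-correction coefficient `z0` and acceleration `a`:
#' `alpha_k = Phi(z0 + (z0 + z_k) / (1 - a (z0 + z_k)))`. With `z0 = 0` and
#' `a = 0` this is the identity, and the BCa interval reduces to the simple
#' percentile interval.
#'
#' @param z0 Bias-correction coefficient.
#' @param a Acceleration coefficient.
#' @param level Confidence level.
#' @return `c(alpha1, alpha2)`, clamped to (0, 1).
#' @export
bca_adjusted_levels <- function(z0, a, level = 0.95) {
  zk <- stats::qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
  adj <- z0 + (z0 + zk) / (1 - a * (z0 + zk))
  adj[!is.finite(adj)] <- sign(zk[!is.finite(adj)]) * Inf
  al <- stats::pnorm(adj)
  eps <- .Machine$double.eps
  pmin(pmax(al, eps), 1 - eps)
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Draws `B` with-replacement resamples of the original sample size,
#' computes the statistic on each, and returns the percentile interval at
#' quantile levels adjusted by the bias-correction coefficient
#' `z0 = Phi^-1[(#\{theta* < theta_hat\} + 0.5 #\{theta* = theta_hat\}) / B_eff]`
#' (the midrank convention keeps heavily tied proportion statistics
#' unbiased; a fraction of 0 or 1 is clamped to `1/(2 B_eff)` from the
#' boundary) and the acceleration
#' `a = sum(m - t_i)^3 / (6 [sum(m - t_i)^2]^{3/2})` estimated from the
#' leave-one-out jackknife values `t_i` with mean `m` (`a = 0` when the
#' denominator vanishes).
#'
#' @param sample A numeric vector, or a data frame resampled by rows.
#' @param statistic Function mapping a sample to a single number.
#' @param B Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling stream (ignored when
#'   `indices` is given).
#' @param indices Optional pre-drawn n-by-B matrix of resample indices, for
#'   sharing one resample stream across methods.
#' @param ... Passed on to `statistic`.
#' @return A `bca_interval` list: `low`, `high`, `diagnostics` (`z0`, `a`,
#'   `alpha1`, `alpha2`), `theta_hat`, `B_requested`, `B_effective`,
#'   `estimates`.
#' @examples
#' y <- rep(c(1, 0), c(20, 80))
#' bca_interval(y, mean, B = 200, seed = 7)[c("low", "high")]
#' @export
bca_interval <- function(sample, statistic, B = 1000L, level = 0.95,
                         seed = 1L, indices = NULL, ...) {
  n <- if (is.data.frame(sample)) nrow(sample) else length(sample)
  if (n < 2L) stop("sample must contain at least two observations", call. = FALSE)
  if (is.null(indices)) {
    if (B < 1L) stop("B must be at least 1", call. = FALSE)
    indices <- withr::with_seed(seed,
      matrix(sample.int(n, n * B, replace = TRUE), nrow = n, ncol = B))
  }
  B_requested <- ncol(indices)
  take <- if (is.data.frame(sample)) {
    function(i) sample[i, , drop = FALSE]
  } else {
    function(i) sample[i]
  }
  theta_hat <- statistic(sample, ...)
  if (!is.finite(theta_hat)) {
    stop("statistic is undefined on the original sample", call. = FALSE)
  }
  estimates <- vapply(seq_len(B_requested),
                      function(b) as.numeric(statistic(take(indices[, b]), ...)),
                      numeric(1))
  estimates <- estimates[is.finite(estimates)]
  B_eff <- length(estimates)
  if (B_eff == 0L) stop("statistic undefined on every resample", call. = FALSE)

  frac <- (sum(estimates < theta_hat) + 0.5 * sum(estimates == theta_hat)) / B_eff
  frac <- min(max(frac, 1 / (2 * B_eff)), 1 - 1 / (2 * B_eff))
  z0 <- stats::qnorm(frac)

  jack <- vapply(seq_len(n), function(i) as.numeric(statistic(take(-i), ...)), numeric(1))
  a <- accel_from_jackknife(jack)

  al <- bca_adjusted_levels(z0, a, level)
  q <- rank_quantile(estimates, al)
  structure(list(low = q[1L], high = q[2L],
                 diagnostics = list(z0 = z0, a = a, alpha1 = al[1L], alpha2 = al[2L]),
                 theta_hat = theta_hat, B_requested = B_requested,
                 B_effective = B_eff, estimates = estimates),
            class = "bca_interval")
}

accel_from_jackknife <- function(jack) {
  jack <- jack[is.finite(jack)]
  if (length(jack) < 2L) return(0)
  d <- mean(jack) - jack
  den <- 6 * sum(d^2)^1.5
  if (den == 0) return(0)
  sum(d^3) / den
}

#' @export
print.bca_interval <- function(x, ...) {
  cat(sprintf("BCa 95%% interval [%.4f, %.4f] (theta_hat %.4f, z0 %.3f, a %.4f, B_eff %d)\n",
              x$low, x$high, x$theta_hat, x$diagnostics$z0, x$diagnostics$a,
              x$B_effective))
  invisible(x)
}

#' Bootstrap confidence intervals of per-score-class outcome proportions
#'
#' The statistic of interest for each score class is the morbid fraction
#' among the patients falling in that class. Whole training cohorts are
#' resampled with replacement (class membership is recomputed within each
#' replicate, so class sizes vary as they should), and one shared stream of
#' resample indices serves every class, keeping all class statistics
#' replicate-coherent. Replicates in which a class is empty are dropped for
#' that class and the effective replicate count recorded (a warning below
#' 90% of `B`, an error below 50%). BCa acceleration uses the
#' leave-one-patient-out jackknife over the full training sample.
#'
#' @param train Training [as_cohort()]; the model must score every patient.
#' @param model A [score_model()].
#' @param classes Optional [pooling_plan()]; by default every score value
#'   observed in training is its own class.
#' @param B Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the shared resample stream.
#' @param test Optional testing cohort; its per-class morbid fractions are
#'   attached for comparison (never used in the intervals).
#' @param method `"bca"` (default) or `"percentile"`.
#' @return A `score_class_ci` tibble with one row per class: `class`,
#'   `score_min`, `score_max`, `n`, `pct_occurrence`, `proportion`,
#'   `ci_low`, `ci_high`, `method`, `B_effective`, `z0`, `a`, `test_n`,
#'   `test_proportion`. The plan used is attached as attribute `"plan"`.
#' @export
score_class_cis <- function(train, model, classes = NULL, B = 1000L,
                            level = 0.95, seed = 1L, test = NULL,
                            method = c("bca", "percentile")) {
  method <- match.arg(method)
  train <- if (inherits(train, "cohort")) train else as_cohort(train)
  y <- outcome_vector(train)
  s <- compute_score(model, train)
  n <- n_train <- length(s)
  plan <- classes %||% plan_from_scores(s, max_score(model))
  check_pooling_plan(plan, max_score(model))
  cls <- assign_classes(plan, s)
  C <- nrow(plan)
  nc <- tabulate(cls, C)
  if (any(nc == 0L)) {
    stop(sprintf("class '%s' is empty in the training data: class definition invalid",
                 plan$label[which(nc == 0L)[1L]]), call. = FALSE)
  }
  mc <- as.numeric(tapply(y, factor(cls, levels = seq_len(C)), sum, default = 0))
  prop <- mc / nc

  idx <- withr::with_seed(seed,
    matrix(sample.int(n, n * B, replace = TRUE), nrow = n, ncol = B))
  est <- matrix(NA_real_, nrow = C, ncol = B)
  for (b in seq_len(B)) {
    cb <- cls[idx[, b]]
    yb <- y[idx[, b]]
    ntab <- tabulate(cb, C)
    mtab <- tabulate(cb[yb == 1], C)
    est[, b] <- ifelse(ntab > 0L, mtab / ntab, NA_real_)
  }

  test_n <- rep(NA_integer_, C); test_prop <- rep(NA_real_, C)
  if (!is.null(test)) {
    test <- if (inherits(test, "cohort")) test else as_cohort(test, outcome_name(train))
    st <- compute_score(model, test)
    ct <- assign_classes(plan, st)
    yt <- outcome_vector(test)
    test_n <- tabulate(ct, C)
    mt <- as.numeric(tapply(yt, factor(ct, levels = seq_len(C)), sum, default = 0))
    test_prop <- ifelse(test_n > 0L, mt / test_n, NA_real_)
  }

  rows <- purrr::map(seq_len(C), function(c_i) {
    e <- est[c_i, ]
    e <- e[!is.na(e)]
    B_eff <- length(e)
    if (B_eff < 0.5 * B) {
      stop(sprintf("class '%s' empty in over half of the %d resamples (B_effective = %d)",
                   plan$label[c_i], B, B_eff), call. = FALSE)
    }
    if (B_eff < 0.9 * B) {
      warning(sprintf("class '%s': only %d of %d resamples contain the class",
                      plan$label[c_i], B_eff, B))
    }
    if (method == "bca") {
      frac <- (sum(e < prop[c_i]) + 0.5 * sum(e == prop[c_i])) / B_eff
      frac <- min(max(frac, 1 / (2 * B_eff)), 1 - 1 / (2 * B_eff))
      z0 <- stats::qnorm(frac)
      # leave-one-out jackknife of the class proportion, in closed form
      in_c <- cls == c_i
      jack <- rep(prop[c_i], n)
      if (nc[c_i] > 1L) {
        jack[in_c] <- (mc[c_i] - y[in_c]) / (nc[c_i] - 1L)
      } else {
        jack[in_c] <- NA_real_          # class vanishes: replicate undefined
      }
      a <- accel_from_jackknife(jack)
      q <- rank_quantile(e, bca_adjusted_levels(z0, a, level))
    } else {
      z0 <- NA_real_; a <- NA_real_
      q <- unname(percentile_interval(e, level))
    }
    tibble::tibble(
      class = plan$label[c_i], score_min = plan$score_min[c_i],
      score_max = plan$score_max[c_i], n = nc[c_i],
      pct_occurrence = 100 * nc[c_i] / n_train, proportion = prop[c_i],
      ci_low = q[1L], ci_high = q[2L], method = method,
      B_effective = B_eff, z0 = z0, a = a,
      test_n = test_n[c_i], test_proportion = test_prop[c_i]
    )
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "plan") <- plan
  attr(res, "level") <- level
  attr(res, "B") <- B
  attr(res, "seed") <- seed
  class(res) <- c("score_class_ci", class(res))
  res
}
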