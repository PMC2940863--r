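#' Default planted-predictor table
#'
#' Five binary risk indicators whose names and prevalences follow the
#' published profile of a CABG ICU-morbidity cohort: oxygen extraction ratio
#' >= 40% (21.3%, double-strength effect, carried by a continuous variable
#' cut at 40), cardiac inotropic drugs (13.6%), peripheral vascular disease
#' (21.3%), emergency status (8.3%), and cardio-pulmonary bypass time >= 2 h
#' (40.9%, continuous carrier cut at 2). Unit effects are one log-odds
#' (odds ratio about 2.7); the double-strength effect is two.
#'
#' @return A tibble with columns `name`, `prevalence`, `beta`, `carrier`,
#'   `cutoff`, `direction`, `scale`.
#' @export
default_predictors <- function() {
  tibble::tibble(
    name = c("O2ER", "CardID", "PVD", "EM", "CPBt"),
    prevalence = c(0.213, 0.136, 0.213, 0.083, 0.409),
    beta = c(2, 1, 1, 1, 1),
    carrier = c("continuous", "intrinsic", "intrinsic", "intrinsic", "continuous"),
    cutoff = c(40, NA, NA, NA, 2),
    direction = c("at-or-above", NA, NA, NA, "at-or-above"),
    scale = c(8, NA, NA, NA, 0.6)
  )
}

#' Specification of a synthetic cohort
#'
#' Describes a cohort in which independent binary risk indicators with set
#' prevalences drive a Bernoulli outcome through an additive-logit model
#' `P(y = 1 | x) = logistic(beta0 + sum_j beta_j x_j)`, some indicators are
#' carried by continuous variables (two half-normal components on either
#' side of the intended cutoff, so that cutoff is the corner-optimal
#' dichotomization in expectation), and additional noise variables are
#' independent of the outcome. The baseline logit `beta0` is calibrated by
#' exact root-finding so the population outcome prevalence equals
#' `target_prevalence`.
#'
#' @param n Cohort size (default 1090).
#' @param predictors Tibble as in [default_predictors()]: `name`,
#'   `prevalence` in (0,1), `beta` >= 0, `carrier`
#'   (`"intrinsic"`/`"continuous"`), `cutoff`, `direction`
#'   (`"at-or-above"`/`"below"`), `scale` (spread of the continuous carrier
#'   around its cutoff).
#' @param n_noise Number of non-informative variables (default 20,
#'   alternating intrinsically binary and continuous).
#' @param target_prevalence Desired population outcome prevalence (default
#'   0.207). Ignored when `baseline_logit` is given.
#' @param baseline_logit Optional fixed `beta0`.
#' @param seed Default seed used by [generate_cohort()].
#' @return A `synthetic_spec` list with the calibrated `beta0` and the exact
#'   population prevalence it attains.
#' @export
synthetic_spec <- function(n = 1090L, predictors = default_predictors(),
                           n_noise = 20L, target_prevalence = 0.207,
                           baseline_logit = NULL, seed = 1L) {
  p <- tibble::as_tibble(predictors)
  req <- c("name", "prevalence", "beta", "carrier")
  if (!all(req %in% names(p))) {
    stop(sprintf("`predictors` needs columns %s", paste(req, collapse = ", ")),
         call. = FALSE)
  }
  if (!"cutoff" %in% names(p)) p$cutoff <- NA_real_
  if (!"direction" %in% names(p)) p$direction <- NA_character_
  if (!"scale" %in% names(p)) p$scale <- NA_real_
  if (any(p$prevalence <= 0 | p$prevalence >= 1)) {
    stop("prevalences must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(p$beta < 0)) stop("true weights beta must be >= 0", call. = FALSE)
  cont <- p$carrier == "continuous"
  if (any(cont & (is.na(p$cutoff) | is.na(p$direction)))) {
    stop("continuous carriers need a cutoff and a direction", call. = FALSE)
  }
  p$scale[cont & is.na(p$scale)] <- abs(p$cutoff[cont & is.na(p$scale)]) * 0.2 + 0.1
  if (is.null(baseline_logit)) {
    if (target_prevalence <= 0 || target_prevalence >= 1) {
      stop("target prevalence must lie strictly in (0, 1)", call. = FALSE)
    }
    beta0 <- stats::uniroot(
      function(b0) exact_prevalence(b0, p$prevalence, p$beta) - target_prevalence,
      interval = c(-40, 40), tol = 1e-10
    )$root
  } else {
    beta0 <- baseline_logit
  }
  structure(list(n = as.integer(n), predictors = p, n_noise = as.integer(n_noise),
                 target_prevalence = target_prevalence, beta0 = beta0,
                 prevalence = exact_prevalence(beta0, p$prevalence, p$beta),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# exact population outcome prevalence under the product-Bernoulli indicator
# law: a finite sum over all 2^d indicator profiles (d <= 20 enforced)
exact_prevalence <- function(beta0, prevalence, beta) {
  g <- indicator_grid(length(prevalence))
  sum(profile_probs(g, prevalence) * stats::plogis(beta0 + drop(g %*% beta)))
}

indicator_grid <- function(d) {
  if (d > 20L) stop("more than 20 planted predictors: exact enumeration refused",
                    call. = FALSE)
  as.matrix(expand.grid(rep(list(c(0, 1)), d)))
}

profile_probs <- function(grid, prevalence) {
  apply(grid, 1L, function(x) prod(ifelse(x == 1, prevalence, 1 - prevalence)))
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "# Synthetic cohort spec: n = %d, %d planted + %d noise variables,\n#   beta0 = %.4f giving population outcome prevalence %.4f\n",
    x$n, nrow(x$predictors), x$n_noise, x$beta0, x$prevalence))
  print(x$predictors)
  invisible(x)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws the planted indicators independently at their prevalences, the
#' outcome from the additive-logit law, continuous carrier values as the
#' cutoff plus/minus a half-normal offset on the indicator's side (so the
#' drawn indicator and the dichotomized carrier agree exactly), and the
#' noise variables independently of everything informative. Deterministic
#' for a given seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (defaults to the spec's).
#' @param outcome Name of the outcome column (default `"morbidity"`).
#' @return A list: `cohort` (an [as_cohort()] tibble) and `truth` (the
#'   spec's parameters, the planted indicator columns and the seed).
#' @export
generate_cohort <- function(spec, seed = spec$seed, outcome = "morbidity") {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$predictors
  n <- spec$n
  res <- withr::with_seed(seed, {
    X <- vapply(p$prevalence, function(pr) stats::rbinom(n, 1L, pr), numeric(n))
    X <- matrix(X, nrow = n, dimnames = list(NULL, p$name))
    y <- stats::rbinom(n, 1L, stats::plogis(spec$beta0 + drop(X %*% p$beta)))
    cols <- purrr::map(seq_len(nrow(p)), function(j) {
      if (p$carrier[j] == "intrinsic") return(X[, j])
      off <- abs(stats::rnorm(n, 0, p$scale[j]))
      side <- if (p$direction[j] == "at-or-above") 2 * X[, j] - 1 else 1 - 2 * X[, j]
      p$cutoff[j] + side * off
    })
    names(cols) <- p$name
    noise <- purrr::map(seq_len(spec$n_noise), function(j) {
      if (j %% 2L == 1L) {
        stats::rbinom(n, 1L, stats::runif(1, 0.05, 0.5))
      } else {
        stats::rnorm(n, mean = stats::runif(1, -1, 1), sd = stats::runif(1, 0.5, 2))
      }
    })
    names(noise) <- sprintf("noise%02d", seq_len(spec$n_noise))
    list(cols = cols, noise = noise, X = X, y = y)
  })
  tab <- tibble::as_tibble(c(res$cols, res$noise))
  tab[[outcome]] <- res$y
  list(
    cohort = as_cohort(tab, outcome),
    truth = list(beta0 = spec$beta0, predictors = p,
                 indicators = res$X,
                 target_prevalence = spec$target_prevalence,
                 population_prevalence = spec$prevalence,
                 planted = p$name, n_noise = spec$n_noise,
                 outcome = outcome, seed = seed)
  )
}

#' The scoring model implied by a synthetic spec's true weights
#'
#' Integer weights proportional to the planted log-odds effects
#' (`round(beta / min positive beta)`); zero-effect predictors get weight 1
#' so they can be planted as known-null score terms.
#'
#' @param spec A [synthetic_spec()].
#' @return A [score_model()] over the planted predictors.
#' @export
true_score_model <- function(spec) {
  p <- spec$predictors
  unit <- if (any(p$beta > 0)) min(p$beta[p$beta > 0]) else 1
  w <- ifelse(p$beta > 0, round(p$beta / unit), 1)
  score_model(tibble::tibble(
    variable = p$name,
    cutoff = p$cutoff,
    direction = ifelse(p$carrier == "intrinsic", "intrinsic", p$direction),
    risk_level = ifelse(p$carrier == "intrinsic", 1, NA_real_),
    weight = as.integer(pmax(w, 1))
  ))
}

#' Exact per-class outcome probabilities under a synthetic spec
#'
#' Enumerates all 2^d indicator profiles of the planted predictors and
#' aggregates the product-Bernoulli profile probabilities and logistic
#' outcome probabilities by score class: `P(class)` and `P(outcome | class)`
#' are exact, not simulated. Model predictors must be a subset of the
#' planted ones (scores are evaluated on the indicator scale).
#'
#' @param spec A [synthetic_spec()] (at most 20 planted predictors).
#' @param model A [score_model()]; defaults to [true_score_model()].
#' @param classes Optional [pooling_plan()]; default one class per score
#'   0..max_score.
#' @return A tibble with `class`, `p_class`, `p_outcome`.
#' @export
true_class_probabilities <- function(spec, model = NULL, classes = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  model <- model %||% true_score_model(spec)
  p <- spec$predictors
  miss <- setdiff(model$entries$variable, p$name)
  if (length(miss)) {
    stop(sprintf("model predictors not planted in the spec: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  g <- indicator_grid(nrow(p))
  colnames(g) <- p$name
  pr <- profile_probs(g, p$prevalence)
  pout <- stats::plogis(spec$beta0 + drop(g %*% p$beta))
  w <- model$entries$weight
  s <- drop(g[, model$entries$variable, drop = FALSE] %*% w)
  ms <- max_score(model)
  plan <- classes %||% pooling_plan(0:ms, 0:ms, ms)
  check_pooling_plan(plan, ms)
  cls <- assign_classes(plan, s)
  p_class <- as.numeric(tapply(pr, factor(cls, levels = plan$class), sum, default = 0))
  p_joint <- as.numeric(tapply(pr * pout, factor(cls, levels = plan$class), sum, default = 0))
  tibble::tibble(class = plan$label, p_class = p_class,
                 p_outcome = ifelse(p_class > 0, p_joint / p_class, NA_real_))
}
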