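test_that("percentile interval follows the nearest-rank rule", {
  grid <- (1:1000) / 1000
  expect_equal(percentile_interval(grid), c(low = 0.025, high = 0.975))
  expect_equal(percentile_interval(rep(0.4, 100)), c(low = 0.4, high = 0.4))
  expect_error(percentile_interval(runif(39)), "40")
  # endpoints are always actual replicates
  withr::local_seed(4)
  x <- rnorm(507)
  ci <- percentile_interval(x)
  expect_true(all(ci %in% x))
})

test_that("BCa matches an independent reference on a shared resample stream", {
  y <- rep(c(1, 0), c(20, 80))
  idx <- withr::with_seed(31, matrix(sample.int(100, 100 * 1000, TRUE), 100, 1000))
  got <- bca_interval(y, mean, indices = idx)
  want <- reference_bca(y, mean, idx)
  expect_equal(c(got$low, got$high), unname(want), tolerance = 1e-12)
  expect_true(got$low <= 0.2 && 0.2 <= got$high)
  expect_true(got$low >= 0 && got$high <= 1)

  # and on a skewed continuous statistic
  x <- withr::with_seed(77, rexp(60))
  idx2 <- withr::with_seed(32, matrix(sample.int(60, 60 * 800, TRUE), 60, 800))
  got2 <- bca_interval(x, mean, indices = idx2)
  want2 <- reference_bca(x, mean, idx2)
  expect_equal(c(got2$low, got2$high), unname(want2), tolerance = 1e-12)
})

test_that("degenerate statistics give z0 = 0, a = 0 and a point interval", {
  y <- rep(c(1, 0), c(10, 10))
  ci <- bca_interval(y, function(s) 0.5, B = 100, seed = 1)
  expect_equal(ci$diagnostics$z0, 0)
  expect_equal(ci$diagnostics$a, 0)
  expect_equal(c(ci$low, ci$high), c(0.5, 0.5))
})

test_that("with z0 = 0 and a = 0 forced, BCa reduces exactly to percentile", {
  for (s in 1:20) {
    est <- withr::with_seed(s, switch(1 + s %% 3,
      rbeta(500, 2, 5), rnorm(750), rbinom(640, 30, 0.3) / 30))
    for (lev in c(0.9, 0.95, 0.99)) {
      al <- bca_adjusted_levels(0, 0, lev)
      expect_equal(rank_quantile(est, al),
                   unname(percentile_interval(est, lev)), tolerance = 0)
    }
  }
})

test_that("raising the level never narrows the interval", {
  y <- withr::with_seed(12, rbinom(150, 1, 0.25))
  prev <- c(1, 0)
  for (lev in c(0.90, 0.95, 0.99)) {
    ci <- bca_interval(y, mean, B = 500, level = lev, seed = 5)
    expect_lte(ci$low, prev[1] + 1e-12)
    expect_gte(ci$high, prev[2] - 1e-12)
    prev <- c(ci$low, ci$high)
  }
})

test_that("identical inputs give bit-identical intervals", {
  y <- withr::with_seed(3, rbinom(80, 1, 0.3))
  a <- bca_interval(y, mean, B = 300, seed = 11)
  b <- bca_interval(y, mean, B = 300, seed = 11)
  expect_identical(a[c("low", "high", "diagnostics")], b[c("low", "high", "diagnostics")])
  c_ <- bca_interval(y, mean, B = 300, seed = 12)
  expect_false(identical(a$estimates, c_$estimates))
})

test_that("BCa is no worse calibrated than percentile for a skewed mean", {
  # weak second-order check: coverage error for the mean of exponential data
  n <- 25; truth <- 1
  hit_b <- logical(400); hit_p <- logical(400)
  for (r in 1:400) {
    x <- withr::with_seed(5000 + r, rexp(n, rate = 1))
    ci <- bca_interval(x, mean, B = 999, seed = 5000 + r)
    hit_b[r] <- ci$low <= truth && truth <= ci$high
    pc <- percentile_interval(ci$estimates)
    hit_p[r] <- pc["low"] <= truth && truth <= pc["high"]
  }
  expect_lte(abs(mean(hit_b) - 0.95), abs(mean(hit_p) - 0.95) + 0.005)
})

test_that("score-class intervals resample whole cohorts coherently", {
  coh <- toy_cohort(300, seed = 6)
  scr <- screen_predictors(coh)
  m <- score_model(dplyr::mutate(scr[scr$variable == "risk", ], weight = 1L))
  st <- score_class_cis(coh, m, B = 500, seed = 9, test = toy_cohort(300, seed = 60))
  expect_equal(nrow(st), 2L)
  expect_equal(sum(st$n), 300)
  expect_equal(sum(st$pct_occurrence), 100)
  expect_true(all(st$ci_low <= st$proportion & st$proportion <= st$ci_high))
  expect_true(all(st$ci_low >= 0 & st$ci_high <= 1))
  expect_true(all(!is.na(st$test_proportion)))
  expect_true(all(st$B_effective <= 500))
  # monotone risk for this cohort: class 1 riskier than class 0
  expect_gt(st$proportion[2], st$proportion[1])

  # identical call is byte-identical
  st2 <- score_class_cis(coh, m, B = 500, seed = 9, test = toy_cohort(300, seed = 60))
  expect_identical(tibble::as_tibble(st), tibble::as_tibble(st2))
})

test_that("a pure-morbid class is a degenerate proportion with upper bound 1", {
  coh <- as_cohort(tibble::tibble(
    flag = rep(c(1, 0), c(25, 175)),
    outcome = c(rep(1, 25), rep(c(0, 1), c(150, 25)))
  ))
  m <- score_model(tibble::tibble(variable = "flag", cutoff = NA, direction = "intrinsic",
                                  risk_level = 1, weight = 1L))
  st <- score_class_cis(coh, m, B = 400, seed = 2)
  top <- st[st$class == "1", ]
  expect_equal(top$proportion, 1)
  expect_equal(top$ci_high, 1)
})

test_that("invalid class definitions and starved classes error out", {
  coh <- toy_cohort(200, seed = 14)
  scr <- screen_predictors(coh)
  m <- score_model(dplyr::mutate(scr[scr$variable == "risk", ], weight = 2L))
  # a plan with a class no training score reaches (score 1 unattainable alone)
  plan <- pooling_plan(c(0, 1, 2), c(0, 1, 2), 2)
  expect_error(score_class_cis(coh, m, plan, B = 100, seed = 1), "empty")
})

test_that("BCa class intervals cover the generator's exact truth near 95%", {
  # moderate-scale coverage check against the enumerated truth for the
  # mid-prevalence score-1 class of a two-predictor design
  pred <- tibble::tibble(name = c("A", "Bv"), prevalence = c(0.35, 0.25),
                         beta = c(1.2, 1.2), carrier = "intrinsic",
                         cutoff = NA_real_, direction = NA_character_,
                         scale = NA_real_)
  spec <- synthetic_spec(n = 545, predictors = pred, n_noise = 0,
                         target_prevalence = 0.207, seed = 1)
  m <- true_score_model(spec)
  truth <- true_class_probabilities(spec, m)
  hits <- logical(120)
  for (r in seq_along(hits)) {
    coh <- generate_cohort(spec, seed = 7000 + r)$cohort
    st <- score_class_cis(coh, m, B = 600, seed = 7000 + r)
    row <- st[st$class == "1", ]
    hits[r] <- row$ci_low <= truth$p_outcome[2] & truth$p_outcome[2] <= row$ci_high
  }
  expect_gt(mean(hits), 0.88)
  expect_lte(mean(hits), 1)
})
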