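six_var_model <- function() {
  # the published six-variable system: O2ER carries twice the weight of the rest
  score_model(tibble::tibble(
    variable = c("O2ER", "CardID", "PVD", "EM", "VCO2", "CPBt"),
    cutoff = c(40, NA, NA, NA, 180, 2),
    direction = c("at-or-above", "intrinsic", "intrinsic", "intrinsic",
                  "below", "at-or-above"),
    risk_level = c(NA, 1, 1, 1, NA, NA),
    weight = c(2L, 1L, 1L, 1L, 1L, 1L)
  ))
}

test_that("compute_score sums weighted risk indicators per the additive rule", {
  m <- six_var_model()
  expect_equal(max_score(m), 7)
  all_pos <- tibble::tibble(O2ER = 45, CardID = 1, PVD = 1, EM = 1,
                            VCO2 = 150, CPBt = 3)
  all_neg <- tibble::tibble(O2ER = 30, CardID = 0, PVD = 0, EM = 0,
                            VCO2 = 220, CPBt = 1)
  two_pos <- tibble::tibble(O2ER = 45, CardID = 0, PVD = 0, EM = 1,
                            VCO2 = 220, CPBt = 1)
  expect_equal(compute_score(m, all_pos), 7L)
  expect_equal(compute_score(m, all_neg), 0L)
  expect_equal(compute_score(m, two_pos), 3L)  # O2ER (2) + EM (1)

  miss <- all_pos; miss$PVD <- NA
  expect_error(compute_score(m, miss), "'PVD'")
  expect_error(compute_score(m, all_pos[, -1]), "'O2ER'")
})

test_that("score model construction enforces integer weights and uniqueness", {
  e <- six_var_model()$entries
  expect_error(score_model(dplyr::mutate(e, weight = 0.5)), "integers")
  expect_error(score_model(e[c(1, 1, 2), ]), "only once")
})

test_that("rank AUC equals the exhaustive pairwise count", {
  expect_equal(rank_auc(c(1, 1, 2, 2), c(0, 0, 1, 1)), 1)
  expect_equal(rank_auc(rep(3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(rank_auc(c(0, 1, 1, 2, 3), c(0, 0, 1, 1, 1)),
               pairwise_auc(c(0, 1, 1, 2, 3), c(0, 0, 1, 1, 1)))
  expect_error(rank_auc(1:4, rep(1, 4)), "both classes")

  for (s in 1:100) {
    n <- withr::with_seed(s, sample(5:200, 1))
    y <- withr::with_seed(s + 50, rbinom(n, 1, 0.4))
    if (length(unique(y)) < 2) next
    sc <- withr::with_seed(s + 99, sample(0:8, n, replace = TRUE))
    expect_equal(rank_auc(sc, y), pairwise_auc(sc, y), tolerance = 1e-12)
  }
})

test_that("forward selection is greedy, re-enters variables, and audits cleanly", {
  spec <- synthetic_spec(n = 2000, seed = 42)
  coh <- generate_cohort(spec, seed = 42)$cohort
  sp <- stratified_split(coh, 0.5, seed = 42)
  scr <- screen_predictors(sp$train)
  sel <- forward_select(sp$train, scr, test = sp$test)

  # train AUC non-decreasing; steps consecutive from 1
  expect_true(all(diff(sel$trace$train_auc) > -1e-12))
  expect_equal(sel$trace$step, seq_len(sel$stop_step))
  expect_true(sel$stop_reason %in% c("window", "no-improvement"))

  # greedy dominance at each step: the applied action beats every alternative
  y <- outcome_vector(sp$train)
  cand <- scr[scr$passed, ]
  w <- stats::setNames(integer(nrow(cand)), cand$variable)
  base <- numeric(nrow(sp$train))
  inds <- sapply(seq_len(nrow(cand)), function(i) {
    e <- cand[i, ]
    v <- sp$train[[e$variable]]
    if (e$direction == "intrinsic") as.numeric(v == e$risk_level)
    else if (e$direction == "at-or-above") as.numeric(v >= e$cutoff)
    else as.numeric(v < e$cutoff)
  })
  colnames(inds) <- cand$variable
  for (k in seq_len(sel$stop_step)) {
    alts <- vapply(cand$variable, function(v) rank_auc(base + inds[, v], y), numeric(1))
    expect_lte(max(alts), sel$trace$train_auc[k] + 1e-12)
    base <- base + inds[, sel$trace$variable[k]]
  }

  # weights in the final model equal the action counts in the trace
  tallied <- table(sel$trace$variable)
  for (v in sel$model$entries$variable) {
    expect_equal(sel$model$entries$weight[sel$model$entries$variable == v],
                 as.integer(tallied[[v]]))
  }
})

test_that("the window stopping rule fires exactly when its arithmetic says so", {
  spec <- synthetic_spec(n = 1500, seed = 7)
  coh <- generate_cohort(spec, seed = 7)$cohort
  scr <- screen_predictors(coh)
  sel <- forward_select(coh, scr, window = 5, min_cum_increment = 0.01)
  a <- sel$trace$train_auc
  t <- sel$stop_step
  if (sel$stop_reason == "window") {
    expect_gt(t, 5)
    expect_lt(a[t] - a[t - 5], 0.01)
    if (t > 6) {
      earlier <- (6):(t - 1)
      expect_true(all(a[earlier] - a[earlier - 5] >= 0.01))
    }
  }
  # an impossible demand stops at the first full window
  sel2 <- forward_select(coh, scr, window = 5, min_cum_increment = 1)
  if (sel2$stop_reason == "window") expect_equal(sel2$stop_step, 6L)
})

test_that("a lone saturating candidate stops with no-improvement", {
  coh <- as_cohort(tibble::tibble(
    flag = rep(c(1, 0), c(30, 70)),
    outcome = rep(c(1, 0), c(30, 70))
  ))
  scr <- screen_predictors(coh)
  sel <- forward_select(coh, scr)
  expect_equal(sel$stop_reason, "no-improvement")
  expect_equal(sel$stop_step, 1L)
  expect_equal(sel$trace$train_auc, 1)
})

test_that("selection is blind to the test outcome", {
  spec <- synthetic_spec(n = 1200, seed = 13)
  coh <- generate_cohort(spec, seed = 13)$cohort
  sp <- stratified_split(coh, 0.5, seed = 13)
  scr <- screen_predictors(sp$train)
  sel <- forward_select(sp$train, scr, test = sp$test)

  perm <- sp$test
  perm[[outcome_name(perm)]] <- withr::with_seed(1, sample(outcome_vector(perm)))
  sel_p <- forward_select(sp$train, scr, test = as_cohort(perm, "morbidity"))
  expect_identical(sel$trace$variable, sel_p$trace$variable)
  expect_identical(sel$model$entries, sel_p$model$entries)
  expect_false(isTRUE(all.equal(sel$trace$test_auc, sel_p$trace$test_auc)))
})

test_that("scores stay within [0, max_score] and weights move it additively", {
  spec <- synthetic_spec(n = 300, seed = 21)
  coh <- generate_cohort(spec, seed = 21)$cohort
  m <- true_score_model(spec)
  s <- compute_score(m, coh)
  expect_true(all(s >= 0 & s <= max_score(m)))
  e2 <- m$entries
  e2$weight[1] <- e2$weight[1] + 3L
  expect_equal(max_score(score_model(e2)), max_score(m) + 3L)
})
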