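# Independent oracles, written naively on purpose: exhaustive enumeration or
# direct formula evaluation, never sharing code with the implementation.

# AUC as an O(n^2) count over all morbid-normal pairs, ties counted one half
pairwise_auc <- function(scores, outcome) {
  m <- scores[outcome == 1]
  n <- scores[outcome == 0]
  tot <- 0
  for (a in m) for (b in n) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(m) * length(n))
}

# exhaustive search over every midpoint cutoff and both directions; returns
# the minimal squared distance to the (sens, spec) = (1, 1) corner
brute_corner_min_d2 <- function(values, outcome) {
  dv <- sort(unique(values))
  cuts <- (dv[-1] + dv[-length(dv)]) / 2
  best <- Inf
  for (ct in cuts) for (dir in c("above", "below")) {
    pos <- if (dir == "above") values >= ct else values < ct
    sens <- sum(pos & outcome == 1) / sum(outcome == 1)
    spec <- sum(!pos & outcome == 0) / sum(outcome == 0)
    best <- min(best, (1 - sens)^2 + (1 - spec)^2)
  }
  best
}

# Woolf logit interval evaluated directly from its formula
woolf_hand <- function(a, b, c, d, level = 0.95) {
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- a * d / (b * c)
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(or = or, low = exp(log(or) - z * se), high = exp(log(or) + z * se))
}

# two-sided Fisher p-value by brute-force enumeration of the hypergeometric
# support: sum of all table probabilities not exceeding the observed one
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# reference BCa interval on a shared, pre-drawn resample index stream;
# independent code path for z0, jackknife acceleration, adjusted levels and
# the nearest-rank quantile
reference_bca <- function(x, statistic, indices, level = 0.95) {
  theta <- statistic(x)
  est <- apply(indices, 2, function(i) statistic(x[i]))
  est <- est[is.finite(est)]
  B <- length(est)
  prop_less <- (sum(est < theta) + sum(est == theta) / 2) / B
  prop_less <- max(min(prop_less, 1 - 1 / (2 * B)), 1 / (2 * B))
  z0 <- qnorm(prop_less)
  th_i <- sapply(seq_along(x), function(i) statistic(x[-i]))
  dev <- mean(th_i) - th_i
  a <- if (sum(dev^2) == 0) 0 else sum(dev^3) / (6 * (sum(dev^2))^(3 / 2))
  zl <- qnorm((1 - level) / 2); zu <- qnorm((1 + level) / 2)
  a1 <- pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  srt <- sort(est)
  pick <- function(al) srt[min(max(ceiling(al * B), 1), B)]
  c(low = pick(a1), high = pick(a2))
}

# small cohort with one clean binary risk factor, for deterministic fixtures
toy_cohort <- function(n = 200, seed = 1) {
  withr::with_seed(seed, {
    risk <- rbinom(n, 1, 0.3)
    y <- rbinom(n, 1, ifelse(risk == 1, 0.6, 0.15))
    as_cohort(tibble::tibble(risk = risk, junk = rnorm(n), outcome = y))
  })
}

# the default planted five-predictor model: double-weight O2ER, units elsewhere
planted_names <- c("O2ER", "CardID", "PVD", "EM", "CPBt")
is_exact_planted <- function(model) {
  e <- model$entries
  setequal(e$variable, planted_names) &&
    e$weight[e$variable == "O2ER"] == 2 &&
    all(e$weight[e$variable != "O2ER"] == 1)
}
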