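#' Score-class pooling plan
#'
#' A pooling plan partitions the raw score range `0..max_score` into
#' contiguous, order-preserving classes. Each class is labelled by its score
#' ("3"), its range ("2-3"), or an open top class (">=5").
#'
#' @param score_min,score_max Integer vectors giving the inclusive bounds of
#'   each class, in increasing order, jointly covering `0..max_score`.
#' @param max_score The model's maximum score.
#' @param label Optional character labels; derived from the ranges when
#'   omitted.
#' @return A `pooling_plan` tibble with columns `class`, `label`,
#'   `score_min`, `score_max`.
#' @export
pooling_plan <- function(score_min, score_max, max_score, label = NULL) {
  plan <- tibble::tibble(
    class = seq_along(score_min),
    label = label %||% mapply(class_label, score_min, score_max,
                              MoreArgs = list(max_score = max_score)),
    score_min = as.integer(score_min),
    score_max = as.integer(score_max)
  )
  class(plan) <- c("pooling_plan", class(plan))
  check_pooling_plan(plan, max_score)
  plan
}

class_label <- function(lo, hi, max_score) {
  if (lo == hi) as.character(lo)
  else if (hi >= max_score) paste0(">=", lo)
  else paste0(lo, "-", hi)
}

check_pooling_plan <- function(plan, max_score) {
  req <- c("class", "label", "score_min", "score_max")
  if (!is.data.frame(plan) || !all(req %in% names(plan))) {
    stop("a pooling plan needs columns class, label, score_min, score_max", call. = FALSE)
  }
  if (any(plan$score_max < plan$score_min)) {
    stop("empty class range in pooling plan", call. = FALSE)
  }
  if (plan$score_min[1L] != 0L || plan$score_max[nrow(plan)] < max_score) {
    stop("pooling plan must cover scores 0 to max_score", call. = FALSE)
  }
  if (nrow(plan) > 1L &&
      any(plan$score_min[-1L] != plan$score_max[-nrow(plan)] + 1L)) {
    stop("pooling plan classes must be contiguous non-overlapping score ranges",
         call. = FALSE)
  }
  invisible(plan)
}

# identity plan: one class per score value observed in training; ranges are
# stretched so the plan still covers 0..max_score (an unobserved score maps
# to the class of the largest observed score below it).
plan_from_scores <- function(scores, max_score) {
  obs <- sort(unique(scores))
  score_min <- c(0L, obs[-1L])
  score_max <- c(obs[-1L] - 1L, max(max_score, obs[length(obs)]))
  pooling_plan(score_min, score_max, max_score,
               label = as.character(obs))
}

assign_classes <- function(plan, scores) {
  i <- findInterval(scores, plan$score_min)
  if (any(i < 1L)) stop("score below the pooling plan's range", call. = FALSE)
  i
}

#' Adjacent score classes with overlapping confidence intervals
#'
#' Two adjacent classes overlap when their closed confidence intervals
#' intersect; a shared endpoint counts as overlap (conservative toward
#' pooling).
#'
#' @param stats A [score_class_cis()] table, ordered by class.
#' @return A tibble with one row per overlapping adjacent pair: `index`
#'   (position of the lower class), `class_lower`, `class_upper`.
#' @export
find_overlaps <- function(stats) {
  C <- nrow(stats)
  if (C < 2L) {
    return(tibble::tibble(index = integer(0), class_lower = character(0),
                          class_upper = character(0)))
  }
  lo <- stats$ci_low; hi <- stats$ci_high
  i <- which(lo[-C] <= hi[-1L] & lo[-1L] <= hi[-C])
  tibble::tibble(index = i,
                 class_lower = stats$class[i],
                 class_upper = stats$class[i + 1L])
}

#' Pool score classes whose confidence intervals overlap
#'
#' `strategy = "greedy-top-down"` repeatedly merges, starting from the
#' highest scores where classes are sparse: first any class holding less
#' than `min_class_frac` of the training patients is united with its lower
#' neighbour (the bottom class, if undersized, joins its upper neighbour),
#' then the highest adjacent pair of overlapping intervals is merged. After
#' each merge the per-class intervals are re-estimated with the same seed,
#' and the process repeats until no overlap or undersized class remains (or
#' one class is left). `strategy = "manual"` applies `manual_plan` verbatim,
#' replicating a judgment call. Discrimination is re-assessed on pooled
#' class ranks before and after.
#'
#' @param train Training [as_cohort()].
#' @param model A [score_model()].
#' @param stats Optional starting [score_class_cis()] table (computed with
#'   the identity plan when omitted).
#' @param strategy `"greedy-top-down"` or `"manual"`.
#' @param manual_plan A [pooling_plan()] (required for `"manual"`).
#' @param B,level,seed,test As in [score_class_cis()].
#' @param min_class_frac Classes below this fraction of training patients
#'   are merge candidates even without CI overlap (default 0.02).
#' @return A `pooled_scores` object: `plan`, `stats` (final), `initial_stats`,
#'   `merges` (log of merge decisions), `auc` (train/test AUC on class ranks
#'   before and after pooling).
#' @export
pool_scores <- function(train, model, stats = NULL,
                        strategy = c("greedy-top-down", "manual"),
                        manual_plan = NULL, B = 1000L, level = 0.95,
                        seed = 1L, test = NULL, min_class_frac = 0.02) {
  strategy <- match.arg(strategy)
  train <- if (inherits(train, "cohort")) train else as_cohort(train)
  if (is.null(stats)) {
    stats <- score_class_cis(train, model, NULL, B = B, level = level,
                             seed = seed, test = test)
  }
  plan0 <- attr(stats, "plan")
  if (is.null(plan0)) stop("`stats` must come from score_class_cis()", call. = FALSE)

  y <- outcome_vector(train)
  s <- compute_score(model, train)
  auc_before_train <- rank_auc(assign_classes(plan0, s), y)
  have_test <- !is.null(test)
  if (have_test) {
    test <- if (inherits(test, "cohort")) test else as_cohort(test, outcome_name(train))
    st <- compute_score(model, test)
    yt <- outcome_vector(test)
    auc_before_test <- rank_auc(assign_classes(plan0, st), yt)
  }

  merges <- list()
  if (strategy == "manual") {
    if (is.null(manual_plan)) stop("manual strategy requires `manual_plan`", call. = FALSE)
    check_pooling_plan(manual_plan, max_score(model))
    plan <- manual_plan
    cur <- score_class_cis(train, model, plan, B = B, level = level,
                           seed = seed, test = test)
  } else {
    plan <- plan0
    cur <- stats
    repeat {
      if (nrow(plan) <= 1L) break
      small <- which(cur$pct_occurrence < 100 * min_class_frac)
      if (length(small)) {
        i <- max(small)
        pair <- if (i == 1L) 1L else i - 1L
        why <- "undersized"
      } else {
        ov <- find_overlaps(cur)
        if (nrow(ov) == 0L) break
        pair <- max(ov$index)
        why <- "ci-overlap"
      }
      merges[[length(merges) + 1L]] <- tibble::tibble(
        merged_lower = plan$label[pair], merged_upper = plan$label[pair + 1L],
        reason = why)
      plan <- merge_plan_pair(plan, pair, max_score(model))
      cur <- score_class_cis(train, model, plan, B = B, level = level,
                             seed = seed, test = test)
    }
  }

  auc <- tibble::tibble(
    dataset = c("train", if (have_test) "test"),
    auc_before = c(auc_before_train, if (have_test) auc_before_test),
    auc_after = c(rank_auc(assign_classes(plan, s), y),
                  if (have_test) rank_auc(assign_classes(plan, st), yt))
  )
  structure(list(plan = plan, stats = cur, initial_stats = stats,
                 merges = dplyr::bind_rows(merges), auc = auc),
            class = "pooled_scores")
}

merge_plan_pair <- function(plan, i, max_score) {
  lo <- plan$score_min; hi <- plan$score_max
  keep <- setdiff(seq_len(nrow(plan)), i + 1L)
  lo2 <- lo[keep]; hi2 <- hi[keep]
  hi2[which(keep == i)] <- hi[i + 1L]
  pooling_plan(lo2, hi2, max_score)
}

#' @export
print.pooled_scores <- function(x, ...) {
  cat(sprintf("# Pooled scoring system: %d classes (%d merges)\n",
              nrow(x$plan), nrow(x$merges)))
  print(x$stats)
  cat("\nDiscrimination on class ranks:\n")
  print(x$auc)
  invisible(x)
}

#' @export
tidy.pooled_scores <- function(x, ...) tibble::as_tibble(x$stats)

#' @export
glance.pooled_scores <- function(x, ...) {
  a <- x$auc
  tibble::tibble(
    n_classes = nrow(x$plan),
    n_merges = nrow(x$merges),
    train_auc_before = a$auc_before[a$dataset == "train"],
    train_auc_after = a$auc_after[a$dataset == "train"],
    test_auc_before = if ("test" %in% a$dataset) a$auc_before[a$dataset == "test"] else NA_real_,
    test_auc_after = if ("test" %in% a$dataset) a$auc_after[a$dataset == "test"] else NA_real_
  )
}

#' Read/write a pooling plan as JSON
#'
#' The file is a JSON object mapping every raw score to its class label,
#' e.g. `{"0":"0", ..., "5":">=5", "6":">=5", "7":">=5"}`.
#'
#' @param plan A [pooling_plan()].
#' @param path File path.
#' @param max_score The model's maximum score (checked on read).
#' @return `read_pooling_plan()` returns a [pooling_plan()].
#' @export
write_pooling_plan <- function(plan, path) {
  scores <- plan$score_min[1L]:plan$score_max[nrow(plan)]
  lab <- plan$label[assign_classes(plan, scores)]
  jsonlite::write_json(as.list(stats::setNames(lab, scores)), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pooling_plan
#' @export
read_pooling_plan <- function(path, max_score) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  scores <- as.integer(names(m))
  lab <- as.character(unlist(m))[order(scores)]
  scores <- sort(scores)
  if (!identical(scores, seq(0L, max_score))) {
    stop("pooling plan file must map every score 0..max_score", call. = FALSE)
  }
  runs <- rle(lab)
  hi <- cumsum(runs$lengths) - 1L
  lo <- hi - runs$lengths + 1L
  if (anyDuplicated(runs$values)) {
    stop("non-contiguous class in pooling plan file", call. = FALSE)
  }
  pooling_plan(lo, hi, max_score, label = runs$values)
}
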