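#' Serialize a scoring model to JSON
#'
#' The file stores everything needed to score a new patient without the
#' training data: predictor names, cutoffs, directions, risk levels and
#' integer weights, plus the outcome name and provenance.
#'
#' @param model A [score_model()].
#' @param path File path.
#' @param outcome_name Name of the outcome the model predicts.
#' @param created_from Optional list recorded verbatim (e.g. `n_train`, `seed`).
#' @return `read_score_model()` returns a [score_model()].
#' @export
write_score_model <- function(model, path, outcome_name = "outcome",
                              created_from = NULL) {
  stopifnot(inherits(model, "score_model"))
  jsonlite::write_json(
    list(predictors = model$entries, outcome_name = outcome_name,
         created_from = created_from),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  e <- tibble::as_tibble(obj$predictors)
  if (!"cutoff" %in% names(e)) e$cutoff <- NA_real_
  if (!"risk_level" %in% names(e)) e$risk_level <- NA_real_
  e$cutoff <- as.numeric(e$cutoff)
  e$risk_level <- as.numeric(e$risk_level)
  score_model(e)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with its standard
#' default: an equal split (fraction 0.5), the soft stopping rule (5-step
#' window, 1% minimum cumulative AUC gain), 1000 bootstrap resamples at the
#' 95% level, greedy pooling with a 2% minimum class size.
#'
#' @param fraction Training fraction of each outcome stratum.
#' @param split_seed,boot_seed Integer seeds for the split and the
#'   bootstrap resampling stream.
#' @param window,min_increment Forward-selection stopping rule.
#' @param B,level Bootstrap replicates and confidence level.
#' @param pooling `"greedy-top-down"` or `"manual"`.
#' @param min_class_frac Minimum class size fraction before pooling triggers.
#' @param final_step Step whose model is pooled and reported; default the
#'   best-generalizing step ([best_step()]).
#' @param ci_steps Steps for which per-class CI tables are written; default
#'   all steps.
#' @return A `run_config` list.
#' @export
run_config <- function(fraction = 0.5, split_seed = 1L, boot_seed = 1L,
                       window = 5L, min_increment = 0.01, B = 1000L,
                       level = 0.95, pooling = "greedy-top-down",
                       min_class_frac = 0.02, final_step = NULL,
                       ci_steps = NULL) {
  structure(list(fraction = fraction, split_seed = split_seed,
                 boot_seed = boot_seed, window = window,
                 min_increment = min_increment, B = B, level = level,
                 pooling = pooling, min_class_frac = min_class_frac,
                 final_step = final_step, ci_steps = ci_steps),
            class = "run_config")
}

#' Run the whole scoring-system pipeline and write a report bundle
#'
#' Executes split, balance check, screening, forward selection, per-step
#' score-class confidence intervals and class pooling, and writes the
#' machine-readable twins of the method's standard displays into `out_dir`:
#' `balance.tsv`, `screening.tsv`, `selection_trace.tsv` (AUC per step),
#' `score_class_ci.tsv` (per-step class intervals), `pooled_report.tsv`,
#' `pooled_auc.tsv`, `model.json`, `pooling_plan.json` and `run_log.txt`.
#' Identical inputs and configuration give a byte-identical bundle.
#'
#' @param cohort A cohort, a data frame, or a path to a cohort CSV.
#' @param outcome Outcome column name (used when `cohort` is a path or a
#'   plain data frame).
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted objects and file paths.
#' @export
run_pipeline <- function(cohort, outcome = "outcome", out_dir,
                         config = run_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort, outcome)
  if (!inherits(cohort, "cohort")) cohort <- as_cohort(cohort, outcome)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- function(f) file.path(out_dir, f)

  sp <- stratified_split(cohort, fraction = config$fraction, seed = config$split_seed)
  bal <- balance_report(sp$train, sp$test)
  readr::write_tsv(bal, paths("balance.tsv"))

  scr <- screen_predictors(sp$train)
  readr::write_tsv(tibble::as_tibble(scr), paths("screening.tsv"))

  sel <- forward_select(sp$train, scr, window = config$window,
                        min_cum_increment = config$min_increment, test = sp$test)
  readr::write_tsv(sel$trace, paths("selection_trace.tsv"))

  ci_steps <- config$ci_steps %||% seq_len(sel$stop_step)
  ci_tabs <- purrr::map(ci_steps, function(k) {
    dplyr::mutate(
      tibble::as_tibble(score_class_cis(sp$train, sel$models[[k]],
                                        B = config$B, level = config$level,
                                        seed = config$boot_seed, test = sp$test)),
      step = k, .before = 1L)
  })
  readr::write_tsv(dplyr::bind_rows(ci_tabs), paths("score_class_ci.tsv"))

  final_step <- config$final_step %||% best_step(sel)
  final_model <- sel$models[[final_step]]
  pooled <- pool_scores(sp$train, final_model, strategy = config$pooling,
                        B = config$B, level = config$level,
                        seed = config$boot_seed, test = sp$test,
                        min_class_frac = config$min_class_frac)
  readr::write_tsv(tibble::as_tibble(pooled$stats), paths("pooled_report.tsv"))
  readr::write_tsv(pooled$auc, paths("pooled_auc.tsv"))
  write_score_model(final_model, paths("model.json"),
                    outcome_name = outcome_name(cohort),
                    created_from = list(n_train = nrow(sp$train),
                                        split_seed = config$split_seed,
                                        step = final_step))
  write_pooling_plan(pooled$plan, paths("pooling_plan.json"))

  log_lines <- c(
    sprintf("bootscore %s", as.character(utils::packageVersion("bootscore"))),
    sprintf("n = %d (train %d / test %d), outcome '%s'",
            nrow(cohort), nrow(sp$train), nrow(sp$test), outcome_name(cohort)),
    sprintf("split: fraction %g, seed %d", config$fraction, config$split_seed),
    sprintf("selection: window %d, min cumulative increment %g, stop at step %d (%s)",
            config$window, config$min_increment, sel$stop_step, sel$stop_reason),
    sprintf("reported model: step %d (%d predictors, max score %d)",
            final_step, n_predictors(final_model), max_score(final_model)),
    sprintf("bootstrap: B %d, level %g, seed %d", config$B, config$level,
            config$boot_seed),
    sprintf("pooling (%s): %d merge(s)%s", config$pooling, nrow(pooled$merges),
            if (nrow(pooled$merges)) paste0(" - ",
              paste(sprintf("%s+%s [%s]", pooled$merges$merged_lower,
                            pooled$merges$merged_upper, pooled$merges$reason),
                    collapse = ", ")) else ""),
    sprintf("class B_effective: %s",
            paste(sprintf("%s=%d", pooled$stats$class, pooled$stats$B_effective),
                  collapse = ", "))
  )
  writeLines(log_lines, paths("run_log.txt"))

  invisible(list(split = sp, balance = bal, screen = scr, selection = sel,
                 class_cis = ci_tabs, final_step = final_step,
                 model = final_model, pooled = pooled,
                 files = paths(c("balance.tsv", "screening.tsv",
                                 "selection_trace.tsv", "score_class_ci.tsv",
                                 "pooled_report.tsv", "pooled_auc.tsv",
                                 "model.json", "pooling_plan.json",
                                 "run_log.txt"))))
}
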