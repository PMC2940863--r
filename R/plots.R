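#' Plot the forward-selection AUC trajectory
#'
#' Training AUC (circles) and, when recorded, test AUC (stars) per step of
#' the forward stepwise algorithm, with the variable acted on at each step
#' on the axis.
#'
#' @param object A [forward_select()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.forward_selection <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("train_auc", "test_auc"),
                            names_to = "dataset", values_to = "auc")
  tr$dataset <- sub("_auc$", "", tr$dataset)
  tr <- tr[!is.na(tr$auc), , drop = FALSE]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$auc,
                                   shape = .data$dataset,
                                   linetype = .data$dataset)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(train = 1, test = 8)) +
    ggplot2::scale_x_continuous(breaks = object$trace$step,
                                labels = paste0(object$trace$step, "\n",
                                                object$trace$variable)) +
    ggplot2::labs(x = "step (variable entered)", y = "AUC", shape = NULL,
                  linetype = NULL,
                  title = "Forward stepwise selection")
}

#' Whisker plot of score-class morbidity probabilities
#'
#' One whisker per score class: the observed training-proportion point with
#' its bootstrap confidence interval; stars mark the morbid fraction
#' observed in the test cohort, and labels give each class's percentage
#' occurrence.
#'
#' @param object A [score_class_cis()] table.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.score_class_ci <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$class <- factor(d$class, levels = d$class)
  pl <- ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$proportion)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::geom_text(ggplot2::aes(y = .data$ci_high,
                                    label = sprintf("%.1f%%", .data$pct_occurrence)),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "score class", y = "probability of morbidity",
                  title = sprintf("%d%% bootstrap confidence intervals (%s)",
                                  round(100 * (attr(object, "level") %||% 0.95)),
                                  d$method[1L]))
  if (any(!is.na(d$test_proportion))) {
    pl <- pl + ggplot2::geom_point(ggplot2::aes(y = .data$test_proportion),
                                   shape = 8, size = 2.5, na.rm = TRUE)
  }
  pl
}

#' @rdname autoplot.score_class_ci
#' @export
autoplot.pooled_scores <- function(object, ...) {
  autoplot.score_class_ci(object$stats, ...)
}
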