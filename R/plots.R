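# ggplot2 displays for the main result types.

#' Volcano plot of per-miRNA differential statistics
#'
#' @param stats A `marker_stats` tibble.
#' @param p_thresh,lfc_thresh Thresholds drawn and used to colour passing
#'   markers.
#' @return A ggplot object.
#' @export
plot_volcano <- function(stats, p_thresh = 0.01, lfc_thresh = 0.5) {
  stats <- stats |>
    mutate(pass = .data$p_value < p_thresh & abs(.data$log2fc) > lfc_thresh)
  ggplot(stats, aes(x = .data$log2fc, y = -log10(.data$p_value),
                    colour = .data$pass)) +
    geom_point(alpha = 0.7, size = 1.2) +
    geom_vline(xintercept = c(-lfc_thresh, lfc_thresh), linetype = "dashed",
               linewidth = 0.3) +
    geom_hline(yintercept = -log10(p_thresh), linetype = "dashed",
               linewidth = 0.3) +
    scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey55"),
                        guide = "none") +
    labs(x = "log2 fold change (cancer vs control)", y = "-log10 p") +
    theme_minimal()
}

#' @rdname plot_volcano
#' @param object A `marker_stats` tibble.
#' @param ... Passed to [plot_volcano()].
#' @method autoplot marker_stats
#' @export
autoplot.marker_stats <- function(object, ...) plot_volcano(object, ...)

#' Cross-validation AUC by panel size
#'
#' Boxplots of training and held-out AUC per panel size across all
#' cross-validation records.
#'
#' @param cv A `panel_cv` record table.
#' @return A ggplot object.
#' @export
plot_cv_auc <- function(cv) {
  long <- cv |>
    tidyr::pivot_longer(c("train_auc", "test_auc"), names_to = "set",
                        values_to = "auc") |>
    mutate(set = ifelse(.data$set == "train_auc", "training", "test"))
  ggplot(long, aes(x = factor(.data$panel_size), y = .data$auc,
                   fill = .data$set)) +
    geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    labs(x = "panel size (number of miRNAs)", y = "AUC", fill = NULL) +
    theme_minimal()
}

#' @rdname plot_cv_auc
#' @param object A `panel_cv` table.
#' @param ... Unused.
#' @method autoplot panel_cv
#' @export
autoplot.panel_cv <- function(object, ...) plot_cv_auc(object)

#' ROC curve of a panel evaluation
#'
#' @param evaluation A `panel_evaluation` (or pass `scores` and `labels`).
#' @return A ggplot object.
#' @export
plot_roc <- function(evaluation) {
  y <- class_vector(evaluation$scores, evaluation$scores$sample_id)
  pts <- roc_points(evaluation$scores$score, y)
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                colour = "grey60") +
    geom_path(linewidth = 0.7, colour = "steelblue") +
    annotate("text", x = 0.7, y = 0.12,
             label = sprintf("AUC %.3f (%.3f-%.3f)", evaluation$auc$auc,
                             evaluation$auc$conf_low,
                             evaluation$auc$conf_high)) +
    labs(x = "1 - specificity", y = "sensitivity") +
    theme_minimal()
}

#' @rdname plot_roc
#' @param object A `panel_evaluation`.
#' @param ... Unused.
#' @method autoplot panel_evaluation
#' @export
autoplot.panel_evaluation <- function(object, ...) plot_roc(object)

#' Risk-score distributions by tumour stage
#'
#' @param scores Score tibble with `score`, `class`, `stage` columns (e.g.
#'   the `scores` element of a `panel_evaluation`).
#' @return A ggplot object.
#' @export
plot_scores_by_stage <- function(scores) {
  scores <- scores |>
    mutate(stage = ifelse(.data$class == "non_cancer", "non-cancer",
                          .data$stage),
           stage = factor(.data$stage,
                          levels = c("non-cancer", stage_levels())))
  ggplot(scores, aes(x = .data$stage, y = .data$score,
                     fill = .data$class)) +
    geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    labs(x = "tumour stage", y = "risk score", fill = NULL) +
    theme_minimal()
}
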