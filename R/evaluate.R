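# Held-out evaluation: ROC/AUC with confidence intervals, operating point,
# and stratified performance.

#' ROC curve points
#'
#' Thresholds at every distinct score; the curve runs from (0, 0) to (1, 1).
#' A point's TPR/FPR uses the rule score >= threshold => predicted cancer.
#'
#' @param scores Numeric risk scores.
#' @param labels Class labels (0/1 or cancer/non_cancer).
#' @return Tibble (`threshold`, `fpr`, `tpr`) ordered by increasing FPR.
#' @export
roc_points <- function(scores, labels) {
  y <- to_binary(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    abort("both classes must be present", class = "mirpanel_stats_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  keep <- !duplicated(s)
  tp <- cumsum(yy)
  fp <- cumsum(1 - yy)
  idx <- c(which(keep)[-1] - 1L, length(s))
  tibble(
    threshold = c(Inf, s[keep]),
    fpr = c(0, fp[idx] / n0),
    tpr = c(0, tp[idx] / n1)
  )
}

#' Trapezoid area under the ROC curve
#'
#' Numerically identical to the Mann-Whitney statistic
#' \eqn{U/(n_1 n_0)} with ties counting 1/2.
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
}

#' AUC with a 95% confidence interval
#'
#' DeLong variance-based interval by default (normal approximation, clipped
#' to \[0, 1\]); a seeded stratified bootstrap (percentile interval) is
#' available as a cross-check and as the fallback when the DeLong variance
#' degenerates.
#'
#' @inheritParams roc_points
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param conf Confidence level.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return Tibble (`auc`, `conf_low`, `conf_high`, `method`).
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   conf = 0.95, n_boot = 2000, seed = 1) {
  method <- match.arg(method)
  y <- to_binary(labels)
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    abort("need at least 2 samples per class", class = "mirpanel_stats_error")
  }
  point <- mw_auc(scores, y)
  if (method == "delong") {
    ci <- tryCatch({
      r <- pROC::roc(response = y, predictor = scores, direction = "<",
                     quiet = TRUE)
      suppressWarnings(as.numeric(pROC::ci.auc(r, conf.level = conf,
                                               method = "delong")))
    }, error = function(e) NULL)
    if (!is.null(ci) && all(is.finite(ci))) {
      return(tibble(auc = point,
                    conf_low = max(0, ci[1]), conf_high = min(1, ci[3]),
                    method = "delong"))
    }
    rlang::inform("DeLong variance degenerate; falling back to bootstrap")
    method <- "bootstrap"
  }
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- c(sample(idx1, replace = TRUE), sample(idx0, replace = TRUE))
      mw_auc(scores[i], y[i])
    }, numeric(1))
  })
  q <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  tibble(auc = point, conf_low = max(0, q[1]), conf_high = min(1, q[2]),
         method = "bootstrap")
}

#' Maximum-accuracy score cutoff
#'
#' Scans thresholds at midpoints between adjacent distinct scores (plus one
#' below and one above the score range) under the rule
#' score >= cutoff => cancer, and returns the cutoff maximizing
#' (TP + TN) / N. Accuracy ties resolve toward higher specificity (and then
#' toward the higher cutoff).
#'
#' @inheritParams roc_points
#' @return Tibble (`cutoff`, `accuracy`, `sensitivity`, `specificity`).
#' @export
max_accuracy_cutoff <- function(scores, labels) {
  y <- to_binary(labels)
  if (!any(y == 1) || !any(y == 0)) {
    abort("both classes must be present", class = "mirpanel_stats_error")
  }
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (head(u, -1) + u[-1]) / 2,
            u[length(u)] + 1)
  stats <- purrr::map_dfr(cand, function(cut) {
    pred <- as.integer(scores >= cut)
    tibble(
      cutoff = cut,
      accuracy = mean(pred == y),
      sensitivity = sum(pred == 1 & y == 1) / sum(y == 1),
      specificity = sum(pred == 0 & y == 0) / sum(y == 0)
    )
  })
  stats |>
    arrange(desc(.data$accuracy), desc(.data$specificity),
            desc(.data$cutoff)) |>
    dplyr::slice(1)
}

#' Wilson score interval for a proportion
#'
#' @param successes,n Counts.
#' @param conf Confidence level.
#' @return Tibble (`estimate`, `conf_low`, `conf_high`).
#' @export
proportion_ci <- function(successes, n, conf = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble(estimate = p,
         conf_low = max(0, centre - half),
         conf_high = min(1, centre + half))
}

#' Evaluate a frozen panel model on a cohort
#'
#' Applies the model to a held-out cohort: global AUC with DeLong CI,
#' maximum-accuracy operating point with Wilson CIs on accuracy /
#' sensitivity / specificity, per-source AUC (each source's cases vs its own
#' controls), per-stage AUC (each stage's cases vs all cohort controls) with
#' score summaries, and the early (stages 0-II) vs late (III-IV) composite
#' strata.
#'
#' @param model A `panel_model`.
#' @param expr Wide normalized expression tibble.
#' @param samples Sample table (`sample_id`, `cohort`, `source_id`, `class`,
#'   `stage`).
#' @param cohort Cohort to evaluate (default `"validation2"`); `NULL` uses
#'   every sample present in `expr`.
#' @param min_stratum_cases Strata with fewer cases are skipped.
#' @return A `panel_evaluation` list: `cohort`, `n`, `auc`,
#'   `operating_point`, `by_source`, `by_stage`, `scores`.
#' @export
evaluate_panel <- function(model, expr, samples, cohort = "validation2",
                           min_stratum_cases = 2) {
  if (!is.null(cohort)) {
    samples <- samples |> filter(.data$cohort %in% !!cohort)
  }
  m <- as_expression_matrix(expr)
  samples <- samples |> filter(.data$sample_id %in% rownames(m))
  scores <- score_samples(expression_tibble(
    m[samples$sample_id, , drop = FALSE]), model, samples)
  y <- class_vector(samples, scores$sample_id)

  auc_tab <- auc_ci(scores$score, y, method = "delong")
  op <- max_accuracy_cutoff(scores$score, y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  op_ci <- bind_rows(
    proportion_ci(round(op$accuracy * length(y)), length(y)) |>
      mutate(metric = "accuracy"),
    proportion_ci(round(op$sensitivity * n1), n1) |> mutate(metric = "sensitivity"),
    proportion_ci(round(op$specificity * n0), n0) |> mutate(metric = "specificity")
  ) |> select("metric", "estimate", "conf_low", "conf_high")

  by_source <- scores |>
    mutate(y = y) |>
    group_by(.data$source_id) |>
    summarise(n_cases = sum(.data$y == 1), n_controls = sum(.data$y == 0),
              auc = if (sum(.data$y == 1) >= min_stratum_cases &&
                        sum(.data$y == 0) >= 2)
                mw_auc(.data$score, .data$y) else NA_real_,
              .groups = "drop")

  ctrl_scores <- scores$score[y == 0]
  stage_groups <- c(as.list(setNames(stage_levels(), stage_levels())),
                    list(early = c("0", "I", "II"), late = c("III", "IV")))
  by_stage <- purrr::imap_dfr(stage_groups, function(stg, label) {
    case_scores <- scores$score[y == 1 & scores$stage %in% stg]
    n_cases <- length(case_scores)
    tibble(
      stage = label,
      n_cases = n_cases,
      auc = if (n_cases >= min_stratum_cases && length(ctrl_scores) >= 2)
        mw_auc(c(case_scores, ctrl_scores),
               rep(1:0, c(n_cases, length(ctrl_scores)))) else NA_real_,
      score_median = if (n_cases > 0) median(case_scores) else NA_real_,
      score_q1 = if (n_cases > 0) quantile(case_scores, 0.25, names = FALSE)
        else NA_real_,
      score_q3 = if (n_cases > 0) quantile(case_scores, 0.75, names = FALSE)
        else NA_real_
    )
  })
  by_stage <- bind_rows(
    tibble(stage = "non_cancer", n_cases = n0, auc = NA_real_,
           score_median = median(ctrl_scores),
           score_q1 = quantile(ctrl_scores, 0.25, names = FALSE),
           score_q3 = quantile(ctrl_scores, 0.75, names = FALSE)),
    by_stage
  )

  structure(list(
    cohort = cohort %||% "all",
    n = length(y),
    auc = auc_tab,
    operating_point = bind_cols(op, tibble(ci = list(op_ci))),
    operating_point_ci = op_ci,
    by_source = by_source,
    by_stage = by_stage,
    scores = scores
  ), class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat("Panel evaluation - cohort:", x$cohort, "(n =", x$n, ")\n")
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f, %s)\n", x$auc$auc,
              x$auc$conf_low, x$auc$conf_high, x$auc$method))
  cat(sprintf("  max-accuracy cutoff %.3f: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              x$operating_point$cutoff, 100 * x$operating_point$accuracy,
              100 * x$operating_point$sensitivity,
              100 * x$operating_point$specificity))
  cat("  per-source AUC:",
      paste(sprintf("%s=%.3f", x$by_source$source_id, x$by_source$auc),
            collapse = ", "), "\n")
  invisible(x)
}
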