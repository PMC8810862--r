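# Per-miRNA differential statistics and candidate filtering across
# discovery and validation cohorts.

#' Per-miRNA differential statistics
#'
#' For each miRNA: log2 fold change (mean log2 cancer minus mean log2
#' control), two-sided pooled-variance Student's t-test on log2 values
#' (Welch optional), Benjamini-Hochberg q-values across all assayed miRNAs,
#' and the Mann-Whitney AUC (probability that a random cancer value exceeds
#' a random control value, ties counting 1/2).
#'
#' @param expr Wide expression tibble (positive values; normalized
#'   copies/ml).
#' @param samples Sample table with `sample_id` and `class`
#'   (cancer/non_cancer); only samples present in `expr` are used.
#' @param var_equal Pooled-variance t-test (`TRUE`, default) or Welch.
#' @return A `marker_stats` tibble: `mirna_id`, `log2fc`, `t_stat`,
#'   `p_value`, `q_value`, `auc`, `n_cancer`, `n_control`.
#' @export
marker_stats <- function(expr, samples, var_equal = TRUE) {
  m <- as_expression_matrix(expr)
  y <- class_vector(samples, rownames(m))
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    abort("each class needs at least 2 samples",
          class = "mirpanel_stats_error")
  }
  l <- log2(m)
  lc <- l[y == 1, , drop = FALSE]
  ln <- l[y == 0, , drop = FALSE]
  res <- purrr::map_dfr(seq_len(ncol(l)), function(j) {
    tt <- t.test(lc[, j], ln[, j], var.equal = var_equal)
    tibble(
      mirna_id = colnames(l)[j],
      log2fc = mean(lc[, j]) - mean(ln[, j]),
      t_stat = unname(tt$statistic),
      p_value = tt$p.value,
      auc = mw_auc(l[, j], y)
    )
  })
  res <- res |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH"),
           n_cancer = sum(y == 1), n_control = sum(y == 0)) |>
    select("mirna_id", "log2fc", "t_stat", "p_value", "q_value", "auc",
           "n_cancer", "n_control")
  class(res) <- c("marker_stats", class(res))
  res
}

#' Select discovery-phase candidate markers
#'
#' Keeps miRNAs with `p < p_thresh`, `|log2FC| > lfc_thresh` (both strict)
#' and directional AUC above `auc_thresh`. The directional AUC orients each
#' marker by the sign of its fold change (AUC for up-regulated markers,
#' 1 - AUC for down-regulated ones), so the filter removes markers whose
#' rank separation contradicts their fold change.
#'
#' @param stats A `marker_stats` tibble for the discovery cohort.
#' @param p_thresh,lfc_thresh,auc_thresh Selection thresholds (defaults
#'   0.01, 0.5, 0.5).
#' @param use_q Apply `p_thresh` to BH q-values instead of raw p-values.
#' @return The passing subset of `stats` (with a `directional_auc` column).
#' @export
select_candidates <- function(stats, p_thresh = 0.01, lfc_thresh = 0.5,
                              auc_thresh = 0.5, use_q = FALSE) {
  p <- if (use_q) stats$q_value else stats$p_value
  stats |>
    mutate(directional_auc = ifelse(.data$log2fc > 0, .data$auc,
                                    1 - .data$auc)) |>
    filter(p < p_thresh,
           abs(.data$log2fc) > lfc_thresh,
           .data$directional_auc > auc_thresh)
}

#' Confirm candidates in a validation cohort
#'
#' A discovery candidate is validated when its validation-cohort statistics
#' satisfy the relaxed cut-off (`p < p_thresh`, `|log2FC| > lfc_thresh`) and
#' its fold-change direction agrees with discovery. Others are excluded with
#' a reason (`sign_flip`, `not_significant`, `small_fold_change`).
#'
#' @param stats_validation `marker_stats` for the validation cohort.
#' @param discovery_pass Discovery candidates: a `marker_stats` subset (from
#'   [select_candidates()]) carrying `mirna_id` and `log2fc`.
#' @param p_thresh,lfc_thresh Relaxed thresholds (defaults 0.05, 0.5).
#' @return Tibble (`mirna_id`, `status`, `reason`, validation `log2fc` and
#'   `p_value`).
#' @export
validate_candidates <- function(stats_validation, discovery_pass,
                                p_thresh = 0.05, lfc_thresh = 0.5) {
  if (nrow(discovery_pass) == 0) {
    abort("discovery candidate set is empty", class = "mirpanel_stats_error")
  }
  discovery_pass |>
    select("mirna_id", discovery_log2fc = "log2fc") |>
    left_join(stats_validation |>
                select("mirna_id", "log2fc", "p_value"),
              by = "mirna_id") |>
    mutate(
      reason = dplyr::case_when(
        is.na(.data$log2fc) ~ "missing_in_validation",
        sign(.data$log2fc) != sign(.data$discovery_log2fc) ~ "sign_flip",
        .data$p_value >= p_thresh ~ "not_significant",
        abs(.data$log2fc) <= lfc_thresh ~ "small_fold_change",
        TRUE ~ NA_character_
      ),
      status = ifelse(is.na(.data$reason), "validated", "excluded")
    ) |>
    select("mirna_id", "status", "reason", "log2fc", "p_value")
}

#' Cross-cohort fold-change correlation
#'
#' Pearson correlation of log2 fold changes over a shared marker set.
#'
#' @param stats_a,stats_b `marker_stats` tibbles for the two cohorts.
#' @param mirnas Markers to correlate (default: all shared markers).
#' @return One-row tibble (`r`, `p_value`, `n`).
#' @export
fold_change_correlation <- function(stats_a, stats_b, mirnas = NULL) {
  joined <- inner_join(
    stats_a |> select("mirna_id", a = "log2fc"),
    stats_b |> select("mirna_id", b = "log2fc"),
    by = "mirna_id"
  )
  if (!is.null(mirnas)) joined <- joined |> filter(.data$mirna_id %in% mirnas)
  if (nrow(joined) < 3) {
    abort("need at least 3 shared miRNAs", class = "mirpanel_stats_error")
  }
  if (sd(joined$a) == 0 || sd(joined$b) == 0) {
    abort("fold-change correlation undefined: zero variance",
          class = "mirpanel_stats_error")
  }
  ct <- cor.test(joined$a, joined$b, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(joined))
}

#' Two-dimensional hierarchical clustering of expression
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of samples
#' and miRNAs on log2 expression standardised per miRNA to zero mean.
#'
#' @param expr Wide expression tibble of positive values.
#' @param mirnas Optional marker subset to cluster on.
#' @return An `expr_clustering` list: `sample_order`, `mirna_order` (leaf
#'   id orders), `sample_tree`, `mirna_tree` (hclust objects), and the
#'   standardized matrix `z`.
#' @export
hierarchical_cluster <- function(expr, mirnas = NULL) {
  m <- as_expression_matrix(expr)
  if (!is.null(mirnas)) m <- m[, colnames(m) %in% mirnas, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("need at least 2 samples and 2 miRNAs",
          class = "mirpanel_stats_error")
  }
  if (anyNA(m) || any(m <= 0)) {
    abort("clustering input must be complete and positive (floor upstream)",
          class = "mirpanel_stats_error")
  }
  z <- scale(log2(m), center = TRUE, scale = FALSE)
  sample_tree <- hclust(dist(z, method = "euclidean"), method = "average")
  mirna_tree <- hclust(dist(t(z), method = "euclidean"), method = "average")
  structure(list(
    sample_order = rownames(z)[sample_tree$order],
    mirna_order = colnames(z)[mirna_tree$order],
    sample_tree = sample_tree,
    mirna_tree = mirna_tree,
    z = z
  ), class = "expr_clustering")
}
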