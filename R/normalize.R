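# Reference-miRNA stability and normalization.
#
# Stability is assessed on log2 copies/ml across all samples of the
# discovery cohort (cases and controls pooled); class labels enter only the
# NormFinder decomposition.

#' geNORM stability measure M
#'
#' For candidate \eqn{j}, \eqn{M_j} is the mean over all other candidates
#' \eqn{k} of the standard deviation across samples of
#' \eqn{\log_2(x_j / x_k)}. Lower M = more stable. Computed from the
#' candidate covariance matrix:
#' \eqn{SD^2(l_j - l_k) = v_j + v_k - 2 c_{jk}}.
#'
#' @param log_expr Samples x candidates matrix of log2 expression (or a wide
#'   expression tibble of positive values, which is log2-transformed).
#' @return Tibble (`mirna_id`, `genorm_m`), input column order.
#' @export
genorm_m <- function(log_expr) {
  l <- stability_input(log_expr)
  if (ncol(l) < 2) {
    abort("geNORM needs at least 2 candidate miRNAs",
          class = "mirpanel_stability_error")
  }
  if (nrow(l) < 2) {
    abort("geNORM needs at least 2 samples",
          class = "mirpanel_stability_error")
  }
  v <- stats::cov(l)
  d <- outer(diag(v), diag(v), `+`) - 2 * v
  d[d < 0] <- 0    # numerical guard
  sd_pair <- sqrt(d)
  m <- rowSums(sd_pair) / (ncol(l) - 1)
  tibble(mirna_id = colnames(l), genorm_m = unname(m))
}

#' geNORM iterative ranking and pairwise variation
#'
#' Repeatedly removes the least stable candidate (highest M, ties broken by
#' excluding the lexicographically last id) and recomputes M on the
#' remainder, until two candidates are left; those two share rank 1. Also
#' reports the pairwise variation \eqn{V_{n,n+1}}: the SD across samples of
#' the difference between the log2 geometric means of the top-n and
#' top-(n+1) stability sets.
#'
#' @inheritParams genorm_m
#' @return List with `ranking` (tibble `mirna_id`, `genorm_rank`,
#'   `m_at_exclusion`) and `pairwise_variation` (tibble `n`, `v`).
#' @export
genorm_rank <- function(log_expr) {
  l <- stability_input(log_expr)
  p <- ncol(l)
  if (p < 3) {
    abort("geNORM ranking needs at least 3 candidates",
          class = "mirpanel_stability_error")
  }
  v <- stats::cov(l)
  ids <- colnames(l)
  active <- ids
  exclusion <- character(0)
  m_excl <- numeric(0)
  while (length(active) > 2) {
    vv <- v[active, active]
    d <- outer(diag(vv), diag(vv), `+`) - 2 * vv
    d[d < 0] <- 0
    m <- rowSums(sqrt(d)) / (length(active) - 1)
    worst <- active[m >= max(m) - 1e-15]
    worst <- worst[order(worst, decreasing = TRUE)][1]
    exclusion <- c(exclusion, worst)
    m_excl <- c(m_excl, m[match(worst, active)])
    active <- setdiff(active, worst)
  }
  # stability order: the two survivors (rank 1), then reverse exclusion order
  order_ids <- c(sort(active), rev(exclusion))
  rank <- c(1L, 1L, seq_len(length(exclusion)) + 1L)
  ranking <- tibble(
    mirna_id = order_ids,
    genorm_rank = rank,
    m_at_exclusion = c(NA_real_, NA_real_, rev(m_excl))
  ) |>
    arrange(match(.data$mirna_id, ids))

  stab_order <- order_ids
  pv <- purrr::map_dfr(2:(p - 1), function(n) {
    top_n <- stab_order[seq_len(n)]
    top_n1 <- stab_order[seq_len(n + 1)]
    diff_log <- rowMeans(l[, top_n, drop = FALSE]) -
      rowMeans(l[, top_n1, drop = FALSE])
    tibble(n = n, v = sd(diff_log))
  })
  list(ranking = ranking, pairwise_variation = pv)
}

#' NormFinder-style stability
#'
#' Model-based stability: each sample is centred across candidates (removing
#' the sample effect); for candidate \eqn{g} and group \eqn{i} the group mean
#' \eqn{v_{gi}} and within-group variance \eqn{w_{gi}} are computed; the
#' intergroup deviation is \eqn{d_{gi} = v_{gi} - \bar v_{g\cdot}} and the
#' stability value is
#' \eqn{\rho_g = \mathrm{mean}_i(|d_{gi}| + \sqrt{w_{gi}/n_i})}.
#' Lower is more stable. This is a simplified estimator of the original
#' model-based decomposition; it preserves the stability ranking behaviour.
#'
#' @inheritParams genorm_m
#' @param groups Group label per sample (e.g. cancer / non_cancer).
#' @return Tibble (`mirna_id`, `normfinder_rho`).
#' @export
normfinder_stability <- function(log_expr, groups) {
  l <- stability_input(log_expr)
  groups <- as.character(groups)
  if (length(groups) != nrow(l)) {
    abort("groups must have one label per sample",
          class = "mirpanel_stability_error")
  }
  tab <- table(groups)
  if (any(tab < 2)) {
    abort("each group needs at least 2 samples for NormFinder",
          class = "mirpanel_stability_error")
  }
  centred <- l - rowMeans(l)
  glev <- names(tab)
  v_gi <- vapply(glev, function(g) colMeans(centred[groups == g, , drop = FALSE]),
                 numeric(ncol(l)))
  w_gi <- vapply(glev, function(g) {
    apply(centred[groups == g, , drop = FALSE], 2, var)
  }, numeric(ncol(l)))
  n_i <- as.numeric(tab[glev])
  d_gi <- v_gi - rowMeans(v_gi)
  rho <- rowMeans(abs(d_gi) + sqrt(sweep(w_gi, 2, n_i, `/`)))
  tibble(mirna_id = colnames(l), normfinder_rho = unname(rho))
}

#' Combined reference-stability table
#'
#' Runs geNORM (M and iterative rank) and NormFinder over a candidate pool.
#' By default the pool is every miRNA whose value is non-floored in at least
#' `min_detected` of samples (flags from [absolute_quantify()]); without
#' flags all miRNAs are candidates.
#'
#' @param expr Wide expression tibble (copies/ml) or a
#'   `quantified_expression` object.
#' @param samples Sample table supplying class labels (and, through
#'   `cohort_filter`, the cohort restriction).
#' @param cohort Cohort(s) whose samples enter the stability computation
#'   (default `"discovery"`); `NULL` = all samples in `expr`.
#' @param min_detected Minimum fraction of samples in which a candidate must
#'   be detected (non-floored).
#' @return Tibble (`mirna_id`, `genorm_m`, `genorm_rank`, `normfinder_rho`,
#'   `normfinder_rank`).
#' @export
reference_stability <- function(expr, samples, cohort = "discovery",
                                min_detected = 0.9) {
  flags <- NULL
  if (inherits(expr, "quantified_expression")) {
    flags <- expr$flags
    expr <- expr$expression
  }
  m <- as_expression_matrix(expr)
  if (!is.null(cohort)) {
    keep <- samples$sample_id[samples$cohort %in% cohort]
    m <- m[rownames(m) %in% keep, , drop = FALSE]
  }
  if (!is.null(flags)) {
    det <- flags |>
      filter(.data$sample_id %in% rownames(m)) |>
      group_by(.data$mirna_id) |>
      summarise(frac = mean(!grepl("floored", .data$flag)), .groups = "drop")
    pool <- det$mirna_id[det$frac >= min_detected]
    m <- m[, colnames(m) %in% pool, drop = FALSE]
  }
  l <- log2(m)
  groups <- samples$class[match(rownames(m), samples$sample_id)]
  gn <- genorm_m(l)
  gr <- genorm_rank(l)$ranking
  nf <- normfinder_stability(l, groups)
  gn |>
    left_join(gr |> select("mirna_id", "genorm_rank"), by = "mirna_id") |>
    left_join(nf, by = "mirna_id") |>
    mutate(normfinder_rank = rank_with_lex_ties(.data$normfinder_rho,
                                                .data$mirna_id))
}

# Integer competition-free ranking with lexicographic tie-breaking.
rank_with_lex_ties <- function(value, id) {
  order(order(value, id))
}

#' Select endogenous reference miRNAs
#'
#' Consensus rule: candidates are ordered by the sum of their geNORM rank and
#' NormFinder rank; the top `k` are returned (ties broken by lexicographic
#' id). `method = "genorm"` or `"normfinder"` rank by a single measure.
#'
#' @param stability Stability table from [reference_stability()].
#' @param k Number of references to select.
#' @param method `"consensus"` (default), `"genorm"`, or `"normfinder"`.
#' @return A `reference_set`: list with `mirna_ids` and `selection_method`.
#' @export
select_references <- function(stability, k = 3,
                              method = c("consensus", "genorm",
                                         "normfinder")) {
  method <- match.arg(method)
  if (k < 1) abort("k must be >= 1", class = "mirpanel_config_error")
  if (k > nrow(stability)) {
    abort("k exceeds the number of candidate miRNAs",
          class = "mirpanel_config_error")
  }
  key <- switch(method,
    consensus = stability$genorm_rank + stability$normfinder_rank,
    genorm = stability$genorm_rank,
    normfinder = stability$normfinder_rank
  )
  ids <- stability$mirna_id[order(key, stability$mirna_id)][seq_len(k)]
  structure(list(mirna_ids = ids, selection_method = method),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference miRNA set (", x$selection_method, "): ",
      paste(x$mirna_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Normalize expression by the geometric mean of reference miRNAs
#'
#' Divides every value in a sample by the geometric mean of that sample's
#' reference-miRNA values (equivalently, subtracts the mean reference log2
#' from each log2 value). Reference columns are retained. Samples with a
#' missing or non-positive reference value are dropped (recorded in the
#' `excluded_samples` attribute).
#'
#' @param expr Wide expression tibble (copies/ml) or matrix.
#' @param refs A `reference_set` or character vector of miRNA ids.
#' @return Wide tibble of normalized expression (unitless, scaled to the
#'   reference geometric mean), with attribute `excluded_samples`.
#' @export
normalize_expression <- function(expr, refs) {
  if (inherits(expr, "quantified_expression")) expr <- expr$expression
  if (inherits(refs, "reference_set")) refs <- refs$mirna_ids
  m <- as_expression_matrix(expr)
  missing_refs <- setdiff(refs, colnames(m))
  if (length(missing_refs) > 0) {
    abort(paste0("reference miRNA(s) absent from the matrix: ",
                 paste(missing_refs, collapse = ", ")),
          class = "mirpanel_config_error")
  }
  ref_vals <- m[, refs, drop = FALSE]
  bad <- !apply(is.finite(ref_vals) & ref_vals > 0, 1, all)
  if (any(bad)) {
    rlang::inform(paste0(sum(bad),
                         " sample(s) excluded: non-positive reference value"))
  }
  m <- m[!bad, , drop = FALSE]
  gm <- exp(rowMeans(log(m[, refs, drop = FALSE])))
  out <- expression_tibble(m / gm)
  attr(out, "excluded_samples") <- rownames(ref_vals)[bad] %||% character(0)
  attr(out, "reference_mirnas") <- refs
  out
}

# Accept a matrix of log2 values or a wide tibble of positive values.
stability_input <- function(log_expr) {
  if (is.matrix(log_expr)) {
    l <- log_expr
    if (is.null(colnames(l))) {
      colnames(l) <- sprintf("candidate%03d", seq_len(ncol(l)))
    }
  } else {
    m <- as_expression_matrix(log_expr)
    if (any(m <= 0, na.rm = TRUE)) {
      abort("expression values must be positive to take log2",
            class = "mirpanel_stability_error")
    }
    l <- log2(m)
  }
  if (anyNA(l)) {
    abort("stability input must be complete (use floored values upstream)",
          class = "mirpanel_stability_error")
  }
  l
}
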