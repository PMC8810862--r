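# Repeated source-stratified two-fold cross-validation of SFFS panels.

#' Source- and class-stratified two-group partition
#'
#' Randomly splits samples into two equal groups A and B such that, within
#' every source and every source x class cell, the group counts differ by at
#' most one. Within each cell the ids are shuffled and split; when a cell is
#' odd its extra sample alternates between A and B across the cells of the
#' source, which keeps the per-source counts balanced too.
#'
#' @param samples Sample table (`sample_id`, `source_id`, `class`).
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as inside [crossvalidate_panels()]).
#' @return Tibble (`sample_id`, `group`) with `group` in `"A"`/`"B"`.
#' @export
stratified_partition <- function(samples, seed = NULL) {
  run <- function() {
    out <- vector("list", 0)
    flip <- TRUE   # odd-cell extras alternate globally: groups stay equal
    for (src in sort(unique(samples$source_id))) {
      for (cls in sort(unique(samples$class))) {
        ids <- samples$sample_id[samples$source_id == src &
                                   samples$class == cls]
        n <- length(ids)
        if (n == 0) next
        if (n == 1) {
          warn(paste0("stratification cell ", src, "/", cls,
                      " has a single sample; assigned at random"),
               .frequency = "once", .frequency_id = "mirpanel_strat")
        }
        ids <- sample(ids)
        n_a <- if (n %% 2 == 0) n / 2 else (n - 1) / 2 + as.integer(flip)
        if (n %% 2 == 1) flip <- !flip
        out[[length(out) + 1]] <- tibble(
          sample_id = ids,
          group = rep(c("A", "B"), c(n_a, n - n_a))
        )
      }
    }
    bind_rows(out) |> arrange(.data$sample_id)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Cross-validate SFFS panels over repeated two-fold splits
#'
#' Per iteration: the samples are partitioned into groups A and B (stratified
#' by source and class); SFFS selects the best panel of every size on the
#' training group; each panel is refit on the training group and its AUC is
#' evaluated on the held-out group; then the group roles are swapped. Two
#' records per size per iteration.
#'
#' @param expr Wide normalized expression tibble (positive values) covering
#'   the training cohorts only.
#' @param samples Sample table restricted to the same cohorts.
#' @param pool Candidate miRNA ids (the validated markers).
#' @param n_iter Number of cross-validation iterations (default 200).
#' @param sizes Panel sizes to report (default 2:12; SFFS searches up to
#'   `max(sizes)`).
#' @param seed Master seed; per-iteration substreams derive from it.
#' @param lambda Ridge penalty for the logistic refits.
#' @return A `panel_cv` tibble: `iteration`, `fold` (`A_train`/`B_train`),
#'   `panel_size`, `panel` (list column, selection order), `panel_key`
#'   (sorted ids collapsed with `+`), `train_auc`, `test_auc`.
#' @export
crossvalidate_panels <- function(expr, samples, pool, n_iter = 200,
                                 sizes = 2:12, seed = 1, lambda = 1e-6) {
  m <- as_expression_matrix(expr)
  missing_pool <- setdiff(pool, colnames(m))
  if (length(missing_pool) > 0) {
    abort(paste0("pool miRNA(s) absent from expression: ",
                 paste(missing_pool, collapse = ", ")),
          class = "mirpanel_config_error")
  }
  max_size <- max(sizes)
  if (length(pool) < max_size) {
    abort("candidate pool smaller than the largest panel size",
          class = "mirpanel_config_error")
  }
  l <- log2(m[, pool, drop = FALSE])
  samples <- samples |> filter(.data$sample_id %in% rownames(l))
  y_all <- setNames(class_vector(samples, samples$sample_id),
                    samples$sample_id)

  records <- purrr::map_dfr(seq_len(n_iter), function(it) {
    with_substream(seed, 1000L + it, {
      part <- stratified_partition(samples)
      ids_a <- part$sample_id[part$group == "A"]
      ids_b <- part$sample_id[part$group == "B"]
      purrr::map_dfr(
        list(c("A_train", "a", "b"), c("B_train", "b", "a")),
        function(spec_fold) {
          tr_ids <- if (spec_fold[2] == "a") ids_a else ids_b
          te_ids <- if (spec_fold[3] == "a") ids_a else ids_b
          cv_fold_records(l, y_all, tr_ids, te_ids, sizes, max_size,
                          lambda) |>
            mutate(iteration = it, fold = spec_fold[1], .before = 1)
        })
    })
  })
  class(records) <- c("panel_cv", class(records))
  records
}

# SFFS on the training ids, evaluated on the test ids; one row per size.
cv_fold_records <- function(l, y_all, tr_ids, te_ids, sizes, max_size,
                            lambda) {
  xtr <- l[tr_ids, , drop = FALSE]
  ytr <- unname(y_all[tr_ids])
  xte <- l[te_ids, , drop = FALSE]
  yte <- unname(y_all[te_ids])
  ctr <- colMeans(xtr)
  sdev <- apply(xtr, 2, sd)
  sdev[sdev == 0] <- 1
  xtr_s <- sweep(sweep(xtr, 2, ctr), 2, sdev, `/`)
  xte_s <- sweep(sweep(xte, 2, ctr), 2, sdev, `/`)

  res <- sffs_core(xtr_s, ytr, max_size, lambda)
  purrr::map_dfr(sizes, function(s) {
    idx <- res$best_idx[[s]]
    fit <- .ridge_logit_cpp(xtr_s[, idx, drop = FALSE], ytr, lambda,
                            200L, 1e-10)
    beta <- fit$coef[-1]
    b0 <- fit$coef[1]
    tr_score <- b0 + drop(xtr_s[, idx, drop = FALSE] %*% beta)
    te_score <- b0 + drop(xte_s[, idx, drop = FALSE] %*% beta)
    panel_ids <- colnames(l)[idx]
    tibble(
      panel_size = s,
      panel = list(panel_ids),
      panel_key = paste(sort(panel_ids), collapse = "+"),
      train_auc = .mw_auc_cpp(tr_score, ytr),
      test_auc = .mw_auc_cpp(te_score, yte)
    )
  })
}

#' Optimal panel size by AUC plateau testing
#'
#' Walking up from the smallest size, compares the held-out AUC
#' distributions at consecutive sizes with a two-sided t-test. The optimal
#' size is the smallest `s` whose increase to `s + 1` is not significant at
#' `alpha` (a significant decrease also ends the climb); when every step is
#' significant the largest size is returned.
#'
#' @param cv A `panel_cv` record table.
#' @param alpha Significance level of the plateau test (default 0.001).
#' @return A list: `size`, and `steps` (tibble `from`, `to`, `p_value`,
#'   `median_from`, `median_to`).
#' @export
optimal_size <- function(cv, alpha = 0.001) {
  sizes <- sort(unique(cv$panel_size))
  if (length(sizes) < 2) {
    abort("need at least 2 panel sizes", class = "mirpanel_stats_error")
  }
  auc_by <- split(cv$test_auc, cv$panel_size)
  if (any(lengths(auc_by) < 2)) {
    abort("need at least 2 records per size", class = "mirpanel_stats_error")
  }
  steps <- purrr::map_dfr(seq_len(length(sizes) - 1), function(i) {
    a <- auc_by[[as.character(sizes[i])]]
    b <- auc_by[[as.character(sizes[i + 1])]]
    p <- if (sd(a) == 0 && sd(b) == 0) {
      if (mean(b) == mean(a)) 1 else 0
    } else {
      t.test(b, a)$p.value
    }
    tibble(from = sizes[i], to = sizes[i + 1], p_value = p,
           mean_from = mean(a), mean_to = mean(b),
           median_from = median(a), median_to = median(b))
  })
  sig_increase <- steps$p_value < alpha & steps$mean_to > steps$mean_from
  size <- if (all(sig_increase)) max(sizes) else steps$from[which(!sig_increase)[1]]
  list(size = size, steps = steps)
}

#' Choose and refit the final panel
#'
#' Among the distinct panels of the chosen size seen across all
#' cross-validation records, each is refit on the discovery cohort and
#' scored on the discovery and validation 1 cohorts; panels are ranked by
#' the mean of the two AUCs (ties by lexicographic panel key) and the winner
#' is refit on the combined discovery + validation 1 samples.
#'
#' @param cv A `panel_cv` record table.
#' @param size Panel size to select (e.g. from [optimal_size()]).
#' @param expr Wide normalized expression covering discovery and
#'   validation 1.
#' @param samples Sample table with `cohort` labels.
#' @param lambda Ridge penalty.
#' @return A list: `model` (the refit `panel_model`), `candidates` (tibble
#'   `panel_key`, `auc_discovery`, `auc_validation1`, `mean_auc`,
#'   `n_iterations`).
#' @export
select_final_panel <- function(cv, size, expr, samples, lambda = 1e-6) {
  cands <- cv |>
    filter(.data$panel_size == size) |>
    group_by(.data$panel_key) |>
    summarise(n_iterations = dplyr::n(),
              panel = .data$panel[1], .groups = "drop")
  if (nrow(cands) == 0) {
    abort("no cross-validation panel of the requested size",
          class = "mirpanel_stats_error")
  }
  m <- as_expression_matrix(expr)
  disc_ids <- samples$sample_id[samples$cohort == "discovery"]
  val1_ids <- samples$sample_id[samples$cohort == "validation1"]
  disc_ids <- intersect(disc_ids, rownames(m))
  val1_ids <- intersect(val1_ids, rownames(m))
  y <- setNames(class_vector(samples, samples$sample_id), samples$sample_id)

  scored <- purrr::pmap_dfr(cands, function(panel_key, n_iterations, panel) {
    fit <- fit_logistic(log2(m[disc_ids, panel, drop = FALSE]),
                        unname(y[disc_ids]), lambda = lambda)
    sc_d <- predict(fit, log2(m[disc_ids, panel, drop = FALSE]))
    sc_v <- predict(fit, log2(m[val1_ids, panel, drop = FALSE]))
    tibble(panel_key = panel_key, n_iterations = n_iterations,
           panel = list(panel),
           auc_discovery = mw_auc(sc_d, y[disc_ids]),
           auc_validation1 = mw_auc(sc_v, y[val1_ids]))
  }) |>
    mutate(mean_auc = (.data$auc_discovery + .data$auc_validation1) / 2) |>
    arrange(desc(.data$mean_auc), .data$panel_key)

  winner <- scored$panel[[1]]
  comb_ids <- c(disc_ids, val1_ids)
  model <- fit_logistic(log2(m[comb_ids, winner, drop = FALSE]),
                        unname(y[comb_ids]), lambda = lambda)
  list(model = model, candidates = scored |> select(-"panel"))
}
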