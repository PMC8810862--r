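# End-to-end orchestration: simulate -> quantify -> normalize -> diffexpr ->
# panel -> evaluate, with cohort isolation (validation 2 is never visible
# before the final evaluation stage) and bitwise-reproducible outputs.

#' Configure a full pipeline run
#'
#' All stage parameters in one list. Defaults mirror the study design the
#' workflow targets: 324 miRNAs, discovery selection at p < 0.01 and
#' |log2FC| > 0.5 with directional AUC > 0.5, relaxed validation cut-off
#' p < 0.05, 3 reference miRNAs, panel sizes 2-12 over 200 cross-validation
#' iterations, plateau alpha 0.001.
#'
#' @param simulate A [sim_config()] (or `NULL` when reading Ct tables from
#'   files via `inputs`).
#' @param inputs Named list of file paths (`ct`, `spikes`, `curves`,
#'   `samples`) used when `simulate` is `NULL`; tab-delimited with the
#'   schemas written by [write_ct_dataset()].
#' @param k_references Number of endogenous references to select.
#' @param p_thresh,lfc_thresh,auc_thresh Discovery selection thresholds.
#' @param use_q Apply the discovery p threshold to BH q-values.
#' @param val_p_thresh,val_lfc_thresh Validation confirmation thresholds.
#' @param n_iter,sizes,alpha Cross-validation iterations, panel sizes, and
#'   plateau significance level.
#' @param panel_cohorts Cohorts the panel stage may see; including
#'   `"validation2"` is refused at run time (cohort-isolation guard).
#' @param eval_cohort Held-out cohort for the final evaluation.
#' @param lambda Ridge penalty of the logistic fits.
#' @param seed Master seed for every stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = sim_config(seed = seed),
                            inputs = NULL,
                            k_references = 3,
                            p_thresh = 0.01, lfc_thresh = 0.5,
                            auc_thresh = 0.5, use_q = FALSE,
                            val_p_thresh = 0.05, val_lfc_thresh = 0.5,
                            n_iter = 200, sizes = 2:12, alpha = 0.001,
                            panel_cohorts = c("discovery", "validation1"),
                            eval_cohort = "validation2",
                            lambda = 1e-6,
                            seed = 1L) {
  config <- list(simulate = simulate, inputs = inputs,
                 k_references = k_references, p_thresh = p_thresh,
                 lfc_thresh = lfc_thresh, auc_thresh = auc_thresh,
                 use_q = use_q, val_p_thresh = val_p_thresh,
                 val_lfc_thresh = val_lfc_thresh, n_iter = n_iter,
                 sizes = sizes, alpha = alpha,
                 panel_cohorts = panel_cohorts, eval_cohort = eval_cohort,
                 lambda = lambda, seed = as.integer(seed))
  class(config) <- "pipeline_config"
  config
}

#' Run the full biomarker-discovery pipeline
#'
#' Stages: (1) simulate or load the Ct dataset; (2) absolute quantification;
#' (3) reference selection on the discovery cohort and normalization of all
#' cohorts with the frozen references; (4) discovery differential screen and
#' validation 1 confirmation; (5) SFFS panel cross-validation on
#' discovery + validation 1, plateau size selection, final panel refit;
#' (6) evaluation of the frozen model on validation 2, untouched before this
#' stage. Rerunning with the same config and seed reproduces every output
#' file bitwise (no timestamps are written).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return (Invisibly) a list of stage results and artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    abort("config must be a pipeline_config()", class = "mirpanel_config_error")
  }
  if ("validation2" %in% config$panel_cohorts ||
      config$eval_cohort %in% config$panel_cohorts) {
    abort("cohort-isolation violation: the held-out cohort may not enter the panel stage",
          class = "mirpanel_isolation_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  # stage 1: data
  if (!is.null(config$simulate)) {
    say("stage simulate: generating synthetic study (seed ",
        config$simulate$seed, ")")
    study <- simulate_study(config$simulate)
    write_ct_dataset(study, out_dir)
  } else {
    say("stage load: reading Ct tables")
    study <- read_ct_dataset(config$inputs)
  }
  samples <- study$samples

  # stage 2: quantify
  say("stage quantify: fitting standard curves and converting Ct to copies/ml")
  quant <- absolute_quantify(study$ct_data, samples)
  readr::write_tsv(quant$expression, file.path(out_dir, "expression.tsv"))
  readr::write_tsv(quant$flags, file.path(out_dir, "flags.tsv"))
  say("  quantified ", nrow(quant$expression), " samples, excluded ",
      nrow(quant$excluded_samples))

  # stage 3: normalize (references frozen on discovery)
  say("stage normalize: reference stability on the discovery cohort")
  stability <- reference_stability(quant, samples, cohort = "discovery")
  refs <- select_references(stability, k = config$k_references)
  norm_expr <- normalize_expression(quant$expression, refs)
  readr::write_tsv(stability, file.path(out_dir, "stability.tsv"))
  jsonlite::write_json(list(mirna_ids = refs$mirna_ids,
                            selection_method = refs$selection_method),
                       file.path(out_dir, "references.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  readr::write_tsv(norm_expr, file.path(out_dir, "normalized_expression.tsv"))
  say("  references: ", paste(refs$mirna_ids, collapse = ", "))

  # stage 4: differential expression
  say("stage diffexpr: discovery screen and validation 1 confirmation")
  cohort_expr <- function(cohorts) {
    ids <- samples$sample_id[samples$cohort %in% cohorts]
    norm_expr |> filter(.data$sample_id %in% ids)
  }
  stats_disc <- marker_stats(cohort_expr("discovery"), samples)
  stats_val1 <- marker_stats(cohort_expr("validation1"), samples)
  discovery_pass <- select_candidates(stats_disc, config$p_thresh,
                                      config$lfc_thresh, config$auc_thresh,
                                      config$use_q)
  validation <- validate_candidates(stats_val1, discovery_pass,
                                    config$val_p_thresh,
                                    config$val_lfc_thresh)
  validated_ids <- validation$mirna_id[validation$status == "validated"]
  fc_cor <- fold_change_correlation(stats_disc, stats_val1,
                                    discovery_pass$mirna_id)
  clust <- hierarchical_cluster(cohort_expr(c("discovery", "validation1")),
                                discovery_pass$mirna_id)
  readr::write_tsv(stats_disc, file.path(out_dir, "marker_stats_discovery.tsv"))
  readr::write_tsv(stats_val1, file.path(out_dir, "marker_stats_validation1.tsv"))
  jsonlite::write_json(
    list(discovery_pass = discovery_pass$mirna_id,
         validated = validated_ids,
         excluded = validation |> filter(.data$status == "excluded") |>
           select("mirna_id", "reason"),
         fold_change_correlation = fc_cor),
    file.path(out_dir, "candidates.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  jsonlite::write_json(list(sample_order = clust$sample_order,
                            mirna_order = clust$mirna_order),
                       file.path(out_dir, "cluster_orders.json"),
                       pretty = TRUE)
  say("  discovery pass: ", nrow(discovery_pass), ", validated: ",
      length(validated_ids), ", fold-change r = ", round(fc_cor$r, 3))

  # stage 5: panel optimisation (validation2 never enters)
  say("stage panel: ", config$n_iter, " cross-validation iterations, sizes ",
      min(config$sizes), "-", max(config$sizes))
  panel_samples <- samples |> filter(.data$cohort %in% config$panel_cohorts)
  assert_cohort_isolation(panel_samples, samples, config$eval_cohort)
  panel_expr <- norm_expr |>
    filter(.data$sample_id %in% panel_samples$sample_id)
  cv <- crossvalidate_panels(panel_expr, panel_samples, validated_ids,
                             n_iter = config$n_iter, sizes = config$sizes,
                             seed = config$seed, lambda = config$lambda)
  opt <- optimal_size(cv, alpha = config$alpha)
  final <- select_final_panel(cv, opt$size, panel_expr, panel_samples,
                              lambda = config$lambda)
  cv_out <- cv |>
    mutate(panel = purrr::map_chr(.data$panel, paste, collapse = ",")) |>
    select("iteration", "fold", "panel_size", "panel", "train_auc",
           "test_auc")
  readr::write_tsv(cv_out, file.path(out_dir, "cv_records.tsv"))
  jsonlite::write_json(
    list(mirna_ids = final$model$mirna_ids,
         coefficients = as.list(final$model$coefficients),
         intercept = final$model$intercept,
         optimal_size = opt$size,
         plateau_steps = opt$steps,
         seed = config$seed),
    file.path(out_dir, "panel_model.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  say("  optimal size: ", opt$size, "; final panel: ",
      paste(final$model$mirna_ids, collapse = ", "))

  # stage 6: held-out evaluation
  say("stage evaluate: cohort ", config$eval_cohort)
  evaluation <- evaluate_panel(final$model, norm_expr, samples,
                               cohort = config$eval_cohort)
  jsonlite::write_json(
    list(cohort = evaluation$cohort, n = evaluation$n,
         auc = evaluation$auc,
         operating_point = evaluation$operating_point |> select(-"ci"),
         operating_point_ci = evaluation$operating_point_ci,
         by_source = evaluation$by_source,
         by_stage = evaluation$by_stage),
    file.path(out_dir, "eval_report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  readr::write_tsv(evaluation$scores, file.path(out_dir, "scores.tsv"))
  say(sprintf("  held-out AUC %.3f (accuracy %.1f%%)",
              evaluation$auc$auc, 100 * evaluation$operating_point$accuracy))

  manifest <- list(
    package = "mirpanel",
    version = as.character(utils::packageVersion("mirpanel")),
    seed = config$seed,
    parameters = config_for_manifest(config),
    outputs = c("expression.tsv", "flags.tsv", "stability.tsv",
                "references.json", "normalized_expression.tsv",
                "marker_stats_discovery.tsv", "marker_stats_validation1.tsv",
                "candidates.json", "cluster_orders.json", "cv_records.tsv",
                "panel_model.json", "eval_report.json", "scores.tsv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)

  invisible(list(
    samples = samples, quant = quant, stability = stability,
    references = refs, normalized = norm_expr,
    stats_discovery = stats_disc, stats_validation1 = stats_val1,
    discovery_pass = discovery_pass, validation = validation,
    fold_change_correlation = fc_cor, cv = cv, optimal = opt,
    final = final, evaluation = evaluation, out_dir = out_dir
  ))
}

# No held-out sample may reach the panel stage.
assert_cohort_isolation <- function(panel_samples, samples, eval_cohort) {
  held_out <- samples$sample_id[samples$cohort == eval_cohort]
  leaked <- intersect(panel_samples$sample_id, held_out)
  if (length(leaked) > 0) {
    abort(paste0("cohort-isolation violation: ", length(leaked),
                 " held-out sample(s) in the panel stage"),
          class = "mirpanel_isolation_error")
  }
  invisible(TRUE)
}

config_for_manifest <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulate)) {
    sim <- unclass(cfg$simulate)
    sim$cohorts <- as.data.frame(sim$cohorts)
    cfg$simulate <- sim
  }
  cfg
}

#' Read a pipeline config from YAML
#'
#' Scalar stage parameters are read from the top level of the file; a
#' `simulate:` block overrides [sim_config()] fields.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  seed <- seed %||% raw$seed %||% 1L
  sim <- NULL
  if (is.null(raw$inputs)) {
    sim_args <- raw$simulate %||% list()
    if (!is.null(sim_args$cohorts)) {
      sim_args$cohorts <- dplyr::bind_rows(sim_args$cohorts)
    }
    sim_args$seed <- seed
    sim <- do.call(sim_config, sim_args)
  }
  args <- raw[setdiff(names(raw), c("simulate", "seed"))]
  args$simulate <- sim
  args$seed <- seed
  if (!is.null(args$sizes) && is.character(args$sizes)) {
    rng <- as.integer(strsplit(args$sizes, ":")[[1]])
    args$sizes <- seq(rng[1], rng[2])
  }
  do.call(pipeline_config, args)
}
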