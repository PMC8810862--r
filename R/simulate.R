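#' Generate a synthetic multi-centre cohort with ground truth
#'
#' Draws the sample table and the true serum abundance matrix (copies/ml)
#' under a log-normal model: for sample \eqn{i} and miRNA \eqn{m},
#' \deqn{\log_2 c_{im} = b_m + \beta_{s(i),m} + 1[case_i]\,\Delta_m\,
#'   \kappa_{stage(i)} + u_i + \epsilon_{im}}
#' with per-miRNA baseline \eqn{b_m}, per-source batch shift
#' \eqn{\beta_{s,m} \sim N(0, batch\_sd^2)}, planted class effect
#' \eqn{\Delta_m} (0 for non-differential miRNAs), a per-sample global
#' RNA-content shift \eqn{u_i \sim N(0, sample\_scale\_sd^2)}, and
#' between-subject noise \eqn{\epsilon_{im}} with SD `bio_sd`
#' (`ref_bio_sd` for the planted reference miRNAs).
#'
#' @param config A [sim_config()] object.
#' @return A list with elements
#'   * `samples`: tibble (`sample_id`, `cohort`, `source_id`, `class`,
#'     `stage`, `age`); `stage` is `"not_applicable"` for non-cancer samples;
#'   * `truth`: list with `abundance` (samples x miRNA matrix, true copies/ml)
#'     and `mirna_info` (tibble: `mirna_id`, `is_differential`,
#'     `true_log2fc`, `is_reference`).
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(
#'   n_mirnas = 30, n_differential = 4, n_reference = 2,
#'   cohorts = small_cohort_design(15, 15), seed = 1))
#' dplyr::count(cohort$samples, class)
generate_cohort <- function(config) {
  config <- validate_sim_config(config)
  with_substream(config$seed, 1L, {
    mirna_ids <- sprintf("miR-sim-%04d", seq_len(config$n_mirnas))
    roles <- sample(config$n_mirnas)
    diff_idx <- roles[seq_len(config$n_differential)]
    ref_idx <- roles[config$n_differential + seq_len(config$n_reference)]

    true_log2fc <- rep(0, config$n_mirnas)
    true_log2fc[diff_idx] <- config$log2fc_effects
    mirna_info <- tibble(
      mirna_id = mirna_ids,
      is_differential = seq_len(config$n_mirnas) %in% diff_idx,
      true_log2fc = true_log2fc,
      is_reference = seq_len(config$n_mirnas) %in% ref_idx
    )

    samples <- purrr::pmap_dfr(config$cohorts, function(cohort, source_id,
                                                        n_cases, n_controls) {
      tibble(
        cohort = cohort, source_id = source_id,
        class = rep(c("cancer", "non_cancer"), c(n_cases, n_controls))
      )
    })
    n <- nrow(samples)
    if (n == 0) abort("invalid simulation config: field 'cohorts' yields no samples",
                      class = "mirpanel_config_error")
    samples <- samples |>
      mutate(
        sample_id = sprintf("S%05d", dplyr::row_number()),
        stage = ifelse(
          .data$class == "cancer",
          sample(names(config$stage_probs), n, replace = TRUE,
                 prob = config$stage_probs),
          "not_applicable"
        ),
        age = round(pmin(pmax(rnorm(n, 54, 8), 25), 90), 1)
      ) |>
      select("sample_id", "cohort", "source_id", "class", "stage", "age")

    baseline <- rnorm(config$n_mirnas, config$baseline_log2_mean,
                      config$baseline_log2_sd)
    sources <- sort(unique(samples$source_id))
    batch <- matrix(rnorm(length(sources) * config$n_mirnas, 0,
                          config$batch_sd),
                    nrow = length(sources),
                    dimnames = list(sources, mirna_ids))

    mirna_sd <- ifelse(mirna_info$is_reference, config$ref_bio_sd,
                       config$bio_sd)
    stage_mult <- config$stage_effect[samples$stage]
    stage_mult[is.na(stage_mult)] <- 0    # non-cancer samples
    is_case <- as.numeric(samples$class == "cancer")
    sample_shift <- rnorm(n, 0, config$sample_scale_sd)

    log2_conc <-
      matrix(baseline, n, config$n_mirnas, byrow = TRUE) +
      batch[samples$source_id, , drop = FALSE] +
      outer(is_case * stage_mult, true_log2fc) +
      sample_shift +
      matrix(rnorm(n * config$n_mirnas), n) *
        matrix(mirna_sd, n, config$n_mirnas, byrow = TRUE)

    abundance <- 2^log2_conc
    if (any(!is.finite(abundance)) || any(abundance <= 0)) {
      abort("generated abundances must be positive and finite",
            class = "mirpanel_generation_error")
    }
    dimnames(abundance) <- list(samples$sample_id, mirna_ids)
    list(samples = samples,
         truth = list(abundance = abundance, mirna_info = mirna_info))
  })
}

spike_ids <- function() c("spike_high", "spike_medium", "spike_low")

#' Simulate the RT-qPCR assay for a synthetic cohort
#'
#' Pushes the true abundances through the measurement model: per-sample
#' RNA-isolation efficiency (monitored by three spike-in controls added at
#' known copy number), fixed volume bookkeeping (serum volume in, RT input
#' fraction of the eluate), per-assay linear standard curves
#' \eqn{Ct = slope \cdot \log_{10}(copies) + intercept}, Gaussian Ct noise,
#' and technical duplicates. Reacted copies below one template molecule are
#' emitted as undetected (`NA` Ct).
#'
#' @param truth The `truth` element returned by [generate_cohort()].
#' @param samples The sample table returned by [generate_cohort()].
#' @param config The same [sim_config()] used to generate the cohort.
#' @return A `ct_dataset` list:
#'   * `measurements`: tibble (`sample_id`, `mirna_id`, `replicate`, `ct`);
#'   * `spikein_measurements`: tibble (`sample_id`, `spike_id`, `replicate`,
#'     `ct`);
#'   * `curve_measurements`: tibble (`assay_id`, `input_copies`, `ct`) over
#'     the six standard levels 1e7..1e2 copies, for every miRNA and spike
#'     assay;
#'   * `ntc`: no-template control wells (always undetected);
#'   * `isolation_efficiency`: tibble (`sample_id`, `isolation_efficiency`)
#'     (simulation ground truth, not visible to the quantification stage);
#'   * `curves_truth`: tibble of the drawn slope/intercept per assay.
#' @export
simulate_assay <- function(truth, samples, config) {
  config <- validate_sim_config(config)
  abundance <- truth$abundance
  if (any(abundance <= 0)) {
    abort("true abundances must be strictly positive",
          class = "mirpanel_generation_error")
  }
  with_substream(config$seed, 2L, {
    mirna_ids <- colnames(abundance)
    assay_ids <- c(mirna_ids, spike_ids())
    n_assay <- length(assay_ids)
    curves <- tibble(
      assay_id = assay_ids,
      slope = runif(n_assay, config$curve_slope_range[1],
                    config$curve_slope_range[2]),
      intercept = runif(n_assay, config$curve_intercept_range[1],
                        config$curve_intercept_range[2])
    )

    n <- nrow(abundance)
    iso_eff <- runif(n, config$isolation_eff_range[1],
                     config$isolation_eff_range[2])

    reacted <- abundance * config$serum_volume_ml * iso_eff *
      config$rt_input_fraction

    slope <- curves$slope[match(mirna_ids, curves$assay_id)]
    intercept <- curves$intercept[match(mirna_ids, curves$assay_id)]
    true_ct <- sweep(sweep(log10(reacted), 2, slope, `*`), 2, intercept, `+`)
    undet <- reacted < 1

    reps <- seq_len(config$duplicate_count)
    measurements <- purrr::map_dfr(reps, function(r) {
      ct <- true_ct + matrix(rnorm(length(true_ct), 0, config$ct_sd),
                             nrow(true_ct))
      ct[undet] <- NA_real_
      tibble(
        sample_id = rep(rownames(abundance), times = length(mirna_ids)),
        mirna_id = rep(mirna_ids, each = n),
        replicate = r,
        ct = as.vector(ct)
      )
    }) |>
      arrange(.data$sample_id, .data$mirna_id, .data$replicate)

    spike_in <- config$spikein_copies[c("high", "medium", "low")]
    spike_assay <- spike_ids()
    spike_reacted <- outer(iso_eff, spike_in * config$rt_input_fraction)
    sl <- curves$slope[match(spike_assay, curves$assay_id)]
    ic <- curves$intercept[match(spike_assay, curves$assay_id)]
    spike_true_ct <- sweep(sweep(log10(spike_reacted), 2, sl, `*`), 2, ic, `+`)
    spikein_measurements <- purrr::map_dfr(reps, function(r) {
      ct <- spike_true_ct +
        matrix(rnorm(length(spike_true_ct), 0, config$ct_sd),
               nrow(spike_true_ct))
      ct[spike_reacted < 1] <- NA_real_
      tibble(
        sample_id = rep(rownames(abundance), times = 3),
        spike_id = rep(spike_assay, each = n),
        replicate = r,
        ct = as.vector(ct)
      )
    }) |>
      arrange(.data$sample_id, .data$spike_id, .data$replicate)

    levels <- 10^(7:2)
    curve_measurements <- tidyr::crossing(
      assay_id = assay_ids, input_copies = levels
    ) |>
      left_join(curves, by = "assay_id") |>
      mutate(ct = .data$slope * log10(.data$input_copies) + .data$intercept +
               rnorm(dplyr::n(), 0, config$curve_ct_sd)) |>
      select("assay_id", "input_copies", "ct")

    out <- list(
      measurements = measurements,
      spikein_measurements = spikein_measurements,
      curve_measurements = curve_measurements,
      # no-template controls: clean water wells never amplify
      ntc = tibble(assay_id = assay_ids, ct = NA_real_),
      isolation_efficiency = tibble(sample_id = rownames(abundance),
                                    isolation_efficiency = iso_eff),
      curves_truth = curves
    )
    class(out) <- "ct_dataset"
    out
  })
}

#' Simulate a complete study (cohort + assay)
#'
#' @param config A [sim_config()] object.
#' @return A list with `samples`, `truth`, and `ct_data`.
#' @export
simulate_study <- function(config) {
  cohort <- generate_cohort(config)
  ct_data <- simulate_assay(cohort$truth, cohort$samples, config)
  list(samples = cohort$samples, truth = cohort$truth, ct_data = ct_data)
}
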