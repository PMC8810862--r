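#' Fit one qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(input copies) over a dilution
#' series. Amplification efficiency is derived from the slope as
#' \eqn{E = 10^{-1/slope} - 1} (1.0 = perfect per-cycle doubling).
#'
#' @param points Data frame with columns `input_copies` (> 0) and `ct`;
#'   rows with missing Ct (undetected standards) are dropped.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `efficiency`,
#'   `min_copies`, `max_copies`, `n_levels`.
#' @export
#' @examples
#' pts <- data.frame(input_copies = 10^(2:7),
#'                   ct = 40 - 3.3219 * (2:7))
#' fit_standard_curve(pts)
fit_standard_curve <- function(points) {
  stopifnot(all(c("input_copies", "ct") %in% names(points)))
  pts <- points[is.finite(points$ct), , drop = FALSE]
  if (any(pts$input_copies <= 0)) {
    abort("standard-curve input copies must be positive",
          class = "mirpanel_curve_error")
  }
  x <- log10(pts$input_copies)
  y <- pts$ct
  if (length(unique(x)) < 2) {
    abort("degenerate standard curve: need at least 2 distinct copy levels",
          class = "mirpanel_curve_error")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  if (slope >= 0) {
    abort("invalid assay: fitted standard-curve slope is not negative",
          class = "mirpanel_curve_error")
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  tibble(
    slope = slope, intercept = intercept,
    r_squared = r2,
    efficiency = 10^(-1 / slope) - 1,
    min_copies = min(pts$input_copies),
    max_copies = max(pts$input_copies),
    n_levels = length(unique(x))
  )
}

#' Fit standard curves for every assay
#'
#' @param curve_measurements Long tibble (`assay_id`, `input_copies`, `ct`),
#'   e.g. the `curve_measurements` element of a simulated `ct_dataset`.
#' @return Tibble with one row per assay (see [fit_standard_curve()]).
#' @export
fit_standard_curves <- function(curve_measurements) {
  curve_measurements |>
    group_by(.data$assay_id) |>
    group_modify(~ fit_standard_curve(.x)) |>
    ungroup()
}

#' Convert Ct values to absolute copies via a standard curve
#'
#' Inverts the curve: \eqn{copies = 10^{(ct - intercept)/slope}}. Values
#' inside the fitted dilution range are flagged `interpolated`; values beyond
#' it `extrapolated_low` / `extrapolated_high`.
#'
#' @param ct Numeric vector of Ct values (NA = undetected).
#' @param curve One-row curve tibble from [fit_standard_curve()] (or any list
#'   with `slope`, `intercept` and optionally `min_copies`, `max_copies`).
#' @return Tibble (`copies`, `flag`); undetected Cts yield `NA` copies with
#'   flag `missing`.
#' @export
ct_to_copies <- function(ct, curve) {
  copies <- 10^((ct - curve$intercept) / curve$slope)
  flag <- rep("interpolated", length(ct))
  lo <- curve$min_copies %||% -Inf
  hi <- curve$max_copies %||% Inf
  flag[copies < lo] <- "extrapolated_low"
  flag[copies > hi] <- "extrapolated_high"
  flag[!is.finite(copies)] <- "missing"
  copies[!is.finite(copies)] <- NA_real_
  tibble(copies = copies, flag = flag)
}

#' Per-sample RNA-isolation recovery from spike-in controls
#'
#' Duplicate spike Cts are averaged on the Ct scale, converted to copies via
#' each spike's own standard curve, and compared with the expected reacted
#' copies (spike input scaled by the RT input fraction). The per-sample
#' recovery is the geometric mean of measured/expected over the observed
#' spikes; samples where all spikes are undetected are flagged as failed.
#'
#' @param spikein_measurements Tibble (`sample_id`, `spike_id`, `replicate`,
#'   `ct`).
#' @param spike_curves Curve tibble with `assay_id` matching the spike ids.
#' @param spikein_copies Named vector (high/medium/low) of spike input copies.
#' @param rt_input_fraction Fraction of the eluate entering RT.
#' @return Tibble (`sample_id`, `recovery`, `n_spikes`, `ok`).
#' @export
spikein_recovery <- function(spikein_measurements, spike_curves,
                             spikein_copies = c(high = 2e5, medium = 2e4,
                                                low = 2e3),
                             rt_input_fraction = 2 / 25) {
  expected <- tibble(
    spike_id = spike_ids(),
    expected_copies = unname(spikein_copies[c("high", "medium", "low")]) *
      rt_input_fraction
  )
  per_spike <- spikein_measurements |>
    group_by(.data$sample_id, .data$spike_id) |>
    summarise(ct = if (all(is.na(.data$ct))) NA_real_ else
      mean(.data$ct, na.rm = TRUE), .groups = "drop") |>
    left_join(spike_curves, by = c(spike_id = "assay_id")) |>
    mutate(measured = 10^((.data$ct - .data$intercept) / .data$slope)) |>
    left_join(expected, by = "spike_id") |>
    mutate(log_ratio = log(.data$measured / .data$expected_copies))

  per_spike |>
    group_by(.data$sample_id) |>
    summarise(
      n_spikes = sum(is.finite(.data$log_ratio)),
      recovery = if (any(is.finite(.data$log_ratio)))
        exp(mean(.data$log_ratio[is.finite(.data$log_ratio)]))
      else NA_real_,
      .groups = "drop"
    ) |>
    mutate(ok = .data$n_spikes > 0)
}

#' Absolute quantification: Ct observations to copies per ml serum
#'
#' Per sample and miRNA: technical duplicates are averaged on the Ct scale,
#' converted to reacted copies through the assay's standard curve, corrected
#' by the sample's spike-in recovery, and scaled by the RT input fraction and
#' serum volume to copies/ml serum. Cells undetected in all duplicates are
#' floored at the bottom standard level scaled identically (flag `floored`).
#' Samples whose spike-ins all failed are excluded.
#'
#' @param ct_data A `ct_dataset` (see [simulate_assay()]) or any list with
#'   `measurements`, `spikein_measurements`, `curve_measurements`.
#' @param samples Sample table; quantification is restricted to its ids.
#' @param curves Optional pre-fit curve tibble; fitted from
#'   `ct_data$curve_measurements` when `NULL`.
#' @param spikein_copies,rt_input_fraction,serum_volume_ml Protocol constants
#'   (defaults: 2e5/2e4/2e3 spike copies, 2 ul of 25 ul eluate, 0.2 ml serum).
#' @param discordance_ct Duplicate Ct spread beyond which a cell is flagged
#'   `discordant_duplicates` (still averaged).
#' @return A `quantified_expression` list: `expression` (wide tibble,
#'   copies/ml), `flags` (long tibble `sample_id`, `mirna_id`, `flag`),
#'   `recovery` (per-sample recovery tibble), `excluded_samples`, `curves`.
#' @export
absolute_quantify <- function(ct_data, samples, curves = NULL,
                              spikein_copies = c(high = 2e5, medium = 2e4,
                                                 low = 2e3),
                              rt_input_fraction = 2 / 25,
                              serum_volume_ml = 0.2,
                              discordance_ct = 2) {
  if (is.null(curves)) curves <- fit_standard_curves(ct_data$curve_measurements)
  mirnas <- sort(unique(ct_data$measurements$mirna_id))
  missing_curves <- setdiff(mirnas, curves$assay_id)
  if (length(missing_curves) > 0) {
    abort(paste0("no standard curve for assay(s): ",
                 paste(head(missing_curves, 5), collapse = ", ")),
          class = "mirpanel_config_error")
  }
  spike_curves <- curves |> filter(.data$assay_id %in% spike_ids())
  recovery <- spikein_recovery(ct_data$spikein_measurements, spike_curves,
                               spikein_copies, rt_input_fraction)
  excluded <- recovery |>
    filter(!.data$ok) |>
    transmute(.data$sample_id, reason = "spikein_failure")

  keep_ids <- intersect(samples$sample_id,
                        recovery$sample_id[recovery$ok])

  # One row per (sample, miRNA, replicate) in: pivot replicates to columns so
  # duplicate averaging on the Ct scale is a vectorized row operation.
  rep_wide <- ct_data$measurements |>
    filter(.data$sample_id %in% keep_ids) |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "ct",
                       names_prefix = "rep")
  rep_mat <- as.matrix(rep_wide[grep("^rep", names(rep_wide))])
  if (nrow(rep_mat) == 0 || ncol(rep_mat) == 0) {
    n_det <- integer(nrow(rep_wide))
    ct_mean <- rep(NA_real_, nrow(rep_wide))
    spread <- numeric(nrow(rep_wide))
  } else {
    n_det <- rowSums(is.finite(rep_mat))
    ct_mean <- rowMeans(rep_mat, na.rm = TRUE)
    ct_mean[n_det == 0] <- NA_real_
    rep_df <- as.data.frame(rep_mat)
    rng_hi <- do.call(pmax, c(rep_df, na.rm = TRUE))
    rng_lo <- do.call(pmin, c(rep_df, na.rm = TRUE))
    spread <- ifelse(n_det >= 2, rng_hi - rng_lo, 0)
  }
  cells <- tibble(
    sample_id = rep_wide$sample_id,
    mirna_id = rep_wide$mirna_id,
    n_detected = n_det,
    spread = spread,
    ct = ct_mean
  )

  curve_cols <- curves |>
    select("assay_id", "slope", "intercept", "min_copies", "max_copies")
  cells <- cells |>
    left_join(curve_cols, by = c(mirna_id = "assay_id")) |>
    left_join(recovery |> select("sample_id", "recovery"), by = "sample_id")

  scale_factor <- rt_input_fraction * serum_volume_ml
  cells <- cells |>
    mutate(
      copies_reacted = 10^((.data$ct - .data$intercept) / .data$slope),
      flag = dplyr::case_when(
        is.na(.data$ct) ~ "floored",
        .data$copies_reacted < .data$min_copies ~ "extrapolated_low",
        .data$copies_reacted > .data$max_copies ~ "extrapolated_high",
        TRUE ~ "interpolated"
      ),
      copies_reacted = ifelse(is.na(.data$ct), .data$min_copies,
                              .data$copies_reacted),
      copies_per_ml = .data$copies_reacted / .data$recovery / scale_factor,
      discordant = .data$spread > discordance_ct
    )

  n_disc <- sum(cells$discordant)
  if (n_disc > 0) {
    rlang::inform(paste0(n_disc, " cell(s) had duplicate Ct spread > ",
                         discordance_ct, " cycles (averaged anyway)"))
  }

  wide <- cells |>
    select("sample_id", "mirna_id", "copies_per_ml") |>
    tidyr::pivot_wider(names_from = "mirna_id",
                       values_from = "copies_per_ml") |>
    arrange(.data$sample_id)

  flags <- cells |>
    transmute(.data$sample_id, .data$mirna_id,
              flag = ifelse(.data$discordant,
                            paste0(.data$flag, ";discordant_duplicates"),
                            .data$flag))

  out <- list(
    expression = wide,
    flags = flags,
    recovery = recovery,
    excluded_samples = excluded,
    curves = curves
  )
  class(out) <- "quantified_expression"
  out
}

#' @export
print.quantified_expression <- function(x, ...) {
  cat("Quantified serum miRNA expression\n")
  cat("  samples:", nrow(x$expression), "  miRNAs:",
      ncol(x$expression) - 1, "\n")
  cat("  excluded (spike-in failure):", nrow(x$excluded_samples), "\n")
  fl <- table(sub(";.*", "", x$flags$flag))
  cat("  cell flags:",
      paste(names(fl), fl, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
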