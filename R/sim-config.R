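#' Default multi-centre cohort design
#'
#' Three-phase case-control design: a single-source discovery cohort and two
#' multi-source validation cohorts drawn from six sample sources, with the
#' per-source case/control counts of the study the generator emulates
#' (discovery 183 cancer / 106 non-cancer; validation 1 with 177/197;
#' validation 2 with 180/199).
#'
#' @return A tibble with columns `cohort`, `source_id`, `n_cases`,
#'   `n_controls`.
#' @export
default_cohort_design <- function() {
  tibble::tribble(
    ~cohort,        ~source_id, ~n_cases, ~n_controls,
    "discovery",    "source1",  183L,     106L,
    "validation1",  "source2",  39L,      39L,
    "validation1",  "source3",  23L,      33L,
    "validation1",  "source4",  48L,      47L,
    "validation1",  "source5",  38L,      35L,
    "validation1",  "source6",  29L,      43L,
    "validation2",  "source2",  40L,      39L,
    "validation2",  "source3",  24L,      34L,
    "validation2",  "source4",  48L,      47L,
    "validation2",  "source5",  38L,      35L,
    "validation2",  "source6",  30L,      44L
  )
}

#' Default planted fold-change effects
#'
#' Signed log2 fold changes for the planted differential miRNAs: a
#' "panel-grade" strong block (default 8 markers at |log2FC| = `strong`)
#' followed by moderate effects, alternating direction (half up-regulated,
#' half down-regulated in cancer).
#'
#' @param n_differential Number of differential miRNAs.
#' @param n_strong Number of strong markers at the head of the vector.
#' @param strong,moderate Effect magnitudes (log2 units).
#' @return Numeric vector of length `n_differential`.
#' @export
default_log2fc_effects <- function(n_differential, n_strong = 8L,
                                   strong = 1.2, moderate = 0.6) {
  n_strong <- min(n_strong, n_differential)
  signs <- rep(c(1, -1), length.out = n_differential)
  mag <- c(rep(strong, n_strong), rep(moderate, n_differential - n_strong))
  signs * mag
}

#' Configure a synthetic serum-miRNA study
#'
#' Parameters of the synthetic-cohort generator. The defaults reproduce the
#' structure of the multi-centre study the package's workflow targets:
#' 324 assayed miRNAs, 30 truly differential markers (|log2FC| >= 0.5, of
#' which 8 are strong at |log2FC| = 1.2), 3 planted low-variance reference
#' miRNAs, six sample sources with batch shifts, three spike-in controls
#' monitoring per-sample RNA-isolation efficiency, per-assay 6-log standard
#' curves (1e7 down to 1e2 copies), and duplicated qPCR wells with Gaussian
#' Ct noise.
#'
#' @param n_mirnas Number of assayed miRNAs.
#' @param n_differential Number of truly differential miRNAs.
#' @param log2fc_effects Signed log2 fold-change (cancer minus control) for
#'   each differential miRNA; length `n_differential`.
#' @param n_reference Number of planted stable reference miRNAs.
#' @param cohorts Cohort design tibble (`cohort`, `source_id`, `n_cases`,
#'   `n_controls`); see [default_cohort_design()].
#' @param batch_sd SD (log2 units) of per-source, per-miRNA batch shifts.
#' @param bio_sd Between-subject biological SD (log2 units) of non-reference
#'   miRNAs.
#' @param ref_bio_sd Between-subject SD (log2 units) of the planted reference
#'   miRNAs; small by construction, since a usable endogenous reference is one
#'   whose abundance varies little across subjects.
#' @param sample_scale_sd SD (log2 units) of a per-sample global shift in
#'   total serum miRNA content. This shift applies to every endogenous miRNA
#'   but not to the spike-ins (which are added at fixed copy number during
#'   isolation), so it is exactly the variation endogenous reference
#'   normalization exists to remove.
#' @param ct_sd Technical SD of observed Ct values (cycles).
#' @param duplicate_count Technical qPCR replicates per well.
#' @param isolation_eff_range Range of per-sample RNA-isolation efficiency
#'   (multiplicative recovery fraction).
#' @param spikein_copies Named vector (high/medium/low) of spike-in input
#'   copies added per sample before isolation.
#' @param curve_slope_range Range of per-assay standard-curve slopes
#'   (cycles per log10 copies; strictly negative).
#' @param curve_intercept_range Range of per-assay curve intercepts (Ct at a
#'   single copy; the fixed 14-cycle pre-amplification shared by samples and
#'   standards is folded into this intercept).
#' @param curve_ct_sd Ct noise of the standard-curve wells (0 = noise-free
#'   standards).
#' @param baseline_log2_mean,baseline_log2_sd Log-normal baseline of serum
#'   abundance: per-miRNA mean log2 copies/ml drawn from
#'   N(`baseline_log2_mean`, `baseline_log2_sd`^2).
#' @param stage_probs Named probability vector over tumour stages
#'   `c("0","I","II","III","IV","unknown")` for cancer cases.
#' @param stage_effect Named multiplier on `log2fc_effects` per stage
#'   (default 1 for all stages: stage labels are annotations only).
#' @param serum_volume_ml Serum volume entering RNA isolation (ml).
#' @param rt_input_fraction Fraction of the RNA eluate entering each RT
#'   reaction (2 ul of a 25 ul eluate).
#' @param seed Master seed; all generator randomness derives from it.
#'
#' @return A validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_mirnas = 40, n_differential = 6, n_reference = 2,
#'                   cohorts = small_cohort_design(20, 20), seed = 7)
#' str(cfg[c("n_mirnas", "n_differential", "log2fc_effects")])
sim_config <- function(n_mirnas = 324L,
                       n_differential = 30L,
                       log2fc_effects = default_log2fc_effects(n_differential),
                       n_reference = 3L,
                       cohorts = default_cohort_design(),
                       batch_sd = 0.3,
                       bio_sd = 0.8,
                       ref_bio_sd = 0.15,
                       sample_scale_sd = 0.25,
                       ct_sd = 0.15,
                       duplicate_count = 2L,
                       isolation_eff_range = c(0.5, 1.0),
                       spikein_copies = c(high = 2e5, medium = 2e4, low = 2e3),
                       curve_slope_range = c(-3.6, -3.1),
                       curve_intercept_range = c(38, 42),
                       curve_ct_sd = 0,
                       baseline_log2_mean = 18,
                       baseline_log2_sd = 1.5,
                       stage_probs = c("0" = 0.07, "I" = 0.32, "II" = 0.36,
                                       "III" = 0.08, "IV" = 0.01,
                                       "unknown" = 0.16),
                       stage_effect = c("0" = 1, "I" = 1, "II" = 1,
                                        "III" = 1, "IV" = 1, "unknown" = 1),
                       serum_volume_ml = 0.2,
                       rt_input_fraction = 2 / 25,
                       seed = 1L) {
  config <- list(
    n_mirnas = as.integer(n_mirnas),
    n_differential = as.integer(n_differential),
    log2fc_effects = as.double(log2fc_effects),
    n_reference = as.integer(n_reference),
    cohorts = as_tibble(cohorts),
    batch_sd = batch_sd, bio_sd = bio_sd, ref_bio_sd = ref_bio_sd,
    sample_scale_sd = sample_scale_sd, ct_sd = ct_sd,
    duplicate_count = as.integer(duplicate_count),
    isolation_eff_range = isolation_eff_range,
    spikein_copies = spikein_copies,
    curve_slope_range = curve_slope_range,
    curve_intercept_range = curve_intercept_range,
    curve_ct_sd = curve_ct_sd,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    stage_probs = stage_probs,
    stage_effect = stage_effect,
    serum_volume_ml = serum_volume_ml,
    rt_input_fraction = rt_input_fraction,
    seed = as.integer(seed)
  )
  class(config) <- "sim_config"
  validate_sim_config(config)
}

#' Single-source two-cohort toy design
#'
#' Convenience design for tests and examples: one source, `n_cases` cancer
#' and `n_controls` non-cancer samples per requested cohort.
#'
#' @param n_cases,n_controls Per-cohort counts.
#' @param cohorts Cohort names to include.
#' @return A cohort-design tibble.
#' @export
small_cohort_design <- function(n_cases, n_controls,
                                cohorts = "discovery") {
  tibble(cohort = cohorts, source_id = "source1",
         n_cases = as.integer(n_cases), n_controls = as.integer(n_controls))
}

validate_sim_config <- function(config) {
  fail <- function(field, msg) {
    abort(paste0("invalid simulation config: field '", field, "' ", msg),
          class = "mirpanel_config_error")
  }
  with(config, {
    if (n_mirnas < 1) fail("n_mirnas", "must be >= 1")
    if (n_differential < 0) fail("n_differential", "must be >= 0")
    if (n_reference < 0) fail("n_reference", "must be >= 0")
    if (n_differential + n_reference > n_mirnas) {
      fail("n_differential", "+ n_reference must not exceed n_mirnas")
    }
    if (length(log2fc_effects) != n_differential) {
      fail("log2fc_effects", "must have length n_differential")
    }
    if (any(!is.finite(log2fc_effects))) fail("log2fc_effects", "must be finite")
    if (!all(c("cohort", "source_id", "n_cases", "n_controls") %in%
             names(cohorts))) {
      fail("cohorts", "must have cohort/source_id/n_cases/n_controls columns")
    }
    if (any(cohorts$n_cases < 0) || any(cohorts$n_controls < 0)) {
      fail("cohorts", "counts must be non-negative")
    }
    for (f in c("batch_sd", "bio_sd", "ref_bio_sd", "sample_scale_sd",
                "ct_sd", "curve_ct_sd")) {
      v <- config[[f]]
      if (!is.numeric(v) || length(v) != 1 || v < 0) fail(f, "must be a single non-negative number")
    }
    if (duplicate_count < 1) fail("duplicate_count", "must be >= 1")
    if (length(isolation_eff_range) != 2 || any(isolation_eff_range <= 0) ||
        diff(isolation_eff_range) < 0 || any(isolation_eff_range > 1)) {
      fail("isolation_eff_range", "must be an increasing interval in (0, 1]")
    }
    if (length(spikein_copies) != 3 || any(spikein_copies <= 0) ||
        !all(c("high", "medium", "low") %in% names(spikein_copies))) {
      fail("spikein_copies", "must be three positive values named high/medium/low")
    }
    if (any(curve_slope_range >= 0) || diff(curve_slope_range) < 0) {
      fail("curve_slope_range", "must be an increasing interval of negative slopes")
    }
    if (diff(curve_intercept_range) < 0) {
      fail("curve_intercept_range", "must be an increasing interval")
    }
    if (!isTRUE(all.equal(sum(stage_probs), 1, tolerance = 1e-8)) ||
        any(stage_probs < 0) ||
        !setequal(names(stage_probs), stage_levels())) {
      fail("stage_probs", "must be non-negative, named 0/I/II/III/IV/unknown, and sum to 1")
    }
    if (!setequal(names(stage_effect), stage_levels())) {
      fail("stage_effect", "must be named 0/I/II/III/IV/unknown")
    }
    if (serum_volume_ml <= 0) fail("serum_volume_ml", "must be positive")
    if (rt_input_fraction <= 0 || rt_input_fraction > 1) {
      fail("rt_input_fraction", "must be in (0, 1]")
    }
  })
  config
}
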