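# Small simulation presets shared across tests.

tiny_config <- function(seed = 1, ...) {
  args <- list(
    n_mirnas = 30L, n_differential = 6L, n_reference = 3L,
    log2fc_effects = default_log2fc_effects(6, n_strong = 6, strong = 1.2),
    cohorts = small_cohort_design(15, 15),
    seed = seed
  )
  do.call(sim_config, modifyList(args, list(...)))
}

noise_free_config <- function(seed = 1, ...) {
  tiny_config(seed = seed, bio_sd = 0, batch_sd = 0, sample_scale_sd = 0,
              ct_sd = 0, ref_bio_sd = 0, isolation_eff_range = c(1, 1), ...)
}

# Construct a ct_dataset by hand around a single known assay curve.
manual_ct_dataset <- function(sample_ct, curve_slope = -3.3219,
                              curve_intercept = 40, spike_shift = 0) {
  spike_in <- c(high = 2e5, medium = 2e4, low = 2e3)
  frac <- 2 / 25
  spike_ct <- curve_slope * log10(spike_in * frac) + curve_intercept +
    spike_shift
  curve_rows <- tidyr::crossing(
    assay_id = c("miR-x", "spike_high", "spike_medium", "spike_low"),
    input_copies = 10^(7:2)
  )
  curve_rows$ct <- curve_slope * log10(curve_rows$input_copies) +
    curve_intercept
  structure(list(
    measurements = tibble::tibble(
      sample_id = "S1", mirna_id = "miR-x",
      replicate = seq_along(sample_ct), ct = sample_ct
    ),
    spikein_measurements = tibble::tibble(
      sample_id = "S1",
      spike_id = rep(c("spike_high", "spike_medium", "spike_low"), each = 2),
      replicate = rep(1:2, 3),
      ct = rep(spike_ct, each = 2)
    ),
    curve_measurements = curve_rows
  ), class = "ct_dataset")
}

# A suppressor-variable pair: f1 = signal + u, f2 = u with large shared
# noise u. Individually both are weak; their difference is the clean signal.
# Greedy picks the mediocre standalone feature first and cannot recover; the
# floating removal step can.
suppressor_instance <- function(seed) {
  set.seed(seed)
  n <- 150
  z <- rnorm(n)
  u <- rnorm(n, 0, 3)
  x <- cbind(f1 = z + u, f2 = u, f3 = 0.35 * z + rnorm(n),
             f4 = rnorm(n), f5 = rnorm(n))
  y <- as.integer(plogis(2.5 * z) > runif(n))
  list(x = x, y = y)
}

one_sample_table <- function() {
  tibble::tibble(sample_id = "S1", cohort = "discovery",
                 source_id = "source1", class = "cancer", stage = "I",
                 age = 50)
}
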