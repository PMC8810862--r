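# Tab-delimited exchange formats (UTF-8, header row, "." decimal, NA for
# undetected Ct).

#' Write a simulated study as TSV tables
#'
#' Emits `samples.tsv`, `ct_long.tsv`, `spikein_ct.tsv`, `curve_ct.tsv`, and
#' the generator ground truth `truth.tsv`.
#'
#' @param study List from [simulate_study()].
#' @param dir Output directory.
#' @return (Invisibly) the written paths.
#' @export
write_ct_dataset <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    samples = file.path(dir, "samples.tsv"),
    ct = file.path(dir, "ct_long.tsv"),
    spikes = file.path(dir, "spikein_ct.tsv"),
    curves = file.path(dir, "curve_ct.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(study$samples, paths["samples"])
  readr::write_tsv(study$ct_data$measurements, paths["ct"])
  readr::write_tsv(study$ct_data$spikein_measurements, paths["spikes"])
  readr::write_tsv(study$ct_data$curve_measurements |>
                     dplyr::rename(mirna_id = "assay_id"), paths["curves"])
  readr::write_tsv(study$truth$mirna_info, paths["truth"])
  invisible(paths)
}

#' Read a Ct dataset from TSV tables
#'
#' @param inputs Named list/vector of paths: `ct`, `spikes`, `curves`,
#'   `samples`.
#' @return A list with `samples` and a `ct_dataset` under `ct_data`.
#' @export
read_ct_dataset <- function(inputs) {
  need <- c("ct", "spikes", "curves", "samples")
  missing_in <- setdiff(need, names(inputs))
  if (length(missing_in) > 0) {
    abort(paste0("missing input path(s): ", paste(missing_in, collapse = ", ")),
          class = "mirpanel_config_error")
  }
  for (f in need) {
    if (!file.exists(inputs[[f]])) {
      abort(paste0("input file not found: ", inputs[[f]]),
            class = "mirpanel_config_error")
    }
  }
  ct <- readr::read_tsv(inputs$ct, show_col_types = FALSE)
  spikes <- readr::read_tsv(inputs$spikes, show_col_types = FALSE)
  curves <- readr::read_tsv(inputs$curves, show_col_types = FALSE)
  if ("mirna_id" %in% names(curves)) {
    curves <- curves |> dplyr::rename(assay_id = "mirna_id")
  }
  samples <- readr::read_tsv(inputs$samples, show_col_types = FALSE)
  ct_data <- structure(list(
    measurements = ct,
    spikein_measurements = spikes,
    curve_measurements = curves
  ), class = "ct_dataset")
  list(samples = samples, ct_data = ct_data)
}
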