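#' Dual-currency formatting of an INR amount
#'
#' Rounds to the nearest rupee and nearest dollar, matching the reporting
#' style of the underlying publication stream; internal arithmetic is
#' always unrounded.
#'
#' @param amount INR amount
#' @param config the `config` component of a parameter set
#' @return character like `"INR 181520 (US$ 2169)"`
#' @export
format_inr_usd <- function(amount, config) {
  sprintf("INR %s (US$ %s)",
          format(round(amount), big.mark = ",", scientific = FALSE),
          format(round(currency_convert(amount, config)),
                 big.mark = ",", scientific = FALSE))
}

#' Write the base-case results table (ladder order) as CSV
#'
#' Columns mirror the publication-style dominance table: group, cost (INR
#' and USD), incremental cost, QALYs, incremental QALYs, ICUR, INMB.
#'
#' @param ladder data.frame from [icur_ladder()]
#' @param config the `config` component of a parameter set
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_ladder_csv <- function(ladder, config, path) {
  out <- data.frame(
    group = ladder$group,
    cost_inr = round(ladder$total_cost, 2),
    cost_usd = round(currency_convert(ladder$total_cost, config), 2),
    incremental_cost_inr = round(ladder$delta_cost, 2),
    qalys = ladder$total_qaly,
    lys = ladder$total_ly,
    incremental_qalys = ladder$delta_qaly,
    icur_inr_per_qaly = round(ladder$icur, 2),
    inmb_inr = round(ladder$inmb, 2),
    dominance = ladder$dominance)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write per-group survival curves as CSV
#' @param results named list of `group_result` objects
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_survival_csv <- function(results, path) {
  out <- do.call(rbind, lapply(results, function(r)
    data.frame(group = r$group, year = seq_along(r$os_curve) - 1,
               os = r$os_curve, dfs = r$dfs_curve)))
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, package version, seed, timestamp and
#' the list of files the run produced, so that deterministic outputs can be
#' reproduced from the manifest alone.
#'
#' @param path output JSON path
#' @param params slnb_params object used for the run
#' @param seed integer seed used (NA for fully deterministic runs)
#' @param outputs character vector of files written
#' @param extra optional named list of additional fields (e.g. knob values)
#' @return `path`, invisibly
#' @export
write_run_manifest <- function(path, params, seed, outputs, extra = list()) {
  manifest <- c(list(
    package = "slnbcea",
    version = as.character(utils::packageVersion("slnbcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = params$config,
    calibration_knobs = params$costs[c(
      "adjuvant_chemo_fraction", "chemo_cycles", "rt_modality_weights",
      "lrr_salvage_fraction", "followup_visits_per_year",
      "followup_visits_after", "radiology_per_visit",
      "group3_fn_readmission_mnd")],
    morbidity_weight = params$utilities$morbidity_weight,
    outputs = outputs), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
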