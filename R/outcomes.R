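#' Summarise a cohort trace into group-level economic outcomes
#'
#' @param trace cohort_trace object from [run_cohort()]
#' @return object of class `group_result`: list with `group`, `total_cost`
#'   (INR, discounted), `total_ly`, `total_qaly` (discounted), `os_curve`
#'   and `dfs_curve` (fractions at the end of cycles 0..H), and the trace
#' @export
group_result <- function(trace) {
  m <- trace_membership(trace)
  structure(list(
    group = trace$group,
    total_cost = sum(trace$cost),
    total_ly = sum(trace$ly),
    total_qaly = sum(trace$qaly),
    os_curve = 1 - (m[, "DEATH_CANCER"] + m[, "DEATH_OTHER"]),
    dfs_curve = m[, "DFS"],
    trace = trace), class = "group_result")
}

#' Run one treatment group end to end
#' @inheritParams run_cohort
#' @return group_result object
#' @export
run_group <- function(group, params, horizon_years = NULL) {
  group_result(run_cohort(group, params, horizon_years))
}

#' Overall and disease-free survival at the end of a model year
#'
#' `os` counts every non-death compartment as alive. `os_excl_dm`
#' additionally treats progression to distant metastasis as a terminal
#' event (i.e. the fraction alive without distant disease); this is the
#' survival readout conventionally quoted for this model's published
#' 5-year figures, which exclude the distant-metastasis compartment.
#'
#' @param trace cohort_trace object
#' @param year model year (0 = entry)
#' @return named list `os`, `os_excl_dm`, `dfs` (cohort fractions)
#' @export
survival_summary <- function(trace, year) {
  if (year < 0 || year > trace$horizon)
    stop("year ", year, " outside the simulated horizon (0-", trace$horizon,
         ")", call. = FALSE)
  m <- trace_membership(trace)
  os <- unname(1 - m[year + 1, "DEATH_CANCER"] - m[year + 1, "DEATH_OTHER"])
  list(os = os,
       os_excl_dm = os - unname(m[year + 1, "DM"]),
       dfs = unname(m[year + 1, "DFS"]))
}

#' Incremental net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`; positive values indicate
#' cost-effectiveness at the given willingness-to-pay.
#'
#' @param delta_cost incremental cost (INR)
#' @param delta_qaly incremental QALYs
#' @param wtp willingness-to-pay threshold (INR/QALY)
#' @return INMB in INR
#' @export
inmb <- function(delta_cost, delta_qaly, wtp) {
  wtp * delta_qaly - delta_cost
}

#' Convert INR to US dollars at the configured exchange rate
#' @param amount amount in INR
#' @param config the `config` component of a parameter set
#' @return amount in USD
#' @export
currency_convert <- function(amount, config) {
  amount / config$inr_per_usd
}

#' Pairwise comparison of two strategies
#' @param reference group_result of the less effective (reference) strategy
#' @param comparator group_result of the strategy being compared
#' @param wtp willingness-to-pay (INR/QALY)
#' @return one-row data.frame: `reference_group`, `comparator_group`,
#'   `delta_cost`, `delta_qaly`, `icur`, `inmb`, `dominance`, `tie`
#' @export
compare_groups <- function(reference, comparator, wtp) {
  dc <- comparator$total_cost - reference$total_cost
  dq <- comparator$total_qaly - reference$total_qaly
  dominance <- "none"
  tie <- FALSE
  icur <- NA_real_
  if (dq == 0) {
    tie <- TRUE
  } else {
    icur <- dc / dq
  }
  if (dq > 0 && dc < 0) {
    dominance <- "dominant"   # comparator cheaper and more effective
    icur <- NA_real_          # a negative ratio is ambiguous; flag instead
  } else if (dq < 0 && dc > 0) {
    dominance <- "dominated"
    icur <- NA_real_
  }
  data.frame(reference_group = reference$group,
             comparator_group = comparator$group,
             delta_cost = dc, delta_qaly = dq, icur = icur,
             inmb = inmb(dc, dq, wtp), dominance = dominance, tie = tie,
             stringsAsFactors = FALSE)
}

#' Dominance-ordered incremental cost-utility ladder
#'
#' Sorts the strategies in ascending order of effectiveness (total QALYs;
#' ties broken on cost and flagged) and compares each strategy with its
#' predecessor, computing incremental costs, incremental QALYs, ICURs,
#' dominance flags and INMB at the given willingness-to-pay.
#'
#' @param results list of `group_result` objects (>= 2)
#' @param wtp willingness-to-pay (INR/QALY)
#' @return data.frame with one row per strategy in ladder order; the first
#'   row (the least effective strategy) carries NA increments
#' @export
icur_ladder <- function(results, wtp) {
  stopifnot(length(results) >= 2)
  q <- vapply(results, function(r) r$total_qaly, numeric(1))
  cst <- vapply(results, function(r) r$total_cost, numeric(1))
  ord <- order(q, cst)
  results <- results[ord]

  rows <- data.frame(
    group = vapply(results, function(r) r$group, character(1)),
    total_cost = cst[ord], total_qaly = q[ord],
    total_ly = vapply(results, function(r) r$total_ly, numeric(1)),
    delta_cost = NA_real_, delta_qaly = NA_real_, icur = NA_real_,
    inmb = NA_real_, dominance = NA_character_, tie = NA,
    stringsAsFactors = FALSE)
  for (i in 2:length(results)) {
    cmp <- compare_groups(results[[i - 1]], results[[i]], wtp)
    rows$delta_cost[i] <- cmp$delta_cost
    rows$delta_qaly[i] <- cmp$delta_qaly
    rows$icur[i] <- cmp$icur
    rows$inmb[i] <- cmp$inmb
    rows$dominance[i] <- cmp$dominance
    rows$tie[i] <- cmp$tie
  }
  rows
}

#' Deterministic base case: all three strategies plus the ICUR ladder
#'
#' @param params slnb_params object
#' @param horizon_years optional horizon override
#' @return list with `results` (named list of group_result for groups
#'   I/II/III), `ladder` (see [icur_ladder()]) and `comparisons` (pairwise
#'   I vs II, I vs III, II vs III)
#' @export
base_case <- function(params, horizon_years = NULL) {
  res <- lapply(c(I = "I", II = "II", III = "III"), run_group,
                params = params, horizon_years = horizon_years)
  wtp <- params$config$wtp_threshold
  list(
    results = res,
    ladder = icur_ladder(unname(res), wtp),
    comparisons = rbind(
      compare_groups(res$II, res$I, wtp),
      compare_groups(res$III, res$I, wtp),
      compare_groups(res$III, res$II, wtp)))
}
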