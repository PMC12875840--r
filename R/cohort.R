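#' Health state labels of the Markov model
#'
#' Six states: disease-free survival, loco-regional recurrence, salvaged
#' (post salvage surgery), distant metastasis, death from oral cancer,
#' death from other causes.
#' @export
slnb_states <- c("DFS", "LRR", "SALVAGE", "DM", "DEATH_CANCER", "DEATH_OTHER")

#' One-cycle transition probability row set for a pathway
#'
#' Builds the 6x6 annual transition matrix for a given patient age,
#' neck-dissection status and recurrence-risk class. Cancer-specific exits
#' are taken from the parameter table; age-dependent background mortality is
#' added as a competing exit from every alive state; the remainder stays.
#' If listed exits plus background mortality exceed 1 in any row the exits
#' are renormalised to sum to 1 (stay becomes 0) and a warning is emitted.
#' Death states are absorbing.
#'
#' @param params slnb_params object
#' @param age patient age in years at the start of the cycle
#' @param dissected logical; was a neck dissection performed in this pathway
#' @param risk_class `"node_pos"` or `"node_neg"` (final histopathology)
#' @return 6x6 matrix with rows and columns named by [slnb_states]
#' @export
transition_matrix <- function(params, age, dissected, risk_class) {
  tr <- params$transitions
  m <- mortality_lookup(age, tr)
  P <- matrix(0, 6, 6, dimnames = list(slnb_states, slnb_states))

  fill <- function(from, exits) {
    tot <- sum(exits)
    if (tot > 1) {
      if (tot > 1 + 1e-9)   # tolerate pure floating-point overshoot silently
        warning("transition row ", from, " exits sum to ", signif(tot, 6),
                " > 1 at age ", age, "; renormalising", call. = FALSE)
      exits <- exits / tot
      tot <- 1
    }
    P[from, names(exits)] <<- exits
    P[from, from] <<- P[from, from] + (1 - tot)
  }

  if (identical(risk_class, "node_pos")) {
    lrr <- tr$dfs_to_lrr_node_pos; dm <- tr$dfs_to_dm_node_pos
  } else {
    lrr <- tr$dfs_to_lrr_node_neg; dm <- tr$dfs_to_dm_node_neg
  }
  fill("DFS", c(LRR = lrr, DM = dm, DEATH_OTHER = m))

  salv <- if (dissected) tr$lrr_to_salvage_dissected else tr$lrr_to_salvage_undissected
  fill("LRR", c(DM = tr$lrr_to_dm, SALVAGE = salv,
                DEATH_CANCER = tr$lrr_to_death_cancer, DEATH_OTHER = m))

  s_lrr <- if (dissected) tr$salvage_to_lrr_dissected else tr$salvage_to_lrr_undissected
  s_dm  <- if (dissected) tr$salvage_to_dm_dissected else tr$salvage_to_dm_undissected
  fill("SALVAGE", c(LRR = s_lrr, DM = s_dm, DEATH_OTHER = m))

  fill("DM", c(DEATH_CANCER = annual_from_median_survival(tr$dm_median_survival_months),
               DEATH_OTHER = m))

  P["DEATH_CANCER", "DEATH_CANCER"] <- 1
  P["DEATH_OTHER", "DEATH_OTHER"] <- 1
  P
}

#' Resolve the model horizon in cycles
#'
#' `"lifetime"` runs the cohort until age 100 (50 annual cycles from the
#' default entry age of 50).
#' @param config the `config` component of a parameter set
#' @param horizon_years optional override: integer or `"lifetime"`
#' @return number of annual cycles
#' @export
resolve_horizon <- function(config, horizon_years = NULL) {
  h <- if (is.null(horizon_years)) config$horizon_years else horizon_years
  if (identical(h, "lifetime")) h <- 100 - config$median_age
  h <- as.integer(h)
  if (is.na(h) || h < 1) stop("horizon must be >= 1 cycle", call. = FALSE)
  h
}

#' Follow-up investigation cost per model year while disease free
#'
#' Visit panel = CBC + liver and renal function + electrolytes + TSH, plus
#' `radiology_per_visit` high-end radiology investigations per visit; visit
#' frequency follows `followup_visits_per_year` for the scheduled early
#' years and `followup_visits_after` thereafter.
#'
#' @param params slnb_params object
#' @param years vector of model years (1-based)
#' @return INR cost accrued per year of DFS occupancy
#' @export
followup_cost_by_year <- function(params, years) {
  co <- params$costs
  panel <- co$cbc + co$lft + co$rft + co$electrolytes + co$tsh +
    co$radiology_per_visit * co$high_end_radiology
  sched <- co$followup_visits_per_year
  visits <- ifelse(years <= length(sched), sched[pmin(years, length(sched))],
                   co$followup_visits_after)
  visits * panel
}

#' Utility of the disease-free state for a pathway track and model year
#'
#' The `primary_resection_only` track (SLNB true negatives) keeps the
#' post-resection utility throughout. Neck-dissection tracks use the
#' procedure-specific utility -- a morbidity-weighted mix of the with/without
#' shoulder-morbidity values -- during the post-surgical utility window
#' (default five years), after which quality of life is assumed to settle at
#' the generic post-neck-dissection utility regardless of dissection extent.
#'
#' @param params slnb_params object
#' @param track `"primary_resection_only"`, `"snd"` or `"mnd"`
#' @param year model year (1-based), vectorised
#' @return utility weight in [0,1]
#' @export
dfs_track_utility <- function(params, track, year) {
  u <- params$utilities
  if (track == "primary_resection_only")
    return(rep(u$dfs_primary_resection, length(year)))
  mw <- u$morbidity_weight
  mixed <- switch(track,
    snd = mw * u$snd_with_morbidity + (1 - mw) * u$snd_without_morbidity,
    mnd = mw * u$mnd_with_morbidity + (1 - mw) * u$mnd_without_morbidity,
    stop("unknown utility track: ", track, call. = FALSE))
  ifelse(year <= u$utility_window_years, mixed, u$dfs_after_neck_dissection)
}

#' Run the Markov cohort model for one treatment group
#'
#' The cohort enters disease free, distributed over the group's diagnostic
#' strata. Each annual cycle applies the stratum-specific transition matrix
#' (age-updated background mortality), and accrues life-years, QALYs and
#' costs with the trapezoidal (life-table) half-cycle correction: per-cycle
#' accruals use the mean of start- and end-of-cycle state membership.
#' Upfront surgical and adjuvant costs fall at model entry (cycle 0,
#' undiscounted, no half-cycle correction); recurrence treatment is charged
#' on entry into LRR (from DFS or from the salvaged state), salvage surgery
#' on entry into the salvaged state, supportive care per cycle of distant
#' metastasis, and follow-up investigations per cycle of DFS. Costs, QALYs
#' and life-years of cycle t are discounted by `1/(1+r)^t`.
#'
#' @param group `"I"`, `"II"` or `"III"`
#' @param params slnb_params object
#' @param horizon_years optional horizon override (integer years or
#'   `"lifetime"`)
#' @return object of class `cohort_trace`: list with `membership`
#'   (array cycle x state x stratum, cycle 0 first), `profiles`,
#'   `cost`, `qaly`, `ly` (discounted per-cycle accruals, cycle 0 first),
#'   `horizon`, `group`
#' @export
run_cohort <- function(group, params, horizon_years = NULL) {
  cfg <- params$config
  H <- resolve_horizon(cfg, horizon_years)
  prof <- pathway_profiles(group, params)
  n_s <- nrow(prof)

  membership <- array(0, dim = c(H + 1, 6, n_s),
                      dimnames = list(NULL, slnb_states, prof$stratum))
  membership[1, "DFS", ] <- 1

  cost <- qaly <- ly <- numeric(H + 1)
  cost[1] <- sum(prof$weight * prof$upfront_cost)

  fu <- followup_cost_by_year(params, seq_len(H))
  u_lrr <- params$utilities$lrr
  u_sal <- params$utilities$salvaged
  u_dm <- params$utilities$dm
  entry_lrr <- lrr_entry_cost(params)
  c_sal <- params$costs$salvage_surgery
  c_bsc <- params$costs$basic_supportive_care
  df <- discount_factor(cfg$discount_rate, seq_len(H))
  u_dfs <- vapply(seq_len(n_s), function(s)
    dfs_track_utility(params, prof$utility_track[s], seq_len(H)),
    numeric(H))                       # H x n_s

  for (t in seq_len(H)) {
    age <- cfg$median_age + t - 1
    for (s in seq_len(n_s)) {
      P <- transition_matrix(params, age, prof$dissected[s], prof$risk_class[s])
      m0 <- membership[t, , s]
      flows <- m0 * P                 # flows[i, j] = mass moving i -> j
      m1 <- colSums(flows)
      membership[t + 1, , s] <- m1
      w <- prof$weight[s]

      alive0 <- sum(m0[1:4]); alive1 <- sum(m1[1:4])
      u <- c(u_dfs[t, s], u_lrr, u_sal, u_dm, 0, 0)
      ly_t <- 0.5 * (alive0 + alive1)
      q_t <- 0.5 * (sum(u * m0) + sum(u * m1))
      c_t <- fu[t] * 0.5 * (m0[1] + m1[1]) +
        c_bsc * 0.5 * (m0[4] + m1[4]) +
        entry_lrr * (flows["DFS", "LRR"] + flows["SALVAGE", "LRR"]) +
        c_sal * flows["LRR", "SALVAGE"]

      ly[t + 1] <- ly[t + 1] + w * ly_t * df[t]
      qaly[t + 1] <- qaly[t + 1] + w * q_t * df[t]
      cost[t + 1] <- cost[t + 1] + w * c_t * df[t]
    }
  }

  structure(list(membership = membership, profiles = prof, cost = cost,
                 qaly = qaly, ly = ly, horizon = H, group = group,
                 discount_rate = cfg$discount_rate),
            class = "cohort_trace")
}

#' Aggregate cohort membership over strata
#' @param trace cohort_trace object
#' @return matrix (cycle 0..H) x state of cohort fractions
#' @export
trace_membership <- function(trace) {
  w <- trace$profiles$weight
  out <- matrix(0, nrow = trace$horizon + 1, ncol = 6,
                dimnames = list(NULL, slnb_states))
  for (s in seq_along(w)) out <- out + w[s] * trace$membership[, , s]
  out
}

#' Export a cohort trace as a long data.frame
#' @param trace cohort_trace object
#' @return data.frame with columns `cycle`, `state`, `track`, `fraction`
#' @export
trace_to_df <- function(trace) {
  prof <- trace$profiles
  do.call(rbind, lapply(seq_len(nrow(prof)), function(s) {
    m <- trace$membership[, , s]
    data.frame(
      cycle = rep(0:trace$horizon, times = 6),
      state = rep(slnb_states, each = trace$horizon + 1),
      track = paste(prof$group[s], prof$stratum[s], sep = ":"),
      fraction = prof$weight[s] * as.vector(m),
      stringsAsFactors = FALSE)
  }))
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> group", x$group, "-", x$horizon, "annual cycles,",
      nrow(x$profiles), "strata\n")
  cat("  discounted totals: cost", round(sum(x$cost)), "INR | LY",
      round(sum(x$ly), 3), "| QALY", round(sum(x$qaly), 3), "\n")
  invisible(x)
}
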