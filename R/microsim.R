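#' Individual-level Monte Carlo simulation of a treatment group
#'
#' Brute-force validation oracle for the cohort engine: each simulated
#' patient is assigned to a diagnostic stratum by the stratum weights, then
#' stepped through the annual transition structure patient by patient,
#' accruing costs, life-years and QALYs with its own accrual code (written
#' independently of [run_cohort()]) under the same conventions: upfront
#' costs at entry (undiscounted), trapezoidal half-cycle credit for state
#' occupancy (half credit in the cycle of a transition), recurrence
#' treatment charged on entry into LRR, salvage surgery on entry into the
#' salvaged state, supportive care while in distant metastasis, follow-up
#' panels while disease free, and end-of-cycle discounting.
#'
#' @param group `"I"`, `"II"` or `"III"`
#' @param params slnb_params object
#' @param n number of simulated patients (>= 1)
#' @param seed integer seed
#' @param horizon_years optional horizon override
#' @return list of per-quantity means and Monte Carlo standard errors:
#'   `mean_cost`, `se_cost`, `mean_ly`, `se_ly`, `mean_qaly`, `se_qaly`,
#'   plus `n` and `occupancy` (empirical state fractions per cycle)
#' @export
simulate_patients <- function(group, params, n, seed, horizon_years = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  cfg <- params$config
  H <- resolve_horizon(cfg, horizon_years)
  prof <- pathway_profiles(group, params)
  n_s <- nrow(prof)

  stratum <- sample.int(n_s, n, replace = TRUE, prob = prof$weight)
  state <- rep(1L, n)                    # 1=DFS ... 6=DEATH_OTHER

  cost <- prof$upfront_cost[stratum]     # cycle 0, undiscounted
  ly <- numeric(n)
  qaly <- numeric(n)

  # per-stratum DFS utility by model year (year x stratum)
  u_dfs <- vapply(seq_len(n_s), function(s)
    dfs_track_utility(params, prof$utility_track[s], seq_len(H)), numeric(H))
  u_state_fix <- c(NA, params$utilities$lrr, params$utilities$salvaged,
                   params$utilities$dm, 0, 0)
  fu <- followup_cost_by_year(params, seq_len(H))
  entry_lrr <- lrr_entry_cost(params)
  c_sal <- params$costs$salvage_surgery
  c_bsc <- params$costs$basic_supportive_care
  occupancy <- matrix(0, H + 1, 6, dimnames = list(NULL, slnb_states))
  occupancy[1, 1] <- 1

  util_of <- function(st, yr) {
    u <- u_state_fix[st]
    in_dfs <- which(st == 1L)
    if (length(in_dfs)) u[in_dfs] <- u_dfs[yr, stratum[in_dfs]]
    u
  }

  for (t in seq_len(H)) {
    age <- cfg$median_age + t - 1
    prev <- state
    nxt <- prev
    alive <- prev <= 4L
    # transition matrices differ only by (dissected, risk_class)
    combos <- unique(data.frame(d = prof$dissected, r = prof$risk_class))
    for (k in seq_len(nrow(combos))) {
      P <- transition_matrix(params, age, combos$d[k], combos$r[k])
      in_combo <- prof$dissected[stratum] == combos$d[k] &
        prof$risk_class[stratum] == combos$r[k]
      for (st in 1:4) {
        idx <- which(alive & in_combo & prev == st)
        if (length(idx))
          nxt[idx] <- sample.int(6, length(idx), replace = TRUE, prob = P[st, ])
      }
    }

    df <- 1 / (1 + cfg$discount_rate)^t
    u0 <- util_of(prev, t)
    u1 <- util_of(nxt, t)
    qaly <- qaly + df * 0.5 * (u0 + u1)
    ly <- ly + df * 0.5 * ((prev <= 4L) + (nxt <= 4L))
    ccost <- fu[t] * 0.5 * ((prev == 1L) + (nxt == 1L)) +
      c_bsc * 0.5 * ((prev == 4L) + (nxt == 4L)) +
      entry_lrr * (prev != 2L & nxt == 2L) +
      c_sal * (prev == 2L & nxt == 3L)
    cost <- cost + df * ccost
    state <- nxt
    occupancy[t + 1, ] <- tabulate(state, 6) / n
  }

  list(mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
       mean_ly = mean(ly), se_ly = stats::sd(ly) / sqrt(n),
       mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n),
       n = n, occupancy = occupancy)
}

#' Randomised but valid parameter fixture
#'
#' Generates a structurally valid parameter set with probabilities drawn in
#' [0.01, 0.6], coherently ordered utilities and positive costs; passes
#' [validate_parameters()] with zero violations. Used by property-style
#' tests exercising the cohort engine and microsimulation on inputs far
#' from the published base case.
#'
#' @param seed integer seed
#' @return slnb_params object
#' @export
random_parameter_fixture <- function(seed) {
  set.seed(seed)
  p <- table1_defaults()
  rp <- function(lo = 0.01, hi = 0.6) stats::runif(1, lo, hi)

  p$config$occult_metastasis_rate <- rp(0.05, 0.5)
  for (test in c("slnb", "endfs")) {
    p$accuracy[[test]]$sensitivity <- stats::runif(1, 0.5, 0.99)
    # keep the implied true-negative fraction feasible
    pmax_npv <- npv_from_spec(p$config$occult_metastasis_rate,
                              p$accuracy[[test]]$sensitivity, 1)
    p$accuracy[[test]]$npv <- stats::runif(1, 0.6, min(0.99, pmax_npv))
  }

  u <- p$utilities
  u$dfs_primary_resection <- stats::runif(1, 0.7, 0.95)
  u$snd_without_morbidity <- stats::runif(1, 0.7, 0.92)
  u$snd_with_morbidity <- u$snd_without_morbidity * stats::runif(1, 0.7, 1)
  u$mnd_without_morbidity <- stats::runif(1, 0.65, 0.9)
  u$mnd_with_morbidity <- u$mnd_without_morbidity * stats::runif(1, 0.7, 1)
  u$dfs_after_neck_dissection <- stats::runif(1, 0.6, 0.9)
  u$lrr <- stats::runif(1, 0.4, 0.8)
  u$dm <- stats::runif(1, 0.3, 0.7)
  u$salvaged <- stats::runif(1, 0.2, 0.6)
  u$morbidity_weight <- stats::runif(1, 0.05, 0.4)
  p$utilities <- u

  tr <- p$transitions
  repeat {
    tr$dfs_to_lrr_node_pos <- rp(0.01, 0.2)
    tr$dfs_to_lrr_node_neg <- rp(0.01, 0.15)
    tr$dfs_to_dm_node_pos <- rp(0.005, 0.1)
    tr$dfs_to_dm_node_neg <- rp(0.002, 0.05)
    tr$lrr_to_dm <- rp(0.02, 0.2)
    tr$lrr_to_salvage_dissected <- rp(0.02, 0.25)
    tr$lrr_to_salvage_undissected <- rp(0.02, 0.3)
    tr$lrr_to_death_cancer <- rp(0.2, 0.6)
    tr$salvage_to_lrr_dissected <- rp(0.02, 0.3)
    tr$salvage_to_lrr_undissected <- rp(0.02, 0.3)
    tr$salvage_to_dm_dissected <- rp(0.01, 0.2)
    tr$salvage_to_dm_undissected <- rp(0.01, 0.2)
    ok <- tr$lrr_to_dm + max(tr$lrr_to_salvage_dissected,
                             tr$lrr_to_salvage_undissected) +
      tr$lrr_to_death_cancer <= 0.84   # head-room for background mortality
    if (ok) break
  }
  tr$dm_median_survival_months <- stats::runif(1, 6, 36)
  p$transitions <- tr

  for (f in c("slnb", "mnd", "snd", "salvage_surgery", "frozen_section",
              "basic_supportive_care", "high_end_radiology"))
    p$costs[[f]] <- stats::runif(1, 1000, 80000)
  p$costs$lrr_salvage_fraction <- rp(0.1, 0.6)
  p$costs$adjuvant_chemo_fraction <- rp(0.2, 0.6)

  # keep the registered distribution means consistent with the drawn values
  dd <- p$distributions
  for (i in seq_len(nrow(dd))) {
    v <- get_param(p, dd$param[i])
    if (is.numeric(v) && length(v) == 1 && !is.na(dd$mean[i])) {
      dd$mean[i] <- v
      if (!is.na(dd$low[i])) {
        dd$low[i] <- if (dd$family[i] == "beta") max(0, v * 0.8) else v * 0.8
        dd$high[i] <- if (dd$family[i] == "beta") min(1, v * 1.2) else v * 1.2
      }
    }
  }
  p$distributions <- dd
  assert_valid_parameters(p)
}
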