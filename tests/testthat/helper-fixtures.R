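# toy parameter sets for closed-form checks

# single-state survival chain: no cancer transitions, constant background
# mortality, utility 1 everywhere, all costs zero
toy_death_chain <- function(death_prob, discount = 0) {
  p <- table1_defaults()
  for (f in c("dfs_to_lrr_node_pos", "dfs_to_lrr_node_neg",
              "dfs_to_dm_node_pos", "dfs_to_dm_node_neg",
              "lrr_to_dm", "lrr_to_salvage_dissected",
              "lrr_to_salvage_undissected", "lrr_to_death_cancer",
              "salvage_to_lrr_dissected", "salvage_to_lrr_undissected",
              "salvage_to_dm_dissected", "salvage_to_dm_undissected"))
    p$transitions[[f]] <- 0
  p$transitions$dm_median_survival_months <- 1e12
  p$transitions$all_cause_mortality[] <- death_prob
  for (f in setdiff(names(p$utilities),
                    c("morbidity_weight", "utility_window_years")))
    p$utilities[[f]] <- 1
  p$utilities$morbidity_weight <- 0
  for (f in c("slnb", "mnd", "snd", "salvage_surgery", "frozen_section",
              "rt_2d", "rt_3dcrt", "rt_imrt", "cisplatin_weekly",
              "basic_supportive_care", "high_end_radiology",
              "cbc", "lft", "rft", "electrolytes", "tsh"))
    p$costs[[f]] <- 0
  p$config$discount_rate <- discount
  p
}

# params with cancer transitions zeroed but everything else at base
no_cancer_params <- function() {
  p <- table1_defaults()
  for (f in c("dfs_to_lrr_node_pos", "dfs_to_lrr_node_neg",
              "dfs_to_dm_node_pos", "dfs_to_dm_node_neg"))
    p$transitions[[f]] <- 0
  p
}

# a feasible (prevalence, sensitivity, npv) triple from (p, se, sp)
feasible_triple <- function(p, se, sp) {
  list(p = p, se = se, npv = npv_from_spec(p, se, sp))
}

expect_within_se <- function(observed, expected, se, k = 3) {
  expect_lt(abs(observed - expected), k * se)
}
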