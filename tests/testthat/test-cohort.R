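test_that("transition rows follow the published rates plus background mortality", {
  p <- table1_defaults()

  P <- transition_matrix(p, age = 52, dissected = TRUE, risk_class = "node_pos")
  expect_equal(P["DEATH_CANCER", "DEATH_CANCER"], 1)
  expect_equal(P["DEATH_OTHER", "DEATH_OTHER"], 1)
  # LRR stay remainder = 1 - (dm + salvage + cancer death + background)
  expect_equal(P["LRR", "LRR"], 1 - (0.076 + 0.083 + 0.613 + 0.008),
               tolerance = 1e-12)
  expect_equal(P["LRR", "LRR"], 0.220, tolerance = 1e-12)

  Pn <- transition_matrix(p, 52, TRUE, "node_neg")
  expect_equal(Pn["DFS", "LRR"], 0.043)
  expect_equal(Pn["DFS", "DM"], 0.004)
  expect_equal(Pn["DFS", "DEATH_OTHER"], 0.008)
  expect_equal(Pn["DFS", "DFS"], 0.945, tolerance = 1e-12)

  Pu <- transition_matrix(p, 52, FALSE, "node_neg")
  expect_equal(Pu["LRR", "SALVAGE"], 0.146)   # undissected salvage rate
  expect_equal(Pu["SALVAGE", "LRR"], 0.115)

  # DM exit uses the exponential annual probability from the 7.5-month median
  expect_equal(P["DM", "DEATH_CANCER"], annual_from_median_survival(7.5))

  # all rows are distributions at every age and pathway combination
  for (age in c(50, 64, 73, 81, 99))
    for (d in c(TRUE, FALSE))
      for (rc in c("node_pos", "node_neg")) {
        M <- transition_matrix(p, age, d, rc)
        expect_equal(unname(rowSums(M)), rep(1, 6), tolerance = 1e-12)
        expect_true(all(M >= 0))
      }
})

test_that("rows exceeding unit mass renormalise with a warning", {
  p <- table1_defaults()
  p$transitions$lrr_to_death_cancer <- 0.8   # 0.076+0.146+0.8+0.151 > 1
  expect_warning(
    M <- transition_matrix(p, 73, FALSE, "node_neg"), "renormalising")
  expect_equal(unname(rowSums(M)), rep(1, 6), tolerance = 1e-12)
  expect_equal(M["LRR", "LRR"], 0)
})

test_that("cohort mass is conserved and death mass is monotone", {
  fixtures <- list(table1_defaults(), random_parameter_fixture(11),
                   random_parameter_fixture(12))
  for (p in fixtures)
    for (g in c("I", "II", "III")) {
      tr <- run_cohort(g, p)
      m <- trace_membership(tr)
      expect_equal(unname(rowSums(m)), rep(1, tr$horizon + 1),
                   tolerance = 1e-10, info = g)
      expect_true(all(m >= -1e-15))
      dead <- m[, "DEATH_CANCER"] + m[, "DEATH_OTHER"]
      expect_true(all(diff(dead) >= -1e-12), info = g)
      # per-cycle accruals are non-negative
      expect_true(all(tr$cost >= 0) && all(tr$qaly >= 0) && all(tr$ly >= 0))
    }
})

test_that("half-life toy chain accrues 1.5 life-years under trapezoidal HCC", {
  # survival halves each year; undiscounted trapezoid sum = 0.5 + sum(0.5^t)
  p <- toy_death_chain(0.5)
  for (g in c("I", "II")) {
    r <- run_group(g, p)
    expect_equal(r$total_ly, 1.5, tolerance = 1e-9, info = g)
    expect_equal(r$total_qaly, 1.5, tolerance = 1e-9, info = g)
    expect_equal(r$total_cost, 0)
  }
  # certain death in the first cycle leaves exactly half a year
  r1 <- run_group("II", toy_death_chain(1))
  expect_equal(r1$total_ly, 0.5, tolerance = 1e-12)
})

test_that("with cancer switched off, life-years equal the mortality annuity", {
  p <- no_cancer_params()
  r <- run_group("II", p)
  # independent annuity computation from the life table alone
  H <- 50
  ages <- 50 + 0:(H - 1)
  surv <- cumprod(1 - mortality_lookup(ages, p$transitions))
  S <- c(1, surv)
  annuity <- sum((0.5 * (S[1:H] + S[2:(H + 1)])) / 1.03^(1:H))
  expect_equal(r$total_ly, annuity, tolerance = 1e-10)
  # everyone stays disease free
  m <- trace_membership(r$trace)
  expect_equal(m[, "LRR"], rep(0, H + 1))
  expect_equal(unname(m[H + 1, "DFS"]), S[H + 1], tolerance = 1e-12)
})

test_that("discounting can only reduce accrued QALYs", {
  p <- table1_defaults()
  p0 <- p; p0$config$discount_rate <- 0
  for (g in c("I", "III")) {
    expect_gte(run_group(g, p0)$total_qaly, run_group(g, p)$total_qaly)
  }
})

test_that("a zero utility window makes SND and MND tracks equivalent", {
  # Groups II and III then differ only through dissection type and cost
  p <- table1_defaults()
  p$utilities$utility_window_years <- 0
  r2 <- run_group("II", p)
  r3 <- run_group("III", p)
  expect_equal(r2$total_qaly, r3$total_qaly, tolerance = 1e-10)
  expect_equal(r2$total_ly, r3$total_ly, tolerance = 1e-12)
})

test_that("DFS utility tracks honour the post-surgical window", {
  p <- table1_defaults()
  u <- p$utilities
  mixed_snd <- 0.17 * u$snd_with_morbidity + 0.83 * u$snd_without_morbidity
  expect_equal(dfs_track_utility(p, "snd", 1:6),
               c(rep(mixed_snd, 5), u$dfs_after_neck_dissection))
  expect_equal(dfs_track_utility(p, "primary_resection_only", c(1, 30)),
               rep(u$dfs_primary_resection, 2))
  expect_error(dfs_track_utility(p, "nope", 1), "unknown utility track")
})

test_that("trace exports carry full per-cycle stratum detail", {
  p <- table1_defaults()
  tr <- run_cohort("I", p, horizon_years = 10)
  df <- trace_to_df(tr)
  expect_equal(nrow(df), 11 * 6 * 4)
  agg <- as.vector(tapply(df$fraction, df$cycle, sum))
  expect_equal(agg, rep(1, 11), tolerance = 1e-10)
})
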