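test_that("published base estimates are reproduced cell for cell", {
  p <- table1_defaults()

  expected <- c(
    "config.median_age" = 50,
    "config.occult_metastasis_rate" = 0.23,
    "accuracy.slnb.sensitivity" = 0.81,
    "accuracy.slnb.npv" = 0.93,
    "accuracy.endfs.sensitivity" = 0.84,
    "accuracy.endfs.npv" = 0.93,
    "utilities.snd_without_morbidity" = 0.862,
    "utilities.snd_with_morbidity" = 0.747,
    "utilities.mnd_without_morbidity" = 0.821,
    "utilities.mnd_with_morbidity" = 0.711,
    "utilities.dfs_primary_resection" = 0.891,
    "utilities.dfs_after_neck_dissection" = 0.819,
    "utilities.lrr" = 0.659,
    "utilities.dm" = 0.508,
    "utilities.salvaged" = 0.264,
    "transitions.dfs_to_lrr_node_pos" = 0.065,
    "transitions.dfs_to_lrr_node_neg" = 0.043,
    "transitions.dfs_to_dm_node_pos" = 0.0136,
    "transitions.dfs_to_dm_node_neg" = 0.004,
    "transitions.lrr_to_dm" = 0.076,
    "transitions.lrr_to_salvage_dissected" = 0.083,
    "transitions.lrr_to_salvage_undissected" = 0.146,
    "transitions.lrr_to_death_cancer" = 0.613,
    "transitions.salvage_to_lrr_dissected" = 0.136,
    "transitions.salvage_to_lrr_undissected" = 0.115,
    "transitions.salvage_to_dm_dissected" = 0.032,
    "transitions.salvage_to_dm_undissected" = 0.030,
    "transitions.dm_median_survival_months" = 7.5,
    "costs.cbc" = 155, "costs.lft" = 259, "costs.rft" = 259,
    "costs.electrolytes" = 460, "costs.tsh" = 104,
    "costs.cisplatin_weekly" = 2900, "costs.cisplatin_high" = 11950,
    "costs.rt_2d" = 13390, "costs.rt_3dcrt" = 25540, "costs.rt_imrt" = 85050,
    "costs.high_end_radiology" = 5560, "costs.paclitaxel" = 14380,
    "costs.paclitaxel_carboplatin" = 17540,
    "costs.basic_supportive_care" = 10215,
    "costs.slnb" = 28670, "costs.mnd" = 36870, "costs.snd" = 26040,
    "costs.salvage_surgery" = 60550, "costs.frozen_section" = 8500,
    "config.wtp_threshold" = 211725, "config.inr_per_usd" = 83.68,
    "config.discount_rate" = 0.03)
  for (nm in names(expected))
    expect_equal(get_param(p, nm), unname(expected[nm]), info = nm)

  expect_equal(
    unname(p$transitions$all_cause_mortality),
    c(0.008, 0.013, 0.019, 0.029, 0.151, 0.066, 0.103))

  # distribution families as printed
  dd <- p$distributions
  fam <- function(nm) dd$family[dd$param == nm]
  expect_equal(fam("config.occult_metastasis_rate"), "beta")
  expect_equal(fam("utilities.dm"), "beta")
  expect_equal(fam("costs.cbc"), "normal")
  expect_equal(fam("costs.slnb"), "gamma")
  expect_equal(fam("transitions.lrr_to_dm"), "dirichlet")
  expect_equal(fam("config.median_age"), "fixed")

  # degenerate printed interval for the SLNB package rate is kept as
  # metadata while the working bounds are the +/-20% fallback
  expect_equal(unname(p$meta$slnb_cost_printed_bounds), c(25900, 25900))
  expect_equal(dd$low[dd$param == "costs.slnb"], 28670 * 0.8)
  expect_equal(dd$high[dd$param == "costs.slnb"], 28670 * 1.2)
})

test_that("validation reports violations without raising", {
  expect_identical(nrow(validate_parameters(table1_defaults())), 0L)

  p <- table1_defaults()
  p$utilities$snd_with_morbidity <- 0.9    # > snd_without_morbidity = 0.862
  v <- validate_parameters(p)
  expect_equal(nrow(v), 1L)
  expect_match(v$field, "snd_with_morbidity")
  expect_match(v$rule, "must not exceed")

  p <- table1_defaults()
  p$costs$rt_modality_weights <- c(0.5, 0.5, 0.5)
  v <- validate_parameters(p)
  expect_equal(nrow(v), 1L)
  expect_match(v$rule, "sum to 1")

  p <- table1_defaults()
  p$transitions$dfs_to_lrr_node_pos <- 1.2
  v <- validate_parameters(p)
  expect_true(any(grepl("dfs_to_lrr_node_pos", v$field)))

  # validate is total: structurally damaged input still returns a data.frame
  broken <- structure(list(accuracy = list()), class = "slnb_params")
  v <- validate_parameters(broken)
  expect_s3_class(v, "data.frame")
  expect_gt(nrow(v), 0)
})

test_that("parameter sets round-trip through JSON unchanged", {
  p <- table1_defaults()
  f <- withr::local_tempfile(fileext = ".json")
  save_parameter_set(p, f)
  q <- load_parameter_set(f)
  for (comp in c("accuracy", "utilities", "transitions", "costs", "config"))
    expect_equal(q[[comp]], p[[comp]], info = comp)
  expect_equal(q$distributions$mean, p$distributions$mean)
  expect_equal(q$distributions$param, p$distributions$param)
})

test_that("malformed parameter files are rejected with the field named", {
  p <- table1_defaults()
  f <- withr::local_tempfile(fileext = ".json")

  save_parameter_set(p, f)
  raw <- jsonlite::read_json(f)
  raw$surprise <- 1
  jsonlite::write_json(raw, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_parameter_set(f), "surprise")

  raw$surprise <- NULL
  raw$costs$mnd <- NULL
  jsonlite::write_json(raw, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_parameter_set(f), "costs.mnd")

  p2 <- table1_defaults()
  p2$transitions$dfs_to_lrr_node_pos <- 1.2
  jsonlite::write_json(unclass(p2), f, auto_unbox = TRUE, digits = NA,
                       na = "null")
  expect_error(load_parameter_set(f), "dfs_to_lrr_node_pos")

  expect_error(load_parameter_set(file.path(tempdir(), "nope.json")),
               "not found")
})
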