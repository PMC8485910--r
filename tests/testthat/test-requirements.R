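drv_fixture <- function(targets, lower = NA_real_, upper = NA_real_,
                        alt_veg = NA_real_, alt_vegan = NA_real_) {
  tibble::tibble(
    nutrient_id = "calcium", sex = rep(c("F", "M"), each = 2),
    age_group = rep(c("young", "old"), 2), unit = "mg",
    target = targets, lower_safe = lower, upper_safe = upper,
    alt_target_vegetarian = alt_veg, alt_target_vegan = alt_vegan)
}

demo_fixture <- function(pops) {
  tibble::tibble(
    region_id = "w", sex = rep(c("F", "M"), each = 2),
    age_group = rep(c("young", "old"), 2), year = 2018L,
    population = pops)
}

test_that("targets are population-weighted means over strata", {
  # identical DRVs across strata weight to themselves
  t1 <- weighted_targets(drv_fixture(rep(1000, 4)),
                         demo_fixture(c(3, 9, 1, 7)), 2018)
  expect_equal(t1$target, 1000)

  # two effective strata with populations 1 and 3: (800*1 + 1200*3)/4
  drv <- drv_fixture(c(800, 1200, 800, 1200))
  demo <- demo_fixture(c(0.5, 1.5, 0.5, 1.5))
  expect_equal(weighted_targets(drv, demo, 2018)$target, 1100)

  # missing stratum in the DRV table is an error naming it
  err <- expect_error(
    weighted_targets(drv[-1, ], demo, 2018),
    class = "deltafood_validation_error")
  expect_match(conditionMessage(err), "F/young")
})

test_that("vegetarian and vegan modes substitute alternate targets", {
  drv <- drv_fixture(rep(10, 4), alt_veg = rep(15, 4),
                     alt_vegan = rep(18, 4))
  demo <- demo_fixture(c(1, 2, 3, 4))
  expect_equal(weighted_targets(drv, demo, 2018)$target, 10)
  expect_equal(weighted_targets(drv, demo, 2018, "vegetarian")$target, 15)
  expect_equal(weighted_targets(drv, demo, 2018, "vegan")$target, 18)
  # 1.5x alternates scale the weighted target by 1.5 under any weights
  expect_equal(weighted_targets(drv, demo, 2018, "vegetarian")$target,
               1.5 * weighted_targets(drv, demo, 2018)$target)
  # nutrients without alternates are untouched in vegan mode
  no_alt <- drv_fixture(rep(10, 4))
  expect_equal(weighted_targets(no_alt, demo, 2018, "vegan")$target, 10)
})

test_that("weighted targets are convex combinations of stratum DRVs", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      targets <- stats::runif(4, 500, 1500)
      pops <- stats::runif(4, 0.1, 10)
      out <- weighted_targets(drv_fixture(targets), demo_fixture(pops),
                              2018)
      expect_gte(out$target, min(targets))
      expect_lte(out$target, max(targets))
    }
  })
  # bounds require every stratum; otherwise they are dropped
  part <- drv_fixture(rep(1000, 4), lower = c(600, NA, 600, 600),
                      upper = rep(2500, 4))
  out <- weighted_targets(part, demo_fixture(rep(1, 4)), 2018)
  expect_true(is.na(out$lower_safe))
  expect_equal(out$upper_safe, 2500)
})

test_that("gap and excess percentages follow the report formulas", {
  targets <- structure(
    tibble::tibble(nutrient_id = c("calcium", "vitamin_e"),
                   unit = c("mg", "mg"), target = c(1000, 12),
                   lower_safe = c(700, NA), upper_safe = c(2500, NA)),
    class = c("delta_target_set", "tbl_df", "tbl", "data.frame"))
  supply <- tibble::tibble(nutrient_id = c("calcium", "vitamin_e"),
                           unit = c("mg", "mg"), supply = c(640, 12))
  rep <- adequacy_report(supply, targets)
  calcium <- rep[rep$nutrient_id == "calcium", ]
  expect_equal(calcium$pct_of_target, 64)
  expect_equal(calcium$gap_pct, 36)
  expect_true(calcium$material)
  ve <- rep[rep$nutrient_id == "vitamin_e", ]
  expect_equal(ve$gap_pct, 0)
  expect_equal(ve$excess_pct, NA_real_)

  over <- adequacy_report(
    tibble::tibble(nutrient_id = "calcium", unit = "mg", supply = 2750),
    targets[1, ])
  expect_equal(over$excess_pct, 10)
  expect_equal(over$gap_pct, 0)

  # sub-threshold gaps are reported but not material
  small <- adequacy_report(
    tibble::tibble(nutrient_id = "calcium", unit = "mg", supply = 960),
    targets[1, ])
  expect_equal(small$gap_pct, 4)
  expect_false(small$material)

  # a supplied nutrient without a target warns and keeps its row
  expect_warning(
    orphan <- adequacy_report(
      tibble::tibble(nutrient_id = "boron", unit = "mg", supply = 1),
      targets), "boron")
  expect_true("boron" %in% orphan$nutrient_id)
  expect_true(is.na(orphan$gap_pct[orphan$nutrient_id == "boron"]))

  expect_error(
    adequacy_report(
      tibble::tibble(nutrient_id = "calcium", unit = "g", supply = 1),
      targets),
    class = "deltafood_validation_error")
})

test_that("gap and excess are never simultaneously positive", {
  for (seed in c(3, 13)) {
    w <- make_world(seed = seed, shape = "mini")
    run <- run_scenario(w)
    both <- !is.na(run$nutrients$excess_pct) &
      run$nutrients$gap_pct > 0 & run$nutrients$excess_pct > 0
    expect_false(any(both))
  }
})

test_that("scenario comparison reports signed deltas", {
  w <- analytic()
  b <- prepare_baseline(w)
  a <- run_scenario(w, scenario(name = "a"), baseline = b)
  same <- compare_scenarios(a, a)
  expect_true(all(same$nutrients$delta_supply == 0))
  expect_true(all(same$nutrients$delta_gap_pct == 0))
  expect_true(all(same$groups$delta_production_t == 0))

  halved <- run_scenario(
    w, scenario(name = "b",
                groups = list(cereals = list(multiplier = 0.5)),
                supply_chain_waste_multiplier = 1), baseline = b)
  cmp <- compare_scenarios(a, halved)
  expect_equal(
    cmp$groups$delta_production_t[cmp$groups$group_id == "cereals"],
    -750)
  expect_true(all(cmp$nutrients$delta_supply <= 0))
  expect_equal(tidy(cmp), cmp$nutrients)
})

test_that("diet-mode switching flows through to run-level iron targets", {
  w <- analytic()
  b <- prepare_baseline(w)
  omni <- run_scenario(w, scenario(), baseline = b)
  vegan <- run_scenario(
    w, scenario(groups = list(fish = list(multiplier = 0))), baseline = b)
  expect_identical(vegan$scenario$diet_mode, "vegan")
  iron_omni <- omni$targets$target[omni$targets$nutrient_id == "iron"]
  iron_vegan <- vegan$targets$target[vegan$targets$nutrient_id == "iron"]
  expect_equal(iron_vegan, 1.8 * iron_omni)
  lys <- function(r) r$targets$target[r$targets$nutrient_id == "lysine"]
  expect_equal(lys(vegan), lys(omni))
})
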