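# Shared fixtures, built in code at test time.

# The analytic world is deterministic; build it once per test run.
analytic <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- make_analytic_world()
    w
  }
})

# Hand-derived closed forms for the analytic world's 2018 baseline run
# (derived step by step in the methods vignette). Consumed edible tons:
#   wheat: 1000 - 100 (feed) - 50 (loss) - 50 (nonfood) = 800 edible,
#          minus 14% in-home waste -> 688
#   maize: 500 - 100 - 50 - 0 = 350; minus 20% inedible -> 280;
#          minus 14% -> 240.8
#   fish:  600 - 0 - 60 - 0 = 540; minus 50% inedible -> 270;
#          minus 7% -> 251.1
analytic_consumed <- c(maize = 240.8, wheat = 688, fish = 251.1)
analytic_population <- 10000
analytic_pc <- analytic_consumed * 1e6 / analytic_population / 365

# Minimal single-item world builder for targeted cascade arithmetic.
one_item_world <- function(feed_fraction = 0.2, loss_fraction = 0.1,
                           nonfood_fraction = 0.05,
                           inedible_fraction = 0.1,
                           in_home_fraction = 0.1,
                           production = 1000) {
  years <- 2014:2017
  balance <- tibble::tibble(
    item_id = "crop", group_id = "plants", year = as.integer(years),
    production_t = rep(production, 4),
    feed_t = feed_fraction * production,
    supply_chain_loss_t = loss_fraction * production,
    nonfood_t = nonfood_fraction * production)
  animal <- tibble::tibble(
    item_id = "beef", group_id = "meat", year = as.integer(years),
    production_t = 500, feed_t = 0, supply_chain_loss_t = 0,
    nonfood_t = 0)
  items <- tibble::tibble(
    item_id = c("crop", "beef"), group_id = c("plants", "meat"),
    origin = c("plant", "animal"),
    inedible_fraction = c(inedible_fraction, 0)) |>
    tidyr::crossing(tibble::tibble(
      nutrient_id = c("energy", "protein"), unit = c("kcal", "g"))) |>
    dplyr::mutate(
      density_per_100g = ifelse(nutrient_id == "energy", 200, 10),
      digestibility = ifelse(nutrient_id == "protein", 0.8, 1))
  waste <- tibble::tibble(region_id = "world",
                          group_id = c("plants", "meat"),
                          waste_fraction = c(in_home_fraction, 0))
  demographics <- tidyr::crossing(
    region_id = "world", sex = c("F", "M"), age_group = "adult",
    year = c(2018L, 2030L)) |>
    dplyr::mutate(population = ifelse(year == 2018L, 500, 1000))
  drv <- tidyr::crossing(
    tibble::tibble(nutrient_id = c("energy", "protein"),
                   unit = c("kcal", "g"), target = c(2000, 50)),
    sex = c("F", "M"), age_group = "adult") |>
    dplyr::mutate(lower_safe = NA_real_, upper_safe = NA_real_,
                  alt_target_vegetarian = NA_real_,
                  alt_target_vegan = NA_real_) |>
    dplyr::select(nutrient_id, sex, age_group, unit, target, lower_safe,
                  upper_safe, alt_target_vegetarian, alt_target_vegan)
  groups <- tibble::tibble(group_id = c("plants", "meat"),
                           origin = c("plant", "animal"),
                           animal_food_type = c(NA, "meat_fish"))
  regions <- tibble::tibble(region_id = "world")
  validate_world(structure(
    list(balance = balance |> dplyr::bind_rows(animal), items = items,
         waste = waste, demographics = demographics, drv = drv,
         groups = groups, regions = regions),
    class = "delta_world"))
}

expect_run_equals_oracle <- function(world, sc, tol = 1e-9) {
  run <- tryCatch(run_scenario(world, sc), error = identity)
  ref <- tryCatch(oracle_evaluate(world, sc), error = identity)
  if (inherits(run, "error") || inherits(ref, "error")) {
    expect_s3_class(run, "deltafood_infeasible_error")
    expect_s3_class(ref, "deltafood_infeasible_error")
    return(invisible(FALSE))
  }
  mass_cols <- c("production_t", "feed_t", "supply_chain_loss_t",
                 "nonfood_t", "inedible_t", "in_home_waste_t",
                 "consumed_edible_t", "per_capita_g_day")
  expect_equal(run$mass$item_id, ref$mass$item_id)
  for (col in mass_cols) {
    expect_equal(run$mass[[col]], ref$mass[[col]], tolerance = tol)
  }
  expect_equal(run$nutrients$nutrient_id, ref$nutrients$nutrient_id)
  for (col in c("supply", "target", "lower_safe", "upper_safe",
                "pct_of_target", "gap_pct", "excess_pct")) {
    expect_equal(run$nutrients[[col]], ref$nutrients[[col]],
                 tolerance = tol)
  }
  for (col in c("wasted_amount", "pct_of_target", "plant_share_pct",
                "animal_share_pct")) {
    expect_equal(run$waste[[col]], ref$waste[[col]], tolerance = tol)
  }
  expect_identical(run$scenario$diet_mode, ref$diet_mode)
  invisible(TRUE)
}
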