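#' The analytic miniature world
#'
#' A fixed, seed-free world of 2 food groups and 3 items (wheat and maize
#' in a plant `cereals` group; `fish` as the sole animal group) with
#' round-number masses, fractions, densities and demographics, chosen so
#' that every pipeline output has a short closed form. Each item's
#' production history is exactly affine and the two cereal histories are
#' proportional, so the baseline-year extrapolation is exact and agrees
#' with the pooled item shares: wheat 1000 t, maize 500 t, fish 600 t in
#' 2018. The baseline cascade then gives consumed edible masses of 688 t
#' (wheat), 240.8 t (maize) and 251.1 t (fish) for the 10,000-person 2018
#' population — see the package vignette for the full hand derivation.
#'
#' @param dir Optional directory; when given, the seven CSV tables are
#'   written there (byte-identical on regeneration).
#' @return The `delta_world`, invisibly when `dir` is given.
#' @export
make_analytic_world <- function(dir = NULL) {
  years <- 2014:2017
  balance <- bind_rows(
    tibble(item_id = "wheat", group_id = "cereals", year = years,
           production_t = c(600, 700, 800, 900)),
    tibble(item_id = "maize", group_id = "cereals", year = years,
           production_t = c(300, 350, 400, 450)),
    tibble(item_id = "fish", group_id = "fish", year = years,
           production_t = rep(600, 4))
  ) |>
    mutate(
      feed_t = case_when(.data$item_id == "wheat" ~ 0.10,
                         .data$item_id == "maize" ~ 0.20,
                         TRUE ~ 0) * .data$production_t,
      supply_chain_loss_t = case_when(.data$item_id == "wheat" ~ 0.05,
                                      TRUE ~ 0.10) * .data$production_t,
      nonfood_t = case_when(.data$item_id == "wheat" ~ 0.05,
                            TRUE ~ 0) * .data$production_t,
      year = as.integer(.data$year)
    )

  item_scalar <- tibble(
    item_id = c("wheat", "maize", "fish"),
    group_id = c("cereals", "cereals", "fish"),
    origin = c("plant", "plant", "animal"),
    inedible_fraction = c(0, 0.2, 0.5)
  )
  nutrients <- tibble(
    nutrient_id = c("energy", "protein", "lysine", "calcium", "iron",
                    "zinc"),
    unit = c("kcal", "g", "g", "mg", "mg", "mg")
  )
  density <- tibble(
    item_id = rep(c("wheat", "maize", "fish"), each = 6),
    nutrient_id = rep(nutrients$nutrient_id, 3),
    density_per_100g = c(340, 12, 0.30, 30, 3.5, 2.6,
                         360, 9, 0.25, 10, 2.7, 2.2,
                         120, 20, 1.80, 15, 0.5, 0.5),
    digestibility = c(1, 0.80, 0.80, 1, 1, 1,
                      1, 0.75, 0.75, 1, 1, 1,
                      1, 0.95, 0.95, 1, 1, 1)
  )
  items <- item_scalar |>
    inner_join(density, by = "item_id") |>
    inner_join(nutrients, by = "nutrient_id") |>
    select("item_id", "group_id", "origin", "inedible_fraction",
           "nutrient_id", "unit", "density_per_100g", "digestibility")

  waste <- tibble(
    region_id = rep(c("north", "south"), each = 2),
    group_id = rep(c("cereals", "fish"), 2),
    waste_fraction = c(0.10, 0.05, 0.20, 0.10)
  )

  demographics <- tidyr::crossing(
    region_id = c("north", "south"), sex = c("F", "M"),
    age_group = c("child", "adult"), year = c(2018L, 2030L)
  ) |>
    mutate(population = ifelse(.data$region_id == "north", 1500, 1000) *
             ifelse(.data$year == 2030L, 1.2, 1))

  drv_base <- tibble(
    nutrient_id = rep(nutrients$nutrient_id, each = 2),
    age_group = rep(c("child", "adult"), 6),
    target = c(1800, 2200,   # energy
               30, 50,       # protein
               1.2, 2.1,     # lysine
               800, 950,     # calcium
               8, 11,        # iron
               6, 9.4),      # zinc
    lower_safe = c(1400, 1700, 25, 40, NA, NA, 600, 700, NA, NA, NA, NA),
    upper_safe = c(2600, 3200, NA, NA, NA, NA, 2500, 2500, NA, NA, NA, NA),
    alt_target_vegetarian = c(NA, NA, NA, NA, NA, NA, NA, NA,
                              12, 16.5, 9, 14.1),
    alt_target_vegan = c(NA, NA, NA, NA, NA, NA, NA, NA,
                         14.4, 19.8, 10.8, 16.92)
  )
  drv <- tidyr::crossing(sex = c("F", "M"), drv_base) |>
    inner_join(nutrients, by = "nutrient_id") |>
    select("nutrient_id", "sex", "age_group", "unit", "target",
           "lower_safe", "upper_safe", "alt_target_vegetarian",
           "alt_target_vegan") |>
    arrange(.data$nutrient_id, .data$sex, .data$age_group)

  groups <- tibble(group_id = c("cereals", "fish"),
                   origin = c("plant", "animal"),
                   animal_food_type = c(NA, "meat_fish"))
  regions <- tibble(region_id = c("north", "south"))

  world <- validate_world(new_world(
    balance = balance, items = items, waste = waste,
    demographics = demographics, drv = drv, groups = groups,
    regions = regions))
  if (!is.null(dir)) {
    write_world(world, dir)
    return(invisible(world))
  }
  world
}
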