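# Nutrient vocabulary used by generated worlds. The mini set keeps runs
# small; the full set carries the macronutrients, 7 indispensable amino
# acids and 17 vitamins/minerals typical of reference-intake tables.
fixture_nutrients <- function(full = FALSE) {
  mini <- tibble(
    nutrient_id = c("energy", "protein", "lysine", "calcium", "iron",
                    "zinc"),
    unit = c("kcal", "g", "g", "mg", "mg", "mg"),
    density_lo = c(50, 1, 0.02, 5, 0.2, 0.2),
    density_hi = c(600, 30, 1.8, 300, 6, 6),
    target_lo = c(1800, 35, 1, 700, 7, 6),
    target_hi = c(2400, 60, 3, 1100, 15, 11),
    digestible = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  if (!full) return(mini)
  iaa <- c("lysine", "methionine", "threonine", "tryptophan",
           "isoleucine", "leucine", "valine")
  macro <- c("energy", "protein", "fat", "carbohydrate", "fiber")
  micro <- c("calcium", "iron", "zinc", "potassium", "magnesium",
             "phosphorus", "vitamin_a", "vitamin_b12", "vitamin_c",
             "vitamin_d", "vitamin_e", "thiamin", "riboflavin", "niacin",
             "folate", "vitamin_b6", "selenium")
  tibble(nutrient_id = c(macro, iaa, micro)) |>
    mutate(
      unit = case_when(
        .data$nutrient_id == "energy" ~ "kcal",
        .data$nutrient_id %in% c(macro[-1], iaa) ~ "g",
        .data$nutrient_id %in% c("vitamin_a", "vitamin_d", "vitamin_b12",
                                 "folate", "selenium") ~ "ug",
        TRUE ~ "mg"),
      density_lo = ifelse(.data$nutrient_id == "energy", 50, 0.01),
      density_hi = case_when(
        .data$nutrient_id == "energy" ~ 600,
        .data$nutrient_id %in% c("fat", "carbohydrate", "protein") ~ 40,
        .data$nutrient_id %in% c("fiber") ~ 15,
        .data$nutrient_id %in% iaa ~ 2,
        TRUE ~ 100),
      target_lo = case_when(
        .data$nutrient_id == "energy" ~ 1800,
        .data$nutrient_id %in% c("protein", "fat", "carbohydrate") ~ 30,
        .data$nutrient_id == "fiber" ~ 20,
        .data$nutrient_id %in% iaa ~ 0.5,
        TRUE ~ 1),
      target_hi = 2.5 * .data$target_lo + 1,
      digestible = .data$nutrient_id %in% c("protein", iaa)
    )
}

fixture_groups <- function(n_groups, full = FALSE) {
  if (full) {
    return(tibble(
      group_id = c("ruminant_meat", "poultry_meat", "other_meat", "eggs",
                   "dairy", "fish", "cereals", "fruit", "nuts", "oilcrops",
                   "pulses", "starchy_roots", "sugar", "vegetables",
                   "other_plants"),
      origin = c(rep("animal", 6), rep("plant", 9)),
      animal_food_type = c("meat_fish", "meat_fish", "meat_fish",
                           "dairy_egg", "dairy_egg", "meat_fish",
                           rep(NA, 9))))
  }
  stopifnot(n_groups >= 2)
  n_animal <- max(2L, round(n_groups / 3))
  n_plant <- n_groups - n_animal
  tibble(
    group_id = c(paste0("animal_g", seq_len(n_animal)),
                 paste0("plant_g", seq_len(n_plant))),
    origin = c(rep("animal", n_animal), rep("plant", n_plant)),
    animal_food_type = c(rep(c("meat_fish", "dairy_egg"),
                             length.out = n_animal), rep(NA, n_plant)))
}

#' Generate a randomized miniature world
#'
#' Draws an invariant-respecting synthetic dataset: per-item production
#' histories are log-uniform over \[1e3, 1e7\] tons with a mild random
#' trend and year-to-year noise; utilization fractions (feed for plant
#' items, supply-chain loss, nonfood) are Beta-distributed and jointly
#' capped so utilization never exceeds production; inedible fractions are
#' Beta(2, 6); protein/amino-acid digestibility is uniform on
#' \[0.3, 1\]; regional in-home waste fractions are Beta(2, 18) (a few
#' percent up to ~15%, the span reported for real food groups); DRV
#' targets vary by stratum around a nutrient-specific base, with lower and
#' upper bounds present for a random subset of nutrients and alternate
#' vegetarian/vegan targets (1.3–1.9 times the default) on iron and zinc.
#' Identical seeds give identical worlds; the global random state is left
#' untouched.
#'
#' @param seed Integer seed.
#' @param shape `"mini"` (default: 3 regions, 4 groups, 8 items, 3 age
#'   groups, 6 nutrients), `"paper"` (5 regions, 15 groups, 121 items, 21
#'   age groups, 2 sexes, 29 nutrients), or `"analytic"` (the fixed world
#'   of [make_analytic_world()], seed ignored).
#' @param n_regions,n_groups,n_items,n_age_groups Optional overrides of
#'   the shape's counts (`mini` shape only).
#' @param years History years of the balance table.
#' @param dir Optional output directory for the seven CSV tables.
#' @return The `delta_world`, invisibly when `dir` is given.
#' @export
make_world <- function(seed = 1L, shape = c("mini", "paper", "analytic"),
                       n_regions = NULL, n_groups = NULL, n_items = NULL,
                       n_age_groups = NULL, years = 2008:2017,
                       dir = NULL) {
  shape <- match.arg(shape)
  if (shape == "analytic") return(make_analytic_world(dir))
  full <- shape == "paper"
  n_regions <- n_regions %||% if (full) 5L else 3L
  n_groups <- n_groups %||% if (full) 15L else 4L
  n_items <- n_items %||% if (full) 121L else 8L
  n_age_groups <- n_age_groups %||% if (full) 21L else 3L
  if (n_items < n_groups) {
    stop_validation("make_world: n_items (", n_items,
                    ") must be >= n_groups (", n_groups, ")")
  }

  world <- with_preserved_seed(seed, {
    groups <- fixture_groups(n_groups, full)
    n_groups <- nrow(groups)
    regions <- tibble(region_id = paste0("region_", seq_len(n_regions)))
    age_groups <- paste0("age_", seq_len(n_age_groups))
    nut <- fixture_nutrients(full)

    # every group gets at least one item; the rest are assigned at random
    item_group <- c(groups$group_id,
                    sample(groups$group_id, n_items - n_groups,
                           replace = TRUE))
    items_tbl <- tibble(
      item_id = sprintf("item_%03d", seq_len(n_items)),
      group_id = item_group) |>
      left_join(groups, by = "group_id")

    base_prod <- 10^stats::runif(n_items, 3, 7)
    trend <- stats::runif(n_items, -0.02, 0.05)
    has_animal <- any(groups$origin == "animal")
    feed_frac <- ifelse(items_tbl$origin == "plant" & has_animal,
                        stats::rbeta(n_items, 2, 8), 0)
    loss_frac <- stats::rbeta(n_items, 2, 18)
    nonfood_frac <- stats::rbeta(n_items, 1.5, 28)
    tot <- feed_frac + loss_frac + nonfood_frac
    over <- tot > 0.9   # keep headroom so utilization stays below production
    scale <- ifelse(over, 0.9 / tot, 1)
    feed_frac <- feed_frac * scale
    loss_frac <- loss_frac * scale
    nonfood_frac <- nonfood_frac * scale

    balance <- purrr::map_dfr(seq_len(n_items), function(i) {
      prod <- base_prod[i] * (1 + trend[i] * (years - min(years))) *
        stats::runif(length(years), 0.85, 1.15)
      prod <- pmax(prod, 0)
      tibble(item_id = items_tbl$item_id[i],
             group_id = items_tbl$group_id[i],
             year = as.integer(years), production_t = prod,
             feed_t = feed_frac[i] * prod,
             supply_chain_loss_t = loss_frac[i] * prod,
             nonfood_t = nonfood_frac[i] * prod)
    })

    density <- tidyr::crossing(item_id = items_tbl$item_id, nut) |>
      mutate(density_per_100g = stats::runif(dplyr::n()) *
               (.data$density_hi - .data$density_lo) + .data$density_lo,
             digestibility = ifelse(.data$digestible,
                                    stats::runif(dplyr::n(), 0.3, 1), 1))
    items <- items_tbl |>
      mutate(inedible_fraction = pmin(stats::rbeta(n_items, 2, 6), 0.8)) |>
      select("item_id", "group_id", "origin", "inedible_fraction") |>
      inner_join(density |> select("item_id", "nutrient_id", "unit",
                                   "density_per_100g", "digestibility"),
                 by = "item_id")

    waste <- tidyr::crossing(region_id = regions$region_id,
                             group_id = groups$group_id) |>
      mutate(waste_fraction = stats::rbeta(dplyr::n(), 2, 18))

    base_year <- max(years) + 1L
    demo_years <- c(base_year, base_year + 12L, base_year + 32L)
    strata <- tidyr::crossing(region_id = regions$region_id,
                              sex = c("F", "M"), age_group = age_groups)
    pop0 <- 10^stats::runif(nrow(strata), 4, 6)
    growth <- stats::runif(nrow(strata), 1.05, 1.30)
    demographics <- purrr::map_dfr(seq_along(demo_years), function(k) {
      strata |>
        mutate(year = demo_years[k],
               population = pop0 * growth^((demo_years[k] - base_year) / 12))
    }) |> arrange(.data$region_id, .data$sex, .data$age_group, .data$year)

    has_lower <- stats::runif(nrow(nut)) < 0.7
    has_upper <- stats::runif(nrow(nut)) < 0.6
    drv <- tidyr::crossing(strata |> distinct(.data$sex, .data$age_group),
                           nut |> select("nutrient_id", "unit",
                                         "target_lo", "target_hi")) |>
      mutate(
        base = stats::runif(dplyr::n()) *
          (.data$target_hi - .data$target_lo) + .data$target_lo,
        target = .data$base * stats::runif(dplyr::n(), 0.85, 1.15)) |>
      left_join(tibble(nutrient_id = nut$nutrient_id,
                       has_lower = has_lower, has_upper = has_upper),
                by = "nutrient_id") |>
      mutate(
        lower_safe = ifelse(.data$has_lower,
                            .data$target * stats::runif(dplyr::n(),
                                                        0.5, 0.9),
                            NA_real_),
        upper_safe = ifelse(.data$has_upper,
                            .data$target * stats::runif(dplyr::n(),
                                                        1.5, 3),
                            NA_real_),
        alt_mult = stats::runif(dplyr::n(), 1.3, 1.9),
        alt_target_vegetarian = ifelse(
          .data$nutrient_id %in% c("iron", "zinc"),
          .data$target * .data$alt_mult, NA_real_),
        alt_target_vegan = ifelse(
          .data$nutrient_id %in% c("iron", "zinc"),
          .data$target * .data$alt_mult * 1.1, NA_real_)) |>
      select("nutrient_id", "sex", "age_group", "unit", "target",
             "lower_safe", "upper_safe", "alt_target_vegetarian",
             "alt_target_vegan") |>
      arrange(.data$nutrient_id, .data$sex, .data$age_group)

    new_world(balance = balance, items = items, waste = waste,
              demographics = demographics, drv = drv, groups = groups,
              regions = regions)
  })
  world <- validate_world(world)
  if (!is.null(dir)) {
    write_world(world, dir)
    return(invisible(world))
  }
  world
}

# Run code under a fixed seed without disturbing the caller's random state.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Random scenario for property testing
#'
#' Draws a scenario within the feasible envelope of a generated world:
#' group multipliers in \[0.3, 1.7\] (occasionally zeroing an animal
#' group), waste multipliers in \[0, 1.5\], either nonfood mode, and a
#' population year tabulated in the world's demographics.
#'
#' @param world A `delta_world`.
#' @param seed Integer seed.
#' @return A `delta_scenario`.
#' @export
random_scenario <- function(world, seed = 1L) {
  with_preserved_seed(seed, {
    gids <- world$groups$group_id
    mult <- stats::runif(length(gids), 0.3, 1.7)
    if (stats::runif(1) < 0.3) {
      animal <- which(world$groups$origin == "animal")
      if (length(animal) > 0) mult[sample(animal, 1)] <- 0
    }
    groups <- stats::setNames(
      lapply(mult, function(m) list(multiplier = m)), gids)
    yrs <- sort(unique(world$demographics$year))
    scenario(
      name = paste0("random_", seed),
      population_year = sample(yrs, 1),
      groups = groups,
      supply_chain_waste_multiplier = stats::runif(1, 0, 1.5),
      in_home_waste_multiplier = stats::runif(1, 0, 1.5),
      nonfood_mode = sample(c("per_capita_constant",
                              "proportional_to_production"), 1),
      diet_mode = "auto")
  })
}
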