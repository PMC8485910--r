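#' Run a scenario end to end
#'
#' The full pipeline: resolve the scenario against the baseline, run the
#' mass-balance cascade, convert allocations to nutrient supply, weight
#' the dietary reference values demographically (switching iron/zinc
#' targets if the resolved diet mode calls for it), build the adequacy
#' report, and account for the nutrients embodied in wasted food.
#'
#' @param world A `delta_world` from [read_world()] or [make_world()].
#' @param sc A `delta_scenario` (from [scenario()] or [read_scenario()]);
#'   the default is the baseline-identity scenario.
#' @param baseline A prepared `delta_baseline`; computed from `world` when
#'   omitted.
#' @param days_per_year Days in the model year (default 365).
#' @param material_threshold_pct Gap materiality threshold (default 5).
#' @param diet_threshold Animal-group absence threshold for diet-mode
#'   detection (default 0.01 of baseline production).
#' @return A `delta_run` object with elements `mass`
#'   (`delta_mass_flow`), `supply` (`delta_nutrient_supply`), `targets`
#'   (`delta_target_set`), `nutrients` (`delta_nutrient_report`), `waste`
#'   (`delta_waste_report`), `scenario` (the `delta_resolved` scenario)
#'   and `population`.
#' @export
run_scenario <- function(world, sc = scenario(name = "baseline"),
                         baseline = NULL, days_per_year = 365,
                         material_threshold_pct = 5,
                         diet_threshold = 0.01) {
  baseline <- baseline %||% prepare_baseline(world)
  resolved <- if (inherits(sc, "delta_resolved")) sc else
    resolve_scenario(sc, baseline, world$groups,
                     diet_threshold = diet_threshold)
  mass <- run_mass_balance(resolved, baseline, world,
                           days_per_year = days_per_year)
  supply <- nutrient_supply(mass, world$items)
  targets <- weighted_targets(world$drv, world$demographics,
                              resolved$population_year,
                              diet_mode = resolved$diet_mode)
  nutrients <- adequacy_report(supply, targets,
                               material_threshold_pct =
                                 material_threshold_pct)
  waste <- nutrient_waste_accounting(mass, world$items, targets)
  structure(list(mass = mass, supply = supply, targets = targets,
                 nutrients = nutrients, waste = waste,
                 scenario = resolved,
                 population = attr(mass, "population")),
            class = "delta_run")
}

#' @export
print.delta_run <- function(x, ...) {
  cat("<delta_run> '", x$scenario$name, "' (year ",
      x$scenario$population_year, ", diet ", x$scenario$diet_mode,
      ")\n", sep = "")
  g <- glance(x)
  cat(sprintf("  biomass %.4g Gt/yr; food after waste %.4g Gt/yr; feed %.4g Gt/yr\n",
              g$total_biomass_bt, g$total_food_supply_bt, g$total_feed_bt))
  cat(sprintf("  population %.4g; material nutrient gaps: %d\n",
              g$population, g$n_material_gaps))
  mat <- x$nutrients |> filter(.data$material) |>
    arrange(dplyr::desc(.data$gap_pct))
  if (nrow(mat) > 0) {
    for (i in seq_len(nrow(mat))) {
      cat(sprintf("    %-12s gap %4.0f%% of target\n",
                  mat$nutrient_id[i], mat$gap_pct[i]))
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scenario run into its nutrient adequacy table
#'
#' @param x A `delta_run`.
#' @param ... Unused.
#' @return The `delta_nutrient_report` tibble of the run.
#' @method tidy delta_run
#' @export
tidy.delta_run <- function(x, ...) x$nutrients

#' One-row summary of a scenario run
#'
#' Headline quantities of a run: total farm-gate biomass, total food
#' supply after all waste (consumed edible mass), total animal-feed use
#' (all in billions of tons per year), the population served, and the
#' count of material nutrient gaps.
#'
#' @param x A `delta_run`.
#' @param ... Unused.
#' @return A one-row tibble with columns `scenario`, `population_year`,
#'   `diet_mode`, `population`, `total_biomass_bt`,
#'   `total_food_supply_bt`, `total_feed_bt`, `n_material_gaps`.
#' @method glance delta_run
#' @export
glance.delta_run <- function(x, ...) {
  tibble(
    scenario = x$scenario$name,
    population_year = x$scenario$population_year,
    diet_mode = x$scenario$diet_mode,
    population = x$population,
    total_biomass_bt = sum(x$mass$production_t) / 1e9,
    total_food_supply_bt = sum(x$mass$consumed_edible_t) / 1e9,
    total_feed_bt = sum(x$mass$feed_t) / 1e9,
    n_material_gaps = sum(x$nutrients$material, na.rm = TRUE)
  )
}

#' @rdname tidy.delta_run
#' @method tidy delta_comparison
#' @export
tidy.delta_comparison <- function(x, ...) x$nutrients
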