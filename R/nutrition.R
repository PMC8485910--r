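#' Convert per-capita item allocations to nutrient supply
#'
#' For each nutrient, supply is the sum over items of
#' `allocation / 100 * density * digestibility`, with densities expressed
#' per 100 g of edible portion. The digestibility coefficient is 1 for
#' every nutrient except protein and the indispensable amino acids, whose
#' profiles carry food-specific coefficients in (0, 1]; the weighting is
#' therefore a no-op outside those nutrients by construction of the
#' profile table.
#'
#' @param allocations A data frame with columns `item_id`,
#'   `per_capita_g_day` (a `delta_mass_flow` works directly).
#' @param profiles The long item-profile tibble.
#' @return A `delta_nutrient_supply` tibble `nutrient_id`, `unit`,
#'   `supply` (per person per day, in the nutrient's unit), with the
#'   per-item contribution table attached as attribute `"provenance"`.
#' @export
nutrient_supply <- function(allocations, profiles) {
  allocations <- as_tibble(allocations)
  require_columns(allocations, c("item_id", "per_capita_g_day"),
                  "allocations")
  missing <- setdiff(allocations$item_id, unique(profiles$item_id))
  if (length(missing) > 0) {
    stop_validation("nutrient_supply: item(s) without a profile: ",
                    fmt_keys(missing))
  }
  if (any(allocations$per_capita_g_day < 0)) {
    stop_validation("nutrient_supply: negative allocation(s) for item(s): ",
                    fmt_keys(allocations$item_id[
                      allocations$per_capita_g_day < 0]))
  }
  provenance <- profiles |>
    inner_join(allocations |> select("item_id", "per_capita_g_day"),
               by = "item_id") |>
    mutate(contribution = .data$per_capita_g_day / 100 *
             .data$density_per_100g * .data$digestibility) |>
    select("nutrient_id", "unit", "item_id", "contribution")
  out <- provenance |>
    group_by(.data$nutrient_id, .data$unit) |>
    summarise(supply = sum(.data$contribution), .groups = "drop") |>
    arrange(.data$nutrient_id)
  structure(out,
            class = c("delta_nutrient_supply", class(out)),
            provenance = provenance)
}

#' Account for the nutrients embodied in wasted food
#'
#' Converts each item's wasted mass to nutrient terms and aggregates per
#' nutrient: the edible share of supply-chain losses (inedible matter
#' carries no nutrients) plus in-home waste (already edible), expressed
#' per person per day, multiplied by nutrient density and digestibility.
#' This uses the same digestibility weighting as consumed supply, so
#' consumed + wasted equals the supply of a zero-waste run of the same
#' scenario (nutrient-mass closure). The report also splits each
#' nutrient's waste between plant- and animal-origin items, and expresses
#' it as a percentage of the target intake.
#'
#' @param mass A `delta_mass_flow` result.
#' @param profiles The long item-profile tibble.
#' @param targets A target set from [weighted_targets()] (columns
#'   `nutrient_id`, `target`), or `NULL` to skip the percentage column.
#' @return A `delta_waste_report` tibble `nutrient_id`, `unit`,
#'   `wasted_amount` (per person per day), `pct_of_target` (`NA` when no
#'   target is available), `plant_share_pct`, `animal_share_pct`.
#' @export
nutrient_waste_accounting <- function(mass, profiles, targets = NULL) {
  stopifnot(inherits(mass, "delta_mass_flow"))
  population <- attr(mass, "population")
  days <- attr(mass, "days_per_year")
  origin <- profiles |> distinct(.data$item_id, .data$origin,
                                 .data$inedible_fraction)
  wasted <- as_tibble(mass) |>
    left_join(origin, by = "item_id") |>
    mutate(wasted_g_day = ((1 - .data$inedible_fraction) *
                             .data$supply_chain_loss_t +
                             .data$in_home_waste_t) * 1e6 /
             population / days) |>
    select("item_id", "origin", "wasted_g_day")

  contrib <- profiles |>
    inner_join(wasted, by = c("item_id", "origin")) |>
    mutate(wasted_amount = .data$wasted_g_day / 100 *
             .data$density_per_100g * .data$digestibility)
  out <- contrib |>
    group_by(.data$nutrient_id, .data$unit) |>
    summarise(
      plant_wasted = sum(.data$wasted_amount[.data$origin == "plant"]),
      wasted_amount = sum(.data$wasted_amount),
      .groups = "drop") |>
    mutate(
      plant_share_pct = ifelse(.data$wasted_amount > 0,
                               100 * .data$plant_wasted /
                                 .data$wasted_amount, NA_real_),
      animal_share_pct = ifelse(is.na(.data$plant_share_pct),
                                NA_real_, 100 - .data$plant_share_pct)) |>
    select(-"plant_wasted")

  if (!is.null(targets)) {
    out <- out |>
      left_join(as_tibble(targets) |> select("nutrient_id", "target"),
                by = "nutrient_id") |>
      mutate(pct_of_target = ifelse(
        !is.na(.data$target) & .data$target > 0,
        100 * .data$wasted_amount / .data$target, NA_real_)) |>
      select(-"target")
  } else {
    out$pct_of_target <- NA_real_
  }
  out <- out |>
    select("nutrient_id", "unit", "wasted_amount", "pct_of_target",
           "plant_share_pct", "animal_share_pct") |>
    arrange(.data$nutrient_id)
  structure(out, class = c("delta_waste_report", class(out)))
}
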