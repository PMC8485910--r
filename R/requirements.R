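#' Demographically weighted target intakes
#'
#' Combines the DRV table with the population structure at `year` to give
#' one target per nutrient for the average citizen:
#' `target(n) = sum over strata of population_share * DRV(n, stratum)`.
#' Population counts vary by (region, sex, age group), but DRVs vary only
#' by (sex, age group), so regions contribute weight only. Lower and upper
#' safe bounds are weighted with the same shares; a bound is reported only
#' if every stratum carries it. In `vegetarian`/`vegan` diet mode, any
#' nutrient with the corresponding alternate target column populated
#' (typically iron and zinc, whose absorption from plant-based diets is
#' lower) has its stratum targets replaced by the alternates before
#' weighting.
#'
#' @param drv A validated DRV table.
#' @param demographics A validated demographic table.
#' @param year Calendar year of the population.
#' @param diet_mode `"omnivore"`, `"vegetarian"` or `"vegan"`.
#' @return A `delta_target_set` tibble `nutrient_id`, `unit`, `target`,
#'   `lower_safe`, `upper_safe` (bounds `NA` where unavailable).
#' @export
weighted_targets <- function(drv, demographics, year,
                             diet_mode = c("omnivore", "vegetarian",
                                           "vegan")) {
  diet_mode <- match.arg(diet_mode)
  drv <- validate_drv_table(drv)
  strata <- population_strata(demographics, year) |>
    group_by(.data$sex, .data$age_group) |>
    summarise(population = sum(.data$population), .groups = "drop")
  total <- sum(strata$population)
  if (total <= 0) stop_validation("weighted_targets: zero total population")
  strata$share <- strata$population / total

  covered <- drv |> distinct(.data$sex, .data$age_group)
  missing <- strata |> anti_join(covered, by = c("sex", "age_group"))
  if (nrow(missing) > 0) {
    stop_validation("weighted_targets: DRV table lacks stratum(s): ",
                    fmt_keys(paste0(missing$sex, "/", missing$age_group)))
  }

  eff <- drv
  alt_col <- switch(diet_mode, vegetarian = "alt_target_vegetarian",
                    vegan = "alt_target_vegan", NULL)
  if (!is.null(alt_col)) {
    eff <- eff |>
      mutate(target = dplyr::coalesce(.data[[alt_col]], .data$target))
  }

  eff |>
    inner_join(strata |> select("sex", "age_group", "share"),
               by = c("sex", "age_group")) |>
    group_by(.data$nutrient_id, .data$unit) |>
    summarise(
      target = sum(.data$share * .data$target),
      lower_safe = if (any(is.na(.data$lower_safe))) NA_real_ else
        sum(.data$share * .data$lower_safe),
      upper_safe = if (any(is.na(.data$upper_safe))) NA_real_ else
        sum(.data$share * .data$upper_safe),
      .groups = "drop") |>
    arrange(.data$nutrient_id) |>
    (\(x) structure(x, class = c("delta_target_set", class(x))))()
}

#' Nutrient adequacy report
#'
#' Compares per-capita nutrient supply against demographically weighted
#' targets. Per nutrient: `pct_of_target = 100 * supply / target`;
#' `gap_pct = max(0, 100 * (target - supply) / target)`;
#' `excess_pct = max(0, 100 * (supply - upper_safe) / upper_safe)` where
#' an upper safe limit exists (NA otherwise). A gap is flagged `material`
#' above `material_threshold_pct` (default 5%, below which differences are
#' within the model's accuracy); smaller gaps are retained in the report
#' and only filtered in display.
#'
#' @param supply A `delta_nutrient_supply` (or tibble `nutrient_id`,
#'   `unit`, `supply`).
#' @param targets A `delta_target_set` from [weighted_targets()].
#' @param material_threshold_pct Gap percentage above which a gap is
#'   material (default 5).
#' @return A `delta_nutrient_report` tibble with columns `nutrient_id`,
#'   `unit`, `supply`, `target`, `lower_safe`, `upper_safe`,
#'   `pct_of_target`, `gap_pct`, `excess_pct`, `material`, covering every
#'   nutrient present in supply or targets.
#' @export
adequacy_report <- function(supply, targets, material_threshold_pct = 5) {
  supply <- as_tibble(supply)
  targets <- as_tibble(targets)
  unmatched <- setdiff(supply$nutrient_id, targets$nutrient_id)
  if (length(unmatched) > 0) {
    warn(paste0("adequacy_report: no target for nutrient(s): ",
                fmt_keys(unmatched), "; row(s) emitted without gap"))
  }
  mism <- supply |>
    inner_join(targets, by = "nutrient_id",
               suffix = c("_supply", "_target")) |>
    filter(.data$unit_supply != .data$unit_target)
  if (nrow(mism) > 0) {
    stop_validation("adequacy_report: unit mismatch for nutrient(s): ",
                    fmt_keys(mism$nutrient_id))
  }
  out <- full_join(supply |> select("nutrient_id", "unit", "supply"),
                   targets, by = "nutrient_id",
                   suffix = c("", "_t")) |>
    mutate(
      unit = dplyr::coalesce(.data$unit, .data$unit_t),
      supply = dplyr::coalesce(.data$supply, 0),
      pct_of_target = ifelse(!is.na(.data$target),
                             100 * .data$supply / .data$target, NA_real_),
      gap_pct = ifelse(!is.na(.data$target),
                       pmax(0, 100 * (.data$target - .data$supply) /
                              .data$target), NA_real_),
      excess_pct = ifelse(!is.na(.data$upper_safe),
                          pmax(0, 100 * (.data$supply - .data$upper_safe) /
                                 .data$upper_safe), NA_real_),
      material = !is.na(.data$gap_pct) &
        .data$gap_pct > material_threshold_pct
    ) |>
    select("nutrient_id", "unit", "supply", "target", "lower_safe",
           "upper_safe", "pct_of_target", "gap_pct", "excess_pct",
           "material") |>
    arrange(.data$nutrient_id)
  structure(out, class = c("delta_nutrient_report", class(out)))
}

#' Compare two scenario runs
#'
#' Side-by-side differences (run B minus run A): per-nutrient supply,
#' percent-of-target and gap deltas, and per-group farm-gate biomass
#' deltas, in deterministic (alphabetical) order.
#'
#' @param a,b `delta_run` objects from [run_scenario()].
#' @return A `delta_comparison` object with tibbles `nutrients`
#'   (`nutrient_id`, `unit`, `supply_a`, `supply_b`, `delta_supply`,
#'   `delta_pct_of_target`, `delta_gap_pct`) and `groups` (`group_id`,
#'   `production_a_t`, `production_b_t`, `delta_production_t`).
#' @export
compare_scenarios <- function(a, b) {
  stopifnot(inherits(a, "delta_run"), inherits(b, "delta_run"))
  na <- a$nutrients$nutrient_id
  nb <- b$nutrients$nutrient_id
  if (!setequal(na, nb)) {
    stop_validation(
      "compare_scenarios: nutrient vocabularies differ; only in A: ",
      fmt_keys(setdiff(na, nb)), "; only in B: ", fmt_keys(setdiff(nb, na)))
  }
  nutrients <- inner_join(
    a$nutrients |> select("nutrient_id", "unit", supply_a = "supply",
                          pct_a = "pct_of_target", gap_a = "gap_pct"),
    b$nutrients |> select("nutrient_id", supply_b = "supply",
                          pct_b = "pct_of_target", gap_b = "gap_pct"),
    by = "nutrient_id") |>
    mutate(delta_supply = .data$supply_b - .data$supply_a,
           delta_pct_of_target = .data$pct_b - .data$pct_a,
           delta_gap_pct = .data$gap_b - .data$gap_a) |>
    select("nutrient_id", "unit", "supply_a", "supply_b", "delta_supply",
           "delta_pct_of_target", "delta_gap_pct") |>
    arrange(.data$nutrient_id)
  groups <- full_join(
    a$scenario$group_production |> rename(production_a_t = "production_t"),
    b$scenario$group_production |> rename(production_b_t = "production_t"),
    by = "group_id") |>
    mutate(production_a_t = dplyr::coalesce(.data$production_a_t, 0),
           production_b_t = dplyr::coalesce(.data$production_b_t, 0),
           delta_production_t = .data$production_b_t -
             .data$production_a_t) |>
    arrange(.data$group_id)
  structure(list(nutrients = nutrients, groups = groups,
                 name_a = a$scenario$name, name_b = b$scenario$name),
            class = "delta_comparison")
}

#' @export
print.delta_comparison <- function(x, ...) {
  cat("<delta_comparison> B ('", x$name_b, "') minus A ('", x$name_a,
      "')\n", sep = "")
  print(x$nutrients, ...)
  invisible(x)
}
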