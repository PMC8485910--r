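#' Distribute group production to individual items
#'
#' Splits each group's scenario production across its items in proportion
#' to the baseline item shares, so the within-group composition always
#' follows the historical distribution.
#'
#' @param group_production A data frame with columns `group_id`,
#'   `production_t` (e.g. the `group_production` of a resolved scenario).
#' @param baseline A `delta_baseline` (supplies item shares).
#' @return A tibble `item_id`, `group_id`, `production_t`; within each
#'   group the item amounts sum exactly to the group production.
#' @export
distribute_to_items <- function(group_production, baseline) {
  bad <- setdiff(group_production$group_id, baseline$items$group_id)
  if (length(bad) > 0) {
    stop_validation("distribute_to_items: group(s) absent from baseline",
                    " shares: ", fmt_keys(bad))
  }
  baseline$items |>
    select("item_id", "group_id", "item_share") |>
    inner_join(group_production |>
                 select("group_id", group_production_t = "production_t"),
               by = "group_id") |>
    mutate(production_t = .data$item_share * .data$group_production_t) |>
    select("item_id", "group_id", "production_t")
}

#' Compute scenario feed use per feed item
#'
#' Feed demand follows animal production: each feed item's baseline
#' attributed tonnage toward an animal group is scaled by that group's
#' scenario-to-baseline production ratio, and summed over animal groups.
#' Zero animal production therefore implies zero feed demand.
#'
#' @param item_production Tibble `item_id`, `production_t` of scenario item
#'   productions (feed demand may not exceed an item's production).
#' @param feed_attribution The baseline `feed_attribution` tibble
#'   (`item_id`, `animal_group_id`, `tons`).
#' @param animal_ratio Tibble `animal_group_id`, `ratio` of
#'   scenario/baseline production per animal group.
#' @return A tibble `item_id`, `feed_t` covering every item in
#'   `item_production` (zero where the item is not used as feed).
#' @export
compute_feed_use <- function(item_production, feed_attribution,
                             animal_ratio) {
  if (any(!is.finite(animal_ratio$ratio) | animal_ratio$ratio < 0)) {
    stop_validation("compute_feed_use: ratios must be finite and >= 0")
  }
  feed <- feed_attribution |>
    left_join(animal_ratio, by = "animal_group_id") |>
    mutate(ratio = dplyr::coalesce(.data$ratio, 0)) |>
    group_by(.data$item_id) |>
    summarise(feed_t = sum(.data$tons * .data$ratio), .groups = "drop")
  out <- item_production |>
    select("item_id", "production_t") |>
    left_join(feed, by = "item_id") |>
    mutate(feed_t = dplyr::coalesce(.data$feed_t, 0))
  over <- out$feed_t > out$production_t * (1 + 1e-9)
  if (any(over)) {
    stop_infeasible("infeasible scenario: feed demand exceeds production",
                    " for item(s): ", fmt_keys(out$item_id[over]))
  }
  out |> select("item_id", "feed_t")
}

#' Compute scenario nonfood use per item
#'
#' Two scaling conventions: `per_capita_constant` keeps baseline nonfood
#' use constant per person (tonnage scales with the population ratio, e.g.
#' biofuel demand tracking population); `proportional_to_production`
#' applies the baseline nonfood fraction to scenario production.
#'
#' @param baseline_nonfood Tibble `item_id`, `nonfood_t` of baseline
#'   nonfood tonnage (used by `per_capita_constant`).
#' @param baseline_population,scenario_population Positive person counts.
#' @param mode `"per_capita_constant"` or `"proportional_to_production"`.
#' @param nonfood_fraction Tibble `item_id`, `nonfood_fraction` (required
#'   for `proportional_to_production`).
#' @param item_production Tibble `item_id`, `production_t` (required for
#'   `proportional_to_production`).
#' @return A tibble `item_id`, `nonfood_t`.
#' @export
compute_nonfood_use <- function(baseline_nonfood, baseline_population,
                                scenario_population,
                                mode = c("per_capita_constant",
                                         "proportional_to_production"),
                                nonfood_fraction = NULL,
                                item_production = NULL) {
  mode <- match.arg(mode)
  if (baseline_population <= 0 || scenario_population <= 0) {
    stop_validation("compute_nonfood_use: populations must be positive")
  }
  if (mode == "per_capita_constant") {
    baseline_nonfood |>
      mutate(nonfood_t = .data$nonfood_t *
               scenario_population / baseline_population) |>
      select("item_id", "nonfood_t")
  } else {
    stopifnot(!is.null(nonfood_fraction), !is.null(item_production))
    item_production |>
      left_join(nonfood_fraction, by = "item_id") |>
      mutate(nonfood_t = dplyr::coalesce(.data$nonfood_fraction, 0) *
               .data$production_t) |>
      select("item_id", "nonfood_t")
  }
}

#' Population-weighted global in-home waste fraction per group
#'
#' Regional in-home waste fractions collapse to one global fraction per
#' food group by weighting each region's fraction with its population at
#' the scenario year; regions missing a (region, group) row contribute a
#' waste fraction of 0.
#'
#' @param waste The regional waste table.
#' @param demographics The demographic table.
#' @param year Scenario population year.
#' @return A tibble `group_id`, `waste_fraction`.
#' @export
global_waste_fractions <- function(waste, demographics, year) {
  pops <- population_strata(demographics, year) |>
    group_by(.data$region_id) |>
    summarise(population = sum(.data$population), .groups = "drop")
  total <- sum(pops$population)
  if (total <= 0) {
    stop_validation("global_waste_fractions: zero total population")
  }
  tidyr::crossing(pops, group_id = unique(waste$group_id)) |>
    left_join(waste, by = c("region_id", "group_id")) |>
    mutate(waste_fraction = dplyr::coalesce(.data$waste_fraction, 0)) |>
    group_by(.data$group_id) |>
    summarise(waste_fraction = sum(.data$population * .data$waste_fraction) /
                total, .groups = "drop")
}

#' Run the mass-balance cascade
#'
#' Executes the deduction cascade per item, from farm-gate production to
#' per-capita daily edible allocation:
#' production − feed − supply-chain loss − nonfood = consumer
#' availability; minus the inedible portion = edible; minus in-home waste
#' = consumed. Feed follows animal production via the baseline feed
#' attribution; supply-chain loss is the baseline loss fraction of
#' production times the scenario's supply-chain waste multiplier; the
#' in-home waste fraction is the population-weighted global group fraction
#' times the in-home waste multiplier, applied to the edible mass.
#' Consumed mass is rescaled to g/person/day at the scenario year's
#' population. Any negative intermediate raises an infeasibility error
#' naming the item and stage; nothing is silently clamped.
#'
#' @param resolved A `delta_resolved` scenario.
#' @param baseline A `delta_baseline` with feed attribution.
#' @param world The `delta_world` (item profiles, waste, demographics).
#' @param days_per_year Days in the model year (default 365).
#' @return A `delta_mass_flow` tibble with one row per item and columns
#'   `item_id`, `group_id`, `production_t`, `feed_t`,
#'   `supply_chain_loss_t`, `nonfood_t`, `inedible_t`, `in_home_waste_t`,
#'   `consumed_edible_t`, `per_capita_g_day`; the scenario population,
#'   year and multipliers ride along as attributes. Per item the six mass
#'   components sum back to production (conservation).
#' @export
run_mass_balance <- function(resolved, baseline, world,
                             days_per_year = 365) {
  stopifnot(inherits(resolved, "delta_resolved"),
            inherits(baseline, "delta_baseline"))
  if (is.null(baseline$feed_attribution)) {
    stop_validation("run_mass_balance: baseline lacks feed attribution;",
                    " run derive_feed_attribution() or prepare_baseline()")
  }
  m_sc <- resolved$supply_chain_waste_multiplier
  m_ih <- resolved$in_home_waste_multiplier
  population <- population_at(world$demographics, resolved$population_year)
  if (population <= 0) {
    stop_validation("run_mass_balance: zero population at year ",
                    resolved$population_year)
  }

  items <- distribute_to_items(resolved$group_production, baseline)

  animal_ratio <- baseline$groups |>
    semi_join(baseline$feed_attribution |>
                distinct(group_id = .data$animal_group_id),
              by = "group_id") |>
    left_join(resolved$group_production, by = "group_id") |>
    mutate(ratio = ifelse(.data$baseline_production_t > 0,
                          .data$production_t / .data$baseline_production_t,
                          0)) |>
    select(animal_group_id = "group_id", "ratio")
  feed <- compute_feed_use(items, baseline$feed_attribution, animal_ratio)

  fractions <- baseline$items |>
    select("item_id", "loss_fraction", "nonfood_fraction")
  eff_loss <- fractions$loss_fraction * m_sc
  if (any(eff_loss > 1 + 1e-12)) {
    stop_infeasible("infeasible scenario: effective supply-chain loss",
                    " fraction exceeds 1 for item(s): ",
                    fmt_keys(fractions$item_id[eff_loss > 1 + 1e-12]))
  }

  baseline_nonfood <- baseline$items |>
    mutate(nonfood_t = .data$nonfood_fraction *
             .data$baseline_production_t) |>
    select("item_id", "nonfood_t")
  nonfood <- compute_nonfood_use(
    baseline_nonfood, baseline$baseline_population, population,
    mode = resolved$nonfood_mode,
    nonfood_fraction = fractions |> select("item_id", "nonfood_fraction"),
    item_production = items)

  profile <- world$items |>
    distinct(.data$item_id, .data$inedible_fraction)
  waste_fraction <- global_waste_fractions(world$waste, world$demographics,
                                           resolved$population_year)
  eff_ih <- waste_fraction$waste_fraction * m_ih
  if (any(eff_ih > 1 + 1e-12)) {
    stop_infeasible("infeasible scenario: effective in-home waste fraction",
                    " exceeds 1 for group(s): ",
                    fmt_keys(waste_fraction$group_id[eff_ih > 1 + 1e-12]))
  }

  flow <- items |>
    left_join(feed, by = "item_id") |>
    left_join(fractions, by = "item_id") |>
    left_join(nonfood, by = "item_id") |>
    left_join(profile, by = "item_id") |>
    left_join(waste_fraction, by = "group_id") |>
    mutate(
      supply_chain_loss_t = .data$loss_fraction * .data$production_t * m_sc,
      waste_fraction = dplyr::coalesce(.data$waste_fraction, 0),
      availability_t = .data$production_t - .data$feed_t -
        .data$supply_chain_loss_t - .data$nonfood_t
    )

  neg <- flow$availability_t < -1e-9 * pmax(flow$production_t, 1)
  if (any(neg)) {
    stop_infeasible("infeasible scenario: negative consumer availability",
                    " after feed/loss/nonfood deduction for item(s): ",
                    fmt_keys(flow$item_id[neg]))
  }
  flow$availability_t <- pmax(flow$availability_t, 0)

  flow <- flow |>
    mutate(
      inedible_t = .data$inedible_fraction * .data$availability_t,
      edible_t = .data$availability_t - .data$inedible_t,
      in_home_waste_t = .data$waste_fraction * m_ih * .data$edible_t,
      consumed_edible_t = .data$edible_t - .data$in_home_waste_t,
      per_capita_g_day = .data$consumed_edible_t * 1e6 /
        population / days_per_year
    ) |>
    select("item_id", "group_id", "production_t", "feed_t",
           "supply_chain_loss_t", "nonfood_t", "inedible_t",
           "in_home_waste_t", "consumed_edible_t", "per_capita_g_day") |>
    arrange(.data$group_id, .data$item_id)

  structure(flow,
            class = c("delta_mass_flow", class(flow)),
            population = population,
            days_per_year = days_per_year,
            population_year = resolved$population_year,
            scenario_name = resolved$name,
            diet_mode = resolved$diet_mode)
}
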