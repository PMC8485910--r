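#' Extrapolate per-item production to a target year
#'
#' Fits a weighted least-squares line through each item's production
#' history and evaluates it at `target_year`. The default weighting rises
#' linearly from 1 at the oldest year to 2 at the newest, so recent years
#' steer the trend while the full history stabilizes it; `"uniform"` gives
#' ordinary least squares, and a numeric vector (one weight per history
#' year, oldest first) gives full control. Any weighting reproduces an
#' exactly affine series exactly. A negative extrapolation is clamped to
#' zero with a warning, since mass cannot be negative.
#'
#' @param history A data frame with columns `item_id`, `year`,
#'   `production_t` (e.g. a balance table; extra columns are ignored).
#' @param target_year Year to extrapolate to; must exceed the last history
#'   year.
#' @param weights `"linear"` (default), `"uniform"`, or a numeric vector of
#'   positive weights, one per distinct history year, oldest first.
#' @return A tibble with columns `item_id`, `production_t` giving the
#'   extrapolated production (tons/yr) for each item.
#' @export
interpolate_production <- function(history, target_year,
                                   weights = "linear") {
  history <- as_tibble(history)
  require_columns(history, c("item_id", "year", "production_t"),
                  "production history")
  if (target_year <= max(history$year)) {
    stop_validation("target_year (", target_year,
                    ") must exceed the last history year (",
                    max(history$year), ")")
  }
  single <- history |> group_by(.data$item_id) |>
    summarise(n_years = dplyr::n_distinct(.data$year), .groups = "drop") |>
    filter(.data$n_years < 2)
  if (nrow(single) > 0) {
    stop_validation(
      "production history: item(s) with a single year of history: ",
      fmt_keys(single$item_id),
      ". A line cannot be fitted; carry the single value forward",
      " explicitly (duplicate the row at a second year) if a constant",
      " history is intended.")
  }

  year_weights <- function(yrs) {
    if (is.numeric(weights)) {
      if (length(weights) != length(yrs)) {
        stop_validation("weights: expected ", length(yrs),
                        " values (one per history year), got ",
                        length(weights))
      }
      if (any(weights <= 0)) stop_validation("weights must be positive")
      weights
    } else if (identical(weights, "uniform")) {
      rep(1, length(yrs))
    } else if (identical(weights, "linear")) {
      if (length(yrs) == 1) 1 else seq(1, 2, length.out = length(yrs))
    } else {
      stop_validation("weights must be \"linear\", \"uniform\" or numeric")
    }
  }

  out <- history |>
    group_by(.data$item_id) |>
    summarise(
      production_t = wls_line_predict(.data$year, .data$production_t,
                                      year_weights(sort(unique(.data$year))),
                                      !!target_year),
      .groups = "drop"
    )
  neg <- out$production_t < 0
  if (any(neg)) {
    warn(paste0("interpolate_production: negative extrapolation clamped to",
                " 0 for item(s): ", fmt_keys(out$item_id[neg])))
    out$production_t[neg] <- 0
  }
  out
}

# Closed-form weighted least-squares line through (x, y) with weights w
# (indexed by sorted unique x), evaluated at x0. Solves the 2x2 normal
# equations directly; centring x keeps the system well conditioned.
wls_line_predict <- function(x, y, w_by_year, x0) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  w <- w_by_year[match(x, sort(unique(x)))]
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  slope <- if (sxx == 0) 0 else sum(w * (x - xb) * (y - yb)) / sxx
  yb + slope * (x0 - xb)
}

#' Derive baseline shares and utilization fractions
#'
#' Pools the balance table across all history years and derives, per item:
#' its share of its group's production, and the fractions of its farm-gate
#' production going to animal feed, supply-chain loss and nonfood use.
#' Pooling (summing masses over years, rather than averaging yearly
#' shares) is robust to years in which an item's production is zero.
#' Baseline production per item is the weighted-line extrapolation to
#' `baseline_year` ([interpolate_production]), or the tabulated values if
#' `baseline_year` is a history year.
#'
#' @param balance A validated balance table.
#' @param demographics A validated demographic table (sets the baseline
#'   population).
#' @param baseline_year Baseline calendar year; defaults to the year after
#'   the last history year.
#' @param weights Interpolation weighting passed to
#'   [interpolate_production()].
#' @return A `delta_baseline` object (see [prepare_baseline()]) without
#'   feed attribution.
#' @export
derive_shares <- function(balance, demographics,
                          baseline_year = max(balance$year) + 1L,
                          weights = "linear") {
  balance <- validate_balance_table(balance)
  pooled <- balance |>
    group_by(.data$item_id, .data$group_id) |>
    summarise(production_t = sum(.data$production_t),
              feed_t = sum(.data$feed_t),
              supply_chain_loss_t = sum(.data$supply_chain_loss_t),
              nonfood_t = sum(.data$nonfood_t),
              .groups = "drop")
  zero_groups <- pooled |> group_by(.data$group_id) |>
    summarise(total = sum(.data$production_t), .groups = "drop") |>
    filter(.data$total == 0)
  if (nrow(zero_groups) > 0) {
    stop_validation("derive_shares: group(s) with zero pooled production",
                    " (item shares undefined): ",
                    fmt_keys(zero_groups$group_id))
  }
  zero_items <- pooled$production_t == 0
  items <- pooled |>
    group_by(.data$group_id) |>
    mutate(item_share = .data$production_t / sum(.data$production_t)) |>
    ungroup() |>
    mutate(
      feed_fraction = ifelse(zero_items, 0,
                             .data$feed_t / .data$production_t),
      loss_fraction = ifelse(zero_items, 0,
                             .data$supply_chain_loss_t / .data$production_t),
      nonfood_fraction = ifelse(zero_items, 0,
                                .data$nonfood_t / .data$production_t)
    ) |>
    select("item_id", "group_id", "item_share", "feed_fraction",
           "loss_fraction", "nonfood_fraction")

  if (baseline_year %in% balance$year) {
    base_prod <- balance |> filter(.data$year == baseline_year) |>
      select("item_id", "production_t")
  } else {
    base_prod <- interpolate_production(balance, baseline_year, weights)
  }
  items <- items |>
    left_join(base_prod |> rename(baseline_production_t = "production_t"),
              by = "item_id") |>
    mutate(baseline_production_t =
             dplyr::coalesce(.data$baseline_production_t, 0))

  groups <- items |>
    group_by(.data$group_id) |>
    summarise(baseline_production_t = sum(.data$baseline_production_t),
              .groups = "drop")

  structure(list(
    items = items,
    groups = groups,
    feed_attribution = NULL,
    baseline_year = baseline_year,
    baseline_population = population_at(demographics, baseline_year)
  ), class = "delta_baseline")
}

#' Attribute baseline feed tonnage to animal food groups
#'
#' Feed use couples plant production to animal production: when a scenario
#' scales an animal group, the feed demand it exerts on feed items scales
#' with it. This function fixes, per feed item, how its baseline feed
#' tonnage is split across the animal groups. With an explicit attribution
#' table (columns `item_id`, `animal_group_id`, `tons`) the rows are
#' validated (a per-item total exceeding the item's baseline feed tonnage
#' is an error) and normalized so each item's attributed tonnage sums
#' exactly to its baseline feed tonnage. Without one, each feed item's
#' tonnage is split across animal groups in proportion to their baseline
#' production.
#'
#' @param baseline A `delta_baseline` from [derive_shares()].
#' @param groups The groups vocabulary table (identifies animal groups).
#' @param attribution An optional explicit attribution data frame.
#' @return The baseline with a `feed_attribution` tibble attached: columns
#'   `item_id`, `animal_group_id`, `tons` (baseline attributed feed) and
#'   `coef_t_per_t` (tons of this feed item per ton of the animal group's
#'   product).
#' @export
derive_feed_attribution <- function(baseline, groups, attribution = NULL) {
  groups <- validate_groups(groups)
  animal_groups <- groups$group_id[groups$origin == "animal"]
  feed_items <- baseline$items |>
    mutate(baseline_feed_t = .data$feed_fraction *
             .data$baseline_production_t) |>
    filter(.data$baseline_feed_t > 0) |>
    select("item_id", "baseline_feed_t")

  animal_prod <- baseline$groups |>
    filter(.data$group_id %in% animal_groups)

  if (nrow(feed_items) == 0) {
    baseline$feed_attribution <- tibble(item_id = character(),
                                        animal_group_id = character(),
                                        tons = double(),
                                        coef_t_per_t = double())
    return(baseline)
  }
  if (nrow(animal_prod) == 0 || sum(animal_prod$baseline_production_t) == 0) {
    stop_validation("derive_feed_attribution: feed tonnage present but no",
                    " animal group with positive baseline production to",
                    " attribute it to")
  }

  if (is.null(attribution)) {
    attr_tbl <- tidyr::crossing(feed_items,
                                animal_prod |>
                                  rename(animal_group_id = "group_id")) |>
      mutate(tons = .data$baseline_feed_t * .data$baseline_production_t /
               sum(animal_prod$baseline_production_t)) |>
      select("item_id", "animal_group_id", "tons")
  } else {
    attribution <- as_tibble(attribution)
    require_columns(attribution, c("item_id", "animal_group_id", "tons"),
                    "feed attribution")
    bad <- setdiff(attribution$animal_group_id, animal_groups)
    if (length(bad) > 0) {
      stop_validation("feed attribution: unknown or non-animal group(s): ",
                      fmt_keys(bad))
    }
    check_finite_nonneg(attribution, "tons",
                        c("item_id", "animal_group_id"), "feed attribution")
    sums <- attribution |> group_by(.data$item_id) |>
      summarise(attributed = sum(.data$tons), .groups = "drop") |>
      left_join(feed_items, by = "item_id")
    unknown <- sums |> filter(is.na(.data$baseline_feed_t))
    if (nrow(unknown) > 0) {
      stop_validation("feed attribution: item(s) without baseline feed",
                      " tonnage: ", fmt_keys(unknown$item_id))
    }
    over <- sums |>
      filter(.data$attributed > .data$baseline_feed_t * (1 + 1e-9))
    if (nrow(over) > 0) {
      stop_validation("feed attribution: attributed tonnage exceeds the",
                      " item's baseline feed tonnage for item(s): ",
                      fmt_keys(over$item_id))
    }
    attr_tbl <- attribution |>
      left_join(feed_items, by = "item_id") |>
      group_by(.data$item_id) |>
      mutate(tons = .data$tons / sum(.data$tons) * .data$baseline_feed_t) |>
      ungroup() |>
      select("item_id", "animal_group_id", "tons")
  }

  attr_tbl <- attr_tbl |>
    left_join(animal_prod |> rename(animal_group_id = "group_id"),
              by = "animal_group_id") |>
    mutate(coef_t_per_t = ifelse(.data$baseline_production_t > 0,
                                 .data$tons / .data$baseline_production_t,
                                 0)) |>
    select("item_id", "animal_group_id", "tons", "coef_t_per_t") |>
    arrange(.data$item_id, .data$animal_group_id)

  baseline$feed_attribution <- attr_tbl
  baseline
}

#' Prepare the full baseline for scenario runs
#'
#' Convenience wrapper chaining [derive_shares()] and
#' [derive_feed_attribution()] on a loaded world.
#'
#' @param world A `delta_world` from [read_world()] or [make_world()].
#' @param baseline_year Baseline year; defaults to the year after the last
#'   balance-table year.
#' @param weights Interpolation weighting (see [interpolate_production()]).
#' @param attribution Optional explicit feed-attribution table.
#' @return A `delta_baseline` object: item shares and utilization
#'   fractions, per-group baseline production, feed attribution, baseline
#'   year and population.
#' @export
prepare_baseline <- function(world, baseline_year = NULL,
                             weights = "linear", attribution = NULL) {
  baseline_year <- baseline_year %||% (max(world$balance$year) + 1L)
  derive_shares(world$balance, world$demographics, baseline_year, weights) |>
    derive_feed_attribution(world$groups, attribution)
}

#' @export
print.delta_baseline <- function(x, ...) {
  cat("<delta_baseline> year", x$baseline_year, "\n")
  cat("  items:", nrow(x$items), "in", nrow(x$groups), "groups;",
      "baseline biomass", format(sum(x$groups$baseline_production_t),
                                 big.mark = ","), "t\n")
  cat("  population:", format(x$baseline_population, big.mark = ","), "\n")
  invisible(x)
}
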