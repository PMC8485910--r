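#' Read a commodity balance table
#'
#' Reads the multi-year commodity balance CSV: farm-gate production and its
#' utilization (animal feed, supply-chain loss, nonfood use) per food item
#' per year, in tons. These tables mirror the structure of national food
#' balance sheets, where utilization quantities are recorded alongside
#' production.
#'
#' @param path Path to a UTF-8 CSV with a single header row and columns
#'   `item_id`, `group_id`, `year`, `production_t`, `feed_t`,
#'   `supply_chain_loss_t`, `nonfood_t`.
#' @return A validated tibble, one row per (item, year).
#' @export
read_balance_table <- function(path) {
  df <- read_csv_strict(path, list(
    item_id = readr::col_character(), group_id = readr::col_character(),
    year = readr::col_integer(), production_t = readr::col_double(),
    feed_t = readr::col_double(), supply_chain_loss_t = readr::col_double(),
    nonfood_t = readr::col_double()
  ), "balance table")
  validate_balance_table(df)
}

#' @rdname read_balance_table
#' @param df A data frame to validate in place of reading from disk.
#' @export
validate_balance_table <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("item_id", "group_id", "year", "production_t",
                        "feed_t", "supply_chain_loss_t", "nonfood_t"),
                  "balance table")
  check_unique_keys(df, c("item_id", "year"), "balance table")
  check_finite_nonneg(df, c("production_t", "feed_t", "supply_chain_loss_t",
                            "nonfood_t"),
                      c("item_id", "year"), "balance table")
  over <- df$feed_t + df$supply_chain_loss_t + df$nonfood_t >
    df$production_t * (1 + 1e-9)
  if (any(over)) {
    labels <- paste0(df$item_id[over], "/", df$year[over])
    stop_validation("balance table: feed + loss + nonfood exceeds production",
                    " for (item, year): ", fmt_keys(labels))
  }
  multi <- df |> distinct(.data$item_id, .data$group_id) |>
    group_by(.data$item_id) |> filter(n() > 1) |> ungroup()
  if (nrow(multi) > 0) {
    stop_validation("balance table: item(s) assigned to multiple groups: ",
                    fmt_keys(multi$item_id))
  }
  df
}

#' Read item nutrient profiles
#'
#' Reads the long-format item profile CSV: one row per (item, nutrient)
#' carrying the item's group membership, plant/animal origin and inedible
#' fraction (repeated across the item's rows) together with the nutrient
#' density per 100 g of edible portion and a digestibility coefficient.
#' Digestibility is meaningful for protein and the indispensable amino
#' acids; for every other nutrient it must be 1 (the loader defaults a
#' missing value to 1).
#'
#' @param path Path to a CSV with columns `item_id`, `group_id`, `origin`,
#'   `inedible_fraction`, `nutrient_id`, `unit`, `density_per_100g`,
#'   `digestibility`.
#' @return A validated long tibble of item profiles.
#' @export
read_item_profiles <- function(path) {
  df <- read_csv_strict(path, list(
    item_id = readr::col_character(), group_id = readr::col_character(),
    origin = readr::col_character(),
    inedible_fraction = readr::col_double(),
    nutrient_id = readr::col_character(), unit = readr::col_character(),
    density_per_100g = readr::col_double(),
    digestibility = readr::col_double()
  ), "item profiles")
  validate_item_profiles(df)
}

#' @rdname read_item_profiles
#' @param df A data frame to validate in place of reading from disk.
#' @export
validate_item_profiles <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("item_id", "group_id", "origin", "inedible_fraction",
                        "nutrient_id", "unit", "density_per_100g",
                        "digestibility"), "item profiles")
  df$digestibility[is.na(df$digestibility)] <- 1
  check_unique_keys(df, c("item_id", "nutrient_id"), "item profiles")
  bad_origin <- !df$origin %in% c("plant", "animal")
  if (any(bad_origin)) {
    stop_validation("item profiles: origin must be 'plant' or 'animal';",
                    " offending item(s): ", fmt_keys(df$item_id[bad_origin]))
  }
  check_in_unit_interval(df, "inedible_fraction", "item_id", "item profiles")
  check_in_unit_interval(df, "digestibility",
                         c("item_id", "nutrient_id"), "item profiles")
  check_finite_nonneg(df, "density_per_100g",
                      c("item_id", "nutrient_id"), "item profiles")
  incons <- df |>
    distinct(.data$item_id, .data$group_id, .data$origin,
             .data$inedible_fraction) |>
    group_by(.data$item_id) |> filter(n() > 1) |> ungroup()
  if (nrow(incons) > 0) {
    stop_validation("item profiles: inconsistent group/origin/inedible",
                    " across rows of item(s): ", fmt_keys(incons$item_id))
  }
  unit_incons <- df |> distinct(.data$nutrient_id, .data$unit) |>
    group_by(.data$nutrient_id) |> filter(n() > 1) |> ungroup()
  if (nrow(unit_incons) > 0) {
    stop_validation("item profiles: conflicting units for nutrient(s): ",
                    fmt_keys(unit_incons$nutrient_id))
  }
  df
}

#' Read the regional in-home waste table
#'
#' In-home waste is the edible food discarded after purchase, expressed as
#' a fraction specific to each (region, food group) pair.
#'
#' @param path Path to a CSV with columns `region_id`, `group_id`,
#'   `waste_fraction`.
#' @return A validated tibble.
#' @export
read_waste_table <- function(path) {
  df <- read_csv_strict(path, list(
    region_id = readr::col_character(), group_id = readr::col_character(),
    waste_fraction = readr::col_double()
  ), "waste table")
  validate_waste_table(df)
}

#' @rdname read_waste_table
#' @param df A data frame to validate in place of reading from disk.
#' @export
validate_waste_table <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("region_id", "group_id", "waste_fraction"),
                  "waste table")
  check_unique_keys(df, c("region_id", "group_id"), "waste table")
  check_in_unit_interval(df, "waste_fraction",
                         c("region_id", "group_id"), "waste table")
  df
}

#' Read the demographic table
#'
#' Population counts per (region, sex, age group, year). Sexes are coded
#' `F`/`M`; region and age-group vocabularies are data-driven.
#'
#' @param path Path to a CSV with columns `region_id`, `sex`, `age_group`,
#'   `year`, `population`.
#' @return A validated tibble.
#' @export
read_demographics <- function(path) {
  df <- read_csv_strict(path, list(
    region_id = readr::col_character(), sex = readr::col_character(),
    age_group = readr::col_character(), year = readr::col_integer(),
    population = readr::col_double()
  ), "demographics")
  validate_demographics(df)
}

#' @rdname read_demographics
#' @param df A data frame to validate in place of reading from disk.
#' @export
validate_demographics <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("region_id", "sex", "age_group", "year",
                        "population"), "demographics")
  bad_sex <- !df$sex %in% c("F", "M")
  if (any(bad_sex)) {
    stop_validation("demographics: sex must be 'F' or 'M'; offending rows: ",
                    fmt_keys(paste0(df$region_id[bad_sex], "/",
                                    df$age_group[bad_sex])))
  }
  check_unique_keys(df, c("region_id", "sex", "age_group", "year"),
                    "demographics")
  check_finite_nonneg(df, "population",
                      c("region_id", "sex", "age_group", "year"),
                      "demographics")
  df
}

#' Read the dietary reference value table
#'
#' One row per (nutrient, sex, age group) with the target daily intake and,
#' where available, lower and upper safe-intake bounds. Iron and zinc rows
#' may additionally carry alternate (higher) targets used for vegetarian
#' and vegan scenarios, where the absence of animal-sourced foods lowers
#' absorption of those minerals.
#'
#' @param path Path to a CSV with columns `nutrient_id`, `sex`, `age_group`,
#'   `unit`, `target`, `lower_safe`, `upper_safe`, `alt_target_vegetarian`,
#'   `alt_target_vegan` (the last four may be empty).
#' @return A validated tibble.
#' @export
read_drv_table <- function(path) {
  df <- read_csv_strict(path, list(
    nutrient_id = readr::col_character(), sex = readr::col_character(),
    age_group = readr::col_character(), unit = readr::col_character(),
    target = readr::col_double(), lower_safe = readr::col_double(),
    upper_safe = readr::col_double(),
    alt_target_vegetarian = readr::col_double(),
    alt_target_vegan = readr::col_double()
  ), "DRV table")
  validate_drv_table(df)
}

#' @rdname read_drv_table
#' @param df A data frame to validate in place of reading from disk.
#' @export
validate_drv_table <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("nutrient_id", "sex", "age_group", "unit", "target"),
                  "DRV table")
  for (col in c("lower_safe", "upper_safe", "alt_target_vegetarian",
                "alt_target_vegan")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  check_unique_keys(df, c("nutrient_id", "sex", "age_group"), "DRV table")
  keys <- c("nutrient_id", "sex", "age_group")
  bad <- !is.finite(df$target) | df$target <= 0
  if (any(bad)) {
    labels <- apply(df[bad, keys], 1, paste, collapse = "/")
    stop_validation("DRV table: target must be > 0; offending (",
                    paste(keys, collapse = ", "), "): ", fmt_keys(labels))
  }
  bad <- !is.na(df$lower_safe) & df$lower_safe > df$target
  bad <- bad | (!is.na(df$upper_safe) & df$upper_safe < df$target)
  if (any(bad)) {
    labels <- apply(df[bad, keys], 1, paste, collapse = "/")
    stop_validation("DRV table: requires lower_safe <= target <= upper_safe;",
                    " offending rows: ", fmt_keys(labels))
  }
  for (col in c("alt_target_vegetarian", "alt_target_vegan")) {
    bad <- !is.na(df[[col]]) & df[[col]] < df$target
    if (any(bad)) {
      labels <- apply(df[bad, keys], 1, paste, collapse = "/")
      stop_validation("DRV table: ", col, " must be >= target;",
                      " offending rows: ", fmt_keys(labels))
    }
  }
  unit_incons <- df |> distinct(.data$nutrient_id, .data$unit) |>
    group_by(.data$nutrient_id) |> filter(n() > 1) |> ungroup()
  if (nrow(unit_incons) > 0) {
    stop_validation("DRV table: conflicting units for nutrient(s): ",
                    fmt_keys(unit_incons$nutrient_id))
  }
  df
}

#' Read the food-group vocabulary
#'
#' Groups are data-driven, not hard-coded: a miniature test world may use 3
#' groups while a full dataset uses 15. Each group declares its origin
#' (`plant`/`animal`) and, for animal groups, whether it is a meat/fish
#' group or a dairy/egg group (`animal_food_type`: `meat_fish`,
#' `dairy_egg`, or empty for plant groups). That distinction drives
#' vegetarian-vs-vegan diet-mode detection.
#'
#' @param path Path to a CSV with columns `group_id`, `origin`,
#'   `animal_food_type`.
#' @return A validated tibble.
#' @export
read_groups <- function(path) {
  df <- read_csv_strict(path, list(
    group_id = readr::col_character(), origin = readr::col_character(),
    animal_food_type = readr::col_character()
  ), "groups table")
  validate_groups(df)
}

#' @rdname read_groups
#' @param df A data frame to validate in place of reading from disk.
#' @export
validate_groups <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("group_id", "origin"), "groups table")
  if (!"animal_food_type" %in% names(df)) df$animal_food_type <- NA_character_
  check_unique_keys(df, "group_id", "groups table")
  bad <- !df$origin %in% c("plant", "animal")
  if (any(bad)) {
    stop_validation("groups table: origin must be 'plant' or 'animal';",
                    " offending group(s): ", fmt_keys(df$group_id[bad]))
  }
  bad <- df$origin == "animal" &
    !df$animal_food_type %in% c("meat_fish", "dairy_egg")
  if (any(bad)) {
    stop_validation("groups table: animal groups need animal_food_type",
                    " 'meat_fish' or 'dairy_egg'; offending group(s): ",
                    fmt_keys(df$group_id[bad]))
  }
  df
}

#' Read the region vocabulary
#'
#' @param path Path to a CSV with a `region_id` column.
#' @return A validated tibble.
#' @export
read_regions <- function(path) {
  df <- read_csv_strict(path, list(region_id = readr::col_character()),
                        "regions table")
  require_columns(df, "region_id", "regions table")
  check_unique_keys(df, "region_id", "regions table")
  df
}

# Reads the CSV with all columns as text, then converts each declared
# column with base strtod (as.numeric/as.integer). The text detour keeps
# the round trip exact to the last bit: the fast multi-threaded double
# parser can land one ULP off the correctly rounded value.
read_csv_strict <- function(path, col_spec, table) {
  if (!file.exists(path)) {
    stop_schema(table, ": file not found: ", path)
  }
  raw <- readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE)
  missing <- setdiff(names(col_spec), names(raw))
  if (length(missing) > 0) {
    stop_schema(table, ": missing required column(s): ", fmt_keys(missing))
  }
  out <- raw[names(col_spec)]
  for (col in names(col_spec)) {
    cls <- class(col_spec[[col]])[1]
    if (cls == "collector_double" || cls == "collector_integer") {
      txt <- out[[col]]
      val <- suppressWarnings(as.numeric(txt))
      bad <- !is.na(txt) & txt != "" & is.na(val)
      if (any(bad)) {
        stop_schema(table, ": column ", col, " has non-numeric value(s): ",
                    fmt_keys(txt[bad]))
      }
      out[[col]] <- if (cls == "collector_integer") as.integer(val) else val
    }
  }
  out
}

#' Load and cross-validate a complete model world
#'
#' Reads the seven standard tables (`balance.csv`, `items.csv`, `waste.csv`,
#' `demographics.csv`, `drv.csv`, `groups.csv`, `regions.csv`) from a
#' directory and cross-validates them: every item and group reference must
#' resolve, every region in the waste table must be declared, and the unit
#' carried for each nutrient must agree between the item profiles and the
#' DRV table (no unit conversion is ever performed).
#'
#' @param dir Directory containing the seven CSV files.
#' @return A `delta_world` object: a named list of validated tibbles
#'   (`balance`, `items`, `waste`, `demographics`, `drv`, `groups`,
#'   `regions`).
#' @export
read_world <- function(dir) {
  world <- new_world(
    balance = read_balance_table(file.path(dir, "balance.csv")),
    items = read_item_profiles(file.path(dir, "items.csv")),
    waste = read_waste_table(file.path(dir, "waste.csv")),
    demographics = read_demographics(file.path(dir, "demographics.csv")),
    drv = read_drv_table(file.path(dir, "drv.csv")),
    groups = read_groups(file.path(dir, "groups.csv")),
    regions = read_regions(file.path(dir, "regions.csv"))
  )
  validate_world(world)
}

new_world <- function(balance, items, waste, demographics, drv, groups,
                      regions) {
  structure(list(balance = balance, items = items, waste = waste,
                 demographics = demographics, drv = drv, groups = groups,
                 regions = regions),
            class = "delta_world")
}

#' @rdname read_world
#' @param world A `delta_world` object to cross-validate.
#' @export
validate_world <- function(world) {
  g <- world$groups$group_id
  r <- world$regions$region_id
  bad <- setdiff(world$balance$group_id, g)
  if (length(bad) > 0) {
    stop_validation("balance table: unknown group(s): ", fmt_keys(bad))
  }
  bad <- setdiff(world$items$group_id, g)
  if (length(bad) > 0) {
    stop_validation("item profiles: unknown group(s): ", fmt_keys(bad))
  }
  bad <- setdiff(world$waste$group_id, g)
  if (length(bad) > 0) {
    stop_validation("waste table: unknown group(s): ", fmt_keys(bad))
  }
  bad <- setdiff(world$waste$region_id, r)
  if (length(bad) > 0) {
    stop_validation("waste table: unknown region(s): ", fmt_keys(bad))
  }
  bad <- setdiff(world$demographics$region_id, r)
  if (length(bad) > 0) {
    stop_validation("demographics: unknown region(s): ", fmt_keys(bad))
  }
  bad <- setdiff(unique(world$balance$item_id),
                 unique(world$items$item_id))
  if (length(bad) > 0) {
    stop_validation("balance table: item(s) without a profile: ",
                    fmt_keys(bad))
  }
  item_group <- world$balance |> distinct(.data$item_id, .data$group_id)
  mism <- item_group |>
    inner_join(world$items |> distinct(.data$item_id,
                                       profile_group = .data$group_id),
               by = "item_id") |>
    filter(.data$group_id != .data$profile_group)
  if (nrow(mism) > 0) {
    stop_validation("item profiles: group disagrees with balance table for",
                    " item(s): ", fmt_keys(mism$item_id))
  }
  # units must agree per nutrient between composition and DRV tables
  units <- world$items |> distinct(.data$nutrient_id, .data$unit) |>
    inner_join(world$drv |> distinct(.data$nutrient_id,
                                     drv_unit = .data$unit),
               by = "nutrient_id") |>
    filter(.data$unit != .data$drv_unit)
  if (nrow(units) > 0) {
    stop_validation("unit mismatch between item profiles and DRV table for",
                    " nutrient(s): ", fmt_keys(units$nutrient_id))
  }
  world
}

#' @export
print.delta_world <- function(x, ...) {
  cat("<delta_world>\n")
  cat("  items:      ", length(unique(x$items$item_id)), "in",
      nrow(x$groups), "groups\n")
  cat("  balance:    ", nrow(x$balance), "rows, years",
      min(x$balance$year), "-", max(x$balance$year), "\n")
  cat("  nutrients:  ", length(unique(x$drv$nutrient_id)), "\n")
  cat("  regions:    ", nrow(x$regions), "; demographic strata:",
      nrow(distinct(x$demographics, .data$region_id, .data$sex,
                    .data$age_group)), "\n")
  invisible(x)
}

#' Convert a native food-balance download to the model's balance schema
#'
#' Placeholder converter: national balance-sheet downloads arrive in many
#' dialects (element codes, wide years, locale separators). Mapping them is
#' left to the data preparer; this stub documents the expected target schema
#' and fails with guidance.
#'
#' @param path Path to a native-format download.
#' @return Never returns; raises an informative error.
#' @export
convert_fbs_download <- function(path) {
  abort(paste0(
    "Automatic conversion of native balance-sheet downloads is not",
    " implemented. Reshape the download to the schema of balance.csv",
    " (item_id, group_id, year, production_t, feed_t, supply_chain_loss_t,",
    " nonfood_t; tons per year, one row per item-year). The mapping of",
    " element codes to the nonfood_t column is dataset-specific and is",
    " left to the data preparer."),
    class = "deltafood_not_implemented")
}
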