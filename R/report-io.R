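#' Write the three scenario reports
#'
#' Writes the mass-flow, nutrient-adequacy and nutrient-waste reports of a
#' run. In `csv` format, three files (`mass_report.csv`,
#' `nutrient_report.csv`, `waste_report.csv`) with fixed column orders:
#' mass — `item_id`, `group_id`, `production_t`, `feed_t`,
#' `supply_chain_loss_t`, `nonfood_t`, `inedible_t`, `in_home_waste_t`,
#' `consumed_edible_t`, `per_capita_g_day`; nutrients — `nutrient_id`,
#' `unit`, `supply`, `target`, `lower_safe`, `upper_safe`,
#' `pct_of_target`, `gap_pct`, `excess_pct`, `material`; waste —
#' `nutrient_id`, `wasted_amount`, `pct_of_target`, `plant_share_pct`,
#' `animal_share_pct`. Bounds that do not exist for a nutrient are empty
#' cells. In `json` format, one `report.json` document keyed
#' `mass_report` / `nutrient_report` / `waste_report`. Output is
#' byte-stable: identical inputs give identical files.
#'
#' @param run A `delta_run` from [run_scenario()].
#' @param out_dir Output directory (created if needed).
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(run, out_dir, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(run, "delta_run"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("write_reports: cannot create directory: ",
                          out_dir))
  }
  mass <- as_tibble(run$mass)
  nutrients <- as_tibble(run$nutrients)
  waste <- as_tibble(run$waste) |>
    select("nutrient_id", "wasted_amount", "pct_of_target",
           "plant_share_pct", "animal_share_pct")
  if (format == "csv") {
    paths <- file.path(out_dir, c("mass_report.csv", "nutrient_report.csv",
                                  "waste_report.csv"))
    readr::write_csv(mass, paths[1])
    readr::write_csv(nutrients, paths[2])
    readr::write_csv(waste, paths[3])
  } else {
    paths <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(mass_report = mass, nutrient_report = nutrients,
           waste_report = waste),
      paths, dataframe = "rows", na = "null", digits = NA,
      auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(paths)
}

#' Write a scenario comparison report
#'
#' One CSV with columns `nutrient_id`, `supply_a`, `supply_b`,
#' `delta_supply`, `delta_gap_pct`, in deterministic nutrient order.
#'
#' @param comparison A `delta_comparison` from [compare_scenarios()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "delta_comparison"))
  comparison$nutrients |>
    select("nutrient_id", "supply_a", "supply_b", "delta_supply",
           "delta_gap_pct") |>
    readr::write_csv(path)
  invisible(path)
}

#' Write a model world to a data directory
#'
#' Writes the seven standard CSV tables of a `delta_world` so the
#' directory can be read back with [read_world()]. The round trip is
#' lossless at full float precision, and regeneration is byte-identical.
#'
#' @param world A `delta_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(world$balance, file.path(dir, "balance.csv"))
  readr::write_csv(world$items, file.path(dir, "items.csv"))
  readr::write_csv(world$waste, file.path(dir, "waste.csv"))
  readr::write_csv(world$demographics, file.path(dir, "demographics.csv"))
  readr::write_csv(world$drv, file.path(dir, "drv.csv"))
  readr::write_csv(world$groups, file.path(dir, "groups.csv"))
  readr::write_csv(world$regions, file.path(dir, "regions.csv"))
  invisible(dir)
}
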