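#' Construct a scenario definition
#'
#' A scenario states how a food system deviates from the baseline: per-group
#' production (absolute tons or a multiplier of baseline, exactly one per
#' group), optional group zeroing with compensation, optional removal of a
#' group with proportional reallocation of its biomass, waste multipliers,
#' the population year, how nonfood use scales, and the diet mode governing
#' which iron/zinc targets apply.
#'
#' @param name Scenario name.
#' @param population_year Calendar year whose population the scenario feeds;
#'   `NULL` means the baseline year.
#' @param groups Named list, one entry per overridden group, each either
#'   `list(tons = X)` or `list(multiplier = Y)`. Unnamed groups default to
#'   multiplier 1.
#' @param zero_groups Character vector of groups to set to zero.
#' @param compensation_factor Multiplier applied to all groups not in
#'   `zero_groups` (default 1).
#' @param remove_group A single group whose production is removed and
#'   reallocated.
#' @param recipients Groups receiving the removed biomass, proportionally
#'   to their production; default (`NULL`) is all remaining plant groups.
#' @param supply_chain_waste_multiplier,in_home_waste_multiplier
#'   Non-negative multipliers on baseline waste fractions (1 = baseline,
#'   0 = no waste).
#' @param nonfood_mode `"per_capita_constant"` (baseline nonfood tonnage
#'   scaled with population) or `"proportional_to_production"` (baseline
#'   nonfood fraction applied to scenario production).
#' @param diet_mode `"auto"` (detect from animal-group production),
#'   `"omnivore"`, `"vegetarian"` or `"vegan"`.
#' @return A `delta_scenario` object.
#' @export
scenario <- function(name = "scenario", population_year = NULL,
                     groups = list(), zero_groups = character(),
                     compensation_factor = 1, remove_group = NULL,
                     recipients = NULL,
                     supply_chain_waste_multiplier = 1,
                     in_home_waste_multiplier = 1,
                     nonfood_mode = c("per_capita_constant",
                                      "proportional_to_production"),
                     diet_mode = c("auto", "omnivore", "vegetarian",
                                   "vegan")) {
  nonfood_mode <- match.arg(nonfood_mode)
  diet_mode <- match.arg(diet_mode)
  for (m in c(supply_chain_waste_multiplier, in_home_waste_multiplier,
              compensation_factor)) {
    if (!is.finite(m) || m < 0) {
      stop_validation("scenario: multipliers must be finite and >= 0")
    }
  }
  for (gid in names(groups)) {
    spec <- groups[[gid]]
    if (!is.list(spec) ||
        length(intersect(names(spec), c("tons", "multiplier"))) != 1) {
      stop_validation("scenario: group '", gid, "' must give exactly one of",
                      " 'tons' or 'multiplier'")
    }
    val <- spec[[intersect(names(spec), c("tons", "multiplier"))]]
    if (!is.numeric(val) || !is.finite(val) || val < 0) {
      stop_validation("scenario: group '", gid,
                      "' value must be finite and >= 0")
    }
  }
  structure(list(
    name = name, population_year = population_year, groups = groups,
    zero_groups = zero_groups, compensation_factor = compensation_factor,
    remove_group = remove_group, recipients = recipients,
    supply_chain_waste_multiplier = supply_chain_waste_multiplier,
    in_home_waste_multiplier = in_home_waste_multiplier,
    nonfood_mode = nonfood_mode, diet_mode = diet_mode
  ), class = "delta_scenario")
}

#' Read a scenario definition from YAML or JSON
#'
#' Applies defaults for anything unstated: all group multipliers 1, waste
#' multipliers 1, nonfood mode `per_capita_constant`, diet mode `auto`. An
#' empty document is therefore the baseline-identity scenario.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` scenario document.
#' @param known_groups Optional character vector of valid group ids; any
#'   group named in the document but absent from it is an error. Group ids
#'   are always checked again at resolution time against the baseline.
#' @return A `delta_scenario` object.
#' @export
read_scenario <- function(path, known_groups = NULL) {
  if (!file.exists(path)) stop_schema("scenario: file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  doc <- doc %||% list()
  known_keys <- c("name", "population_year", "groups", "zero_groups",
                  "compensation_factor", "remove_group", "recipients",
                  "waste", "nonfood_mode", "diet_mode")
  unknown <- setdiff(names(doc), known_keys)
  if (length(unknown) > 0) {
    stop_schema("scenario: unknown key(s): ", fmt_keys(unknown))
  }
  waste <- doc$waste %||% list()
  sc <- scenario(
    name = doc$name %||% sub("\\.[^.]+$", "", basename(path)),
    population_year = doc$population_year,
    groups = doc$groups %||% list(),
    zero_groups = as.character(doc$zero_groups %||% character()),
    compensation_factor = doc$compensation_factor %||% 1,
    remove_group = doc$remove_group,
    recipients = doc$recipients,
    supply_chain_waste_multiplier = waste$supply_chain %||% 1,
    in_home_waste_multiplier = waste$in_home %||% 1,
    nonfood_mode = doc$nonfood_mode %||% "per_capita_constant",
    diet_mode = doc$diet_mode %||% "auto"
  )
  if (!is.null(known_groups)) {
    referenced <- c(names(sc$groups), sc$zero_groups, sc$remove_group,
                    sc$recipients)
    bad <- setdiff(referenced, known_groups)
    if (length(bad) > 0) {
      stop_validation("scenario: unknown group(s): ", fmt_keys(bad))
    }
  }
  sc
}

#' Resolve a scenario against a baseline
#'
#' Turns a scenario definition into absolute per-group productions by
#' applying, in order: per-group tons/multipliers on baseline production;
#' zeroing with compensation ([zero_groups_with_compensation()]); removal
#' with reallocation ([remove_and_reallocate()]); and diet-mode detection
#' when the mode is `auto`.
#'
#' @param sc A `delta_scenario`.
#' @param baseline A `delta_baseline` from [prepare_baseline()].
#' @param groups The groups vocabulary table (for origin lookups).
#' @param diet_threshold Fraction of baseline production below which an
#'   animal group counts as absent for diet-mode detection (default 0.01).
#' @return A `delta_resolved` object: tibble `group_production`
#'   (`group_id`, `production_t`), waste multipliers, `population_year`,
#'   `nonfood_mode`, and a concrete `diet_mode`.
#' @export
resolve_scenario <- function(sc, baseline, groups,
                             diet_threshold = 0.01) {
  stopifnot(inherits(sc, "delta_scenario"),
            inherits(baseline, "delta_baseline"))
  groups <- validate_groups(groups)
  known <- baseline$groups$group_id
  referenced <- c(names(sc$groups), sc$zero_groups, sc$remove_group,
                  sc$recipients)
  bad <- setdiff(referenced, known)
  if (length(bad) > 0) {
    stop_validation("scenario: unknown group(s): ", fmt_keys(bad))
  }

  gp <- baseline$groups |>
    rename(production_t = "baseline_production_t")
  for (gid in names(sc$groups)) {
    spec <- sc$groups[[gid]]
    i <- which(gp$group_id == gid)
    gp$production_t[i] <- if ("tons" %in% names(spec)) {
      spec$tons
    } else {
      gp$production_t[i] * spec$multiplier
    }
  }

  resolved <- new_resolved(
    group_production = gp,
    supply_chain_waste_multiplier = sc$supply_chain_waste_multiplier,
    in_home_waste_multiplier = sc$in_home_waste_multiplier,
    population_year = sc$population_year %||% baseline$baseline_year,
    nonfood_mode = sc$nonfood_mode,
    diet_mode = sc$diet_mode,
    name = sc$name
  )

  if (length(sc$zero_groups) > 0 || sc$compensation_factor != 1) {
    resolved <- zero_groups_with_compensation(resolved, sc$zero_groups,
                                              sc$compensation_factor)
  }
  if (!is.null(sc$remove_group)) {
    recipients <- sc$recipients
    if (is.null(recipients)) {
      plant <- groups$group_id[groups$origin == "plant"]
      recipients <- setdiff(intersect(plant, known), sc$remove_group)
    }
    resolved <- remove_and_reallocate(resolved, sc$remove_group, recipients)
  }
  if (identical(resolved$diet_mode, "auto")) {
    resolved$diet_mode <- detect_diet_mode(resolved, baseline, groups,
                                           threshold = diet_threshold)
  }
  resolved
}

new_resolved <- function(group_production, supply_chain_waste_multiplier,
                         in_home_waste_multiplier, population_year,
                         nonfood_mode, diet_mode, name) {
  structure(list(
    group_production = group_production,
    supply_chain_waste_multiplier = supply_chain_waste_multiplier,
    in_home_waste_multiplier = in_home_waste_multiplier,
    population_year = population_year,
    nonfood_mode = nonfood_mode,
    diet_mode = diet_mode,
    name = name
  ), class = "delta_resolved")
}

#' @export
print.delta_resolved <- function(x, ...) {
  cat("<delta_resolved> '", x$name, "': total biomass ",
      format(total_biomass(x), big.mark = ","), " t; year ",
      x$population_year, "; diet ", x$diet_mode, "\n", sep = "")
  cat("  waste multipliers: supply chain ",
      x$supply_chain_waste_multiplier, ", in-home ",
      x$in_home_waste_multiplier, "\n", sep = "")
  invisible(x)
}

#' Total farm-gate biomass of a resolved scenario
#'
#' @param resolved A `delta_resolved` scenario.
#' @return Total production over all groups, tons/yr.
#' @export
total_biomass <- function(resolved) {
  sum(resolved$group_production$production_t)
}

#' Scale every food group by a common factor
#'
#' @param resolved A `delta_resolved` scenario.
#' @param factor Non-negative multiplier applied to every group's
#'   production (1.12 models a 12% across-the-board scale-up).
#' @return The scaled `delta_resolved` scenario.
#' @export
scale_all_groups <- function(resolved, factor) {
  if (!is.finite(factor) || factor < 0) {
    stop_validation("scale_all_groups: factor must be finite and >= 0")
  }
  resolved$group_production$production_t <-
    resolved$group_production$production_t * factor
  resolved
}

#' Zero selected groups and compensate with the rest
#'
#' Sets the listed groups' production to zero and multiplies every other
#' group by `factor` (e.g. eliminating meat and seafood while raising all
#' remaining groups by 20%). [compensation_factor()] computes the factor
#' that would keep total biomass unchanged.
#'
#' @param resolved A `delta_resolved` scenario.
#' @param zero_groups Character vector of group ids to zero.
#' @param factor Multiplier for all remaining groups (default 1).
#' @return The transformed `delta_resolved` scenario.
#' @export
zero_groups_with_compensation <- function(resolved, zero_groups,
                                          factor = 1) {
  gp <- resolved$group_production
  bad <- setdiff(zero_groups, gp$group_id)
  if (length(bad) > 0) {
    stop_validation("zero_groups_with_compensation: unknown group(s): ",
                    fmt_keys(bad))
  }
  if (!is.finite(factor) || factor < 0) {
    stop_validation("zero_groups_with_compensation: factor must be >= 0")
  }
  zeroed <- gp$group_id %in% zero_groups
  gp$production_t[zeroed] <- 0
  gp$production_t[!zeroed] <- gp$production_t[!zeroed] * factor
  resolved$group_production <- gp
  resolved
}

#' Compensation factor preserving total biomass
#'
#' Reports the multiplier for the remaining groups under which zeroing
#' `zero_groups` leaves total biomass unchanged: `1 + m / R` with `m` the
#' removed mass and `R` the remaining mass.
#'
#' @inheritParams zero_groups_with_compensation
#' @return A single number.
#' @export
compensation_factor <- function(resolved, zero_groups) {
  gp <- resolved$group_production
  zeroed <- gp$group_id %in% zero_groups
  removed <- sum(gp$production_t[zeroed])
  remaining <- sum(gp$production_t[!zeroed])
  if (remaining == 0) {
    stop_validation("compensation_factor: remaining groups have zero",
                    " production")
  }
  1 + removed / remaining
}

#' Remove a group and reallocate its biomass
#'
#' Sets `removed_group` to zero and scales each recipient group by
#' `1 + m / R` (removed mass over recipients' total), which distributes
#' the removed biomass across recipients in proportion to their current
#' production and conserves total biomass exactly.
#'
#' @param resolved A `delta_resolved` scenario.
#' @param removed_group The group to remove.
#' @param recipients Character vector of recipient groups (must exclude
#'   `removed_group` and have positive total production).
#' @return The transformed `delta_resolved` scenario.
#' @export
remove_and_reallocate <- function(resolved, removed_group, recipients) {
  gp <- resolved$group_production
  bad <- setdiff(c(removed_group, recipients), gp$group_id)
  if (length(bad) > 0) {
    stop_validation("remove_and_reallocate: unknown group(s): ",
                    fmt_keys(bad))
  }
  if (removed_group %in% recipients) {
    stop_validation("remove_and_reallocate: removed group '", removed_group,
                    "' cannot be a recipient")
  }
  if (length(recipients) == 0) {
    stop_validation("remove_and_reallocate: recipients must be non-empty")
  }
  removed_mass <- gp$production_t[gp$group_id == removed_group]
  recipient_mass <- sum(gp$production_t[gp$group_id %in% recipients])
  if (recipient_mass <= 0) {
    stop_validation("remove_and_reallocate: recipients have zero total",
                    " production; nothing to scale")
  }
  scale <- 1 + removed_mass / recipient_mass
  gp$production_t[gp$group_id == removed_group] <- 0
  idx <- gp$group_id %in% recipients
  gp$production_t[idx] <- gp$production_t[idx] * scale
  resolved$group_production <- gp
  resolved
}

#' Detect the diet mode of a resolved scenario
#'
#' Classifies the scenario by how much animal-sourced production remains
#' relative to baseline: `vegan` when every animal-origin group is below
#' `threshold` (default 1%) of its baseline production; `vegetarian` when
#' all meat/fish groups are below the threshold but dairy or egg groups
#' remain; `omnivore` otherwise. The detected mode selects which iron and
#' zinc intake targets apply (plant-based diets absorb these minerals less
#' efficiently, so their targets are higher).
#'
#' @param resolved A `delta_resolved` scenario.
#' @param baseline A `delta_baseline` (supplies baseline group production).
#' @param groups The groups vocabulary table (origin and animal food type).
#' @param threshold Fraction of baseline production below which an animal
#'   group counts as absent (default 0.01).
#' @return One of `"omnivore"`, `"vegetarian"`, `"vegan"`.
#' @export
detect_diet_mode <- function(resolved, baseline, groups,
                             threshold = 0.01) {
  groups <- validate_groups(groups)
  tbl <- resolved$group_production |>
    left_join(baseline$groups, by = "group_id") |>
    left_join(groups, by = "group_id") |>
    filter(.data$origin == "animal")
  if (nrow(tbl) == 0) return("vegan")
  absent <- tbl$production_t < threshold * tbl$baseline_production_t |
    (tbl$baseline_production_t == 0 & tbl$production_t == 0)
  if (all(absent)) return("vegan")
  meat <- tbl$animal_food_type == "meat_fish"
  if (all(absent[meat]) && any(!absent[!meat])) return("vegetarian")
  "omnivore"
}
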