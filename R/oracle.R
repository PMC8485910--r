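#' Brute-force reference evaluation of a scenario
#'
#' Recomputes the entire pipeline — baseline shares, scenario resolution,
#' the mass cascade, nutrient supply, demographically weighted targets,
#' adequacy and waste accounting — by direct, unoptimized nested
#' iteration over plain vectors, sharing no code with the pipeline
#' functions (even the baseline-trend fit goes through [stats::lm()]
#' rather than the pipeline's closed-form solve). It exists purely as an
#' equivalence oracle for tests: any disagreement beyond floating-point
#' noise indicates a defect in one of the two routes. Infeasible
#' scenarios raise the same error class as the pipeline. Explicit feed
#' attribution tables are not supported (the proportional fallback is
#' always used).
#'
#' @param world A `delta_world`.
#' @param sc A `delta_scenario` (default: baseline identity).
#' @param days_per_year Days in the model year (default 365).
#' @param material_threshold_pct Gap materiality threshold (default 5).
#' @param diet_threshold Diet-detection threshold (default 0.01).
#' @return A list with `mass`, `nutrients`, `waste` data frames, the
#'   `targets` data frame and the scenario `population`, mirroring
#'   [run_scenario()] output columns.
#' @export
oracle_evaluate <- function(world, sc = scenario(), days_per_year = 365,
                            material_threshold_pct = 5,
                            diet_threshold = 0.01) {
  bal <- as.data.frame(world$balance)
  prof <- as.data.frame(world$items)
  demo <- as.data.frame(world$demographics)
  drv <- as.data.frame(world$drv)
  grp <- as.data.frame(world$groups)
  wst <- as.data.frame(world$waste)

  items <- sort(unique(bal$item_id))
  item_group <- sapply(items, function(i) bal$group_id[bal$item_id == i][1])
  groups_all <- sort(unique(grp$group_id))

  # ---- pooled shares and fractions --------------------------------------
  pooled_prod <- pooled_feed <- pooled_loss <- pooled_nonfood <-
    stats::setNames(numeric(length(items)), items)
  for (i in items) {
    rows <- bal[bal$item_id == i, ]
    pooled_prod[i] <- sum(rows$production_t)
    pooled_feed[i] <- sum(rows$feed_t)
    pooled_loss[i] <- sum(rows$supply_chain_loss_t)
    pooled_nonfood[i] <- sum(rows$nonfood_t)
  }
  feed_frac <- ifelse(pooled_prod > 0, pooled_feed / pooled_prod, 0)
  loss_frac <- ifelse(pooled_prod > 0, pooled_loss / pooled_prod, 0)
  nonfood_frac <- ifelse(pooled_prod > 0, pooled_nonfood / pooled_prod, 0)

  # ---- baseline production via lm at baseline year ----------------------
  base_year <- max(bal$year) + 1
  base_prod <- stats::setNames(numeric(length(items)), items)
  for (i in items) {
    rows <- bal[bal$item_id == i, ]
    rows <- rows[order(rows$year), ]
    yrs <- sort(unique(rows$year))
    w <- seq(1, 2, length.out = length(yrs))[match(rows$year, yrs)]
    fit <- stats::lm(production_t ~ year, data = rows, weights = w)
    base_prod[i] <- max(0, unname(stats::predict(
      fit, newdata = data.frame(year = base_year))))
  }
  group_base <- stats::setNames(numeric(length(groups_all)), groups_all)
  for (g in groups_all) {
    group_base[g] <- sum(base_prod[item_group == g])
  }
  item_share <- stats::setNames(numeric(length(items)), items)
  for (i in items) {
    gsum <- sum(pooled_prod[item_group == item_group[i]])
    item_share[i] <- pooled_prod[i] / gsum
  }

  pop_at <- function(year) {
    total <- 0
    key <- paste(demo$region_id, demo$sex, demo$age_group)
    for (k in unique(key)) {
      rows <- demo[key == k, ]
      rows <- rows[order(rows$year), ]
      if (nrow(rows) == 1) {
        if (rows$year != year) stop("oracle: year not tabulated")
        total <- total + rows$population
      } else {
        total <- total +
          stats::approx(rows$year, rows$population, xout = year,
                        rule = 1)$y
      }
    }
    total
  }
  pop_region_at <- function(year) {
    out <- stats::setNames(numeric(0), character(0))
    for (r in unique(demo$region_id)) {
      sub <- demo[demo$region_id == r, ]
      total <- 0
      key <- paste(sub$sex, sub$age_group)
      for (k in unique(key)) {
        rows <- sub[key == k, ]
        rows <- rows[order(rows$year), ]
        total <- total + if (nrow(rows) == 1) rows$population else
          stats::approx(rows$year, rows$population, xout = year,
                        rule = 1)$y
      }
      out[r] <- total
    }
    out
  }
  base_population <- pop_at(base_year)

  # ---- scenario resolution ----------------------------------------------
  gp <- group_base
  for (g in names(sc$groups)) {
    spec <- sc$groups[[g]]
    gp[g] <- if ("tons" %in% names(spec)) spec$tons else
      gp[g] * spec$multiplier
  }
  if (length(sc$zero_groups) > 0 || sc$compensation_factor != 1) {
    for (g in groups_all) {
      gp[g] <- if (g %in% sc$zero_groups) 0 else
        gp[g] * sc$compensation_factor
    }
  }
  if (!is.null(sc$remove_group)) {
    recipients <- sc$recipients
    if (is.null(recipients)) {
      recipients <- setdiff(
        grp$group_id[grp$origin == "plant"], sc$remove_group)
    }
    m <- gp[sc$remove_group]
    r <- sum(gp[recipients])
    gp[sc$remove_group] <- 0
    for (g in recipients) gp[g] <- gp[g] * (1 + m / r)
  }

  animal_groups <- grp$group_id[grp$origin == "animal"]
  diet <- sc$diet_mode
  if (diet == "auto") {
    absent <- logical(0)
    for (g in animal_groups) {
      absent[g] <- gp[g] < diet_threshold * group_base[g] ||
        (group_base[g] == 0 && gp[g] == 0)
    }
    meat <- grp$animal_food_type[match(animal_groups, grp$group_id)] ==
      "meat_fish"
    diet <- if (length(animal_groups) == 0 || all(absent)) "vegan"
    else if (all(absent[meat]) && any(!absent[!meat])) "vegetarian"
    else "omnivore"
  }

  pop_year <- if (is.null(sc$population_year)) base_year else
    sc$population_year
  population <- pop_at(pop_year)

  # ---- mass cascade ------------------------------------------------------
  scalars <- prof[!duplicated(prof$item_id), ]
  rownames(scalars) <- scalars$item_id
  pops_r <- pop_region_at(pop_year)
  ih_frac <- stats::setNames(numeric(length(groups_all)), groups_all)
  for (g in unique(wst$group_id)) {
    acc <- 0
    for (r in names(pops_r)) {
      w <- wst$waste_fraction[wst$region_id == r & wst$group_id == g]
      acc <- acc + pops_r[r] * (if (length(w) == 1) w else 0)
    }
    ih_frac[g] <- acc / sum(pops_r)
  }

  total_animal_base <- sum(group_base[animal_groups])
  mass <- data.frame()
  for (i in items) {
    g <- item_group[i]
    production <- item_share[i] * gp[g]
    feed <- 0
    base_feed_i <- feed_frac[i] * base_prod[i]
    if (base_feed_i > 0) {
      for (ag in animal_groups) {
        ratio <- if (group_base[ag] > 0) gp[ag] / group_base[ag] else 0
        feed <- feed + base_feed_i * group_base[ag] / total_animal_base *
          ratio
      }
    }
    if (feed > production * (1 + 1e-9)) {
      stop_infeasible("oracle: feed demand exceeds production for item ", i)
    }
    loss <- loss_frac[i] * production * sc$supply_chain_waste_multiplier
    if (loss_frac[i] * sc$supply_chain_waste_multiplier > 1 + 1e-12) {
      stop_infeasible("oracle: effective loss fraction exceeds 1 for ", i)
    }
    nonfood <- if (sc$nonfood_mode == "per_capita_constant") {
      nonfood_frac[i] * base_prod[i] * population / base_population
    } else {
      nonfood_frac[i] * production
    }
    avail <- production - feed - loss - nonfood
    if (avail < -1e-9 * max(production, 1)) {
      stop_infeasible("oracle: negative availability for item ", i)
    }
    avail <- max(avail, 0)
    inedible <- scalars[i, "inedible_fraction"] * avail
    edible <- avail - inedible
    wf <- ih_frac[g] * sc$in_home_waste_multiplier
    if (wf > 1 + 1e-12) {
      stop_infeasible("oracle: effective in-home waste fraction exceeds 1")
    }
    in_home <- wf * edible
    consumed <- edible - in_home
    mass <- rbind(mass, data.frame(
      item_id = i, group_id = g, production_t = production, feed_t = feed,
      supply_chain_loss_t = loss, nonfood_t = nonfood,
      inedible_t = inedible, in_home_waste_t = in_home,
      consumed_edible_t = consumed,
      per_capita_g_day = consumed * 1e6 / population / days_per_year))
  }
  mass <- mass[order(mass$group_id, mass$item_id), ]
  rownames(mass) <- NULL

  # ---- nutrient supply ---------------------------------------------------
  nutrients <- sort(unique(drv$nutrient_id))
  units <- sapply(nutrients,
                  function(n) drv$unit[drv$nutrient_id == n][1])
  supply <- wasted <- plant_wasted <-
    stats::setNames(numeric(length(nutrients)), nutrients)
  for (n in nutrients) {
    for (i in items) {
      row <- prof[prof$item_id == i & prof$nutrient_id == n, ]
      if (nrow(row) == 0) next
      alloc <- mass$per_capita_g_day[mass$item_id == i]
      coef <- row$density_per_100g * row$digestibility / 100
      supply[n] <- supply[n] + alloc * coef
      wg <- ((1 - scalars[i, "inedible_fraction"]) *
               mass$supply_chain_loss_t[mass$item_id == i] +
               mass$in_home_waste_t[mass$item_id == i]) * 1e6 /
        population / days_per_year
      wasted[n] <- wasted[n] + wg * coef
      if (row$origin == "plant") {
        plant_wasted[n] <- plant_wasted[n] + wg * coef
      }
    }
  }

  # ---- weighted targets --------------------------------------------------
  strata <- unique(demo[, c("sex", "age_group")])
  share <- numeric(nrow(strata))
  for (s in seq_len(nrow(strata))) {
    tot <- 0
    key <- paste(demo$region_id, demo$sex, demo$age_group)
    sub <- demo[demo$sex == strata$sex[s] &
                  demo$age_group == strata$age_group[s], ]
    for (k in unique(paste(sub$region_id))) {
      rows <- sub[sub$region_id == k, ]
      rows <- rows[order(rows$year), ]
      tot <- tot + if (nrow(rows) == 1) rows$population else
        stats::approx(rows$year, rows$population, xout = pop_year,
                      rule = 1)$y
    }
    share[s] <- tot
  }
  share <- share / sum(share)

  target <- lower <- upper <- stats::setNames(rep(NA_real_,
                                                  length(nutrients)),
                                              nutrients)
  for (n in nutrients) {
    t_acc <- l_acc <- u_acc <- 0
    l_ok <- u_ok <- TRUE
    for (s in seq_len(nrow(strata))) {
      row <- drv[drv$nutrient_id == n & drv$sex == strata$sex[s] &
                   drv$age_group == strata$age_group[s], ]
      tval <- row$target
      if (diet == "vegetarian" && !is.na(row$alt_target_vegetarian)) {
        tval <- row$alt_target_vegetarian
      }
      if (diet == "vegan" && !is.na(row$alt_target_vegan)) {
        tval <- row$alt_target_vegan
      }
      t_acc <- t_acc + share[s] * tval
      if (is.na(row$lower_safe)) l_ok <- FALSE else
        l_acc <- l_acc + share[s] * row$lower_safe
      if (is.na(row$upper_safe)) u_ok <- FALSE else
        u_acc <- u_acc + share[s] * row$upper_safe
    }
    target[n] <- t_acc
    lower[n] <- if (l_ok) l_acc else NA_real_
    upper[n] <- if (u_ok) u_acc else NA_real_
  }

  nutrient_report <- data.frame(
    nutrient_id = nutrients, unit = unname(units),
    supply = unname(supply[nutrients]), target = unname(target),
    lower_safe = unname(lower), upper_safe = unname(upper))
  nutrient_report$pct_of_target <-
    100 * nutrient_report$supply / nutrient_report$target
  nutrient_report$gap_pct <- pmax(
    0, 100 * (nutrient_report$target - nutrient_report$supply) /
      nutrient_report$target)
  nutrient_report$excess_pct <- ifelse(
    is.na(nutrient_report$upper_safe), NA_real_,
    pmax(0, 100 * (nutrient_report$supply - nutrient_report$upper_safe) /
           nutrient_report$upper_safe))
  nutrient_report$material <-
    nutrient_report$gap_pct > material_threshold_pct

  waste_report <- data.frame(
    nutrient_id = nutrients, unit = unname(units),
    wasted_amount = unname(wasted[nutrients]),
    pct_of_target = 100 * unname(wasted[nutrients]) / unname(target),
    plant_share_pct = ifelse(
      wasted[nutrients] > 0,
      100 * unname(plant_wasted[nutrients]) / unname(wasted[nutrients]),
      NA_real_))
  waste_report$animal_share_pct <- ifelse(
    is.na(waste_report$plant_share_pct), NA_real_,
    100 - waste_report$plant_share_pct)

  list(mass = mass, nutrients = nutrient_report, waste = waste_report,
       targets = data.frame(nutrient_id = nutrients,
                            target = unname(target),
                            lower_safe = unname(lower),
                            upper_safe = unname(upper)),
       population = population, diet_mode = diet)
}
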