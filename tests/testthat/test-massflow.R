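test_that("group production distributes to items by baseline shares", {
  w <- analytic()
  b <- prepare_baseline(w)
  out <- distribute_to_items(
    tibble::tibble(group_id = "cereals", production_t = 100), b)
  expect_equal(tibble::deframe(out[, c("item_id", "production_t")]),
               c(maize = 100 / 3, wheat = 200 / 3))
  zero <- distribute_to_items(
    tibble::tibble(group_id = "cereals", production_t = 0), b)
  expect_equal(zero$production_t, c(0, 0))
  expect_error(
    distribute_to_items(
      tibble::tibble(group_id = "nope", production_t = 1), b),
    class = "deltafood_validation_error")
  # within-group sums reproduce group production exactly
  for (seed in 1:3) {
    wr <- make_world(seed = seed, shape = "mini")
    br <- prepare_baseline(wr)
    gp <- br$groups |>
      dplyr::transmute(group_id,
                       production_t = baseline_production_t * 1.3)
    items <- distribute_to_items(gp, br)
    sums <- items |> dplyr::group_by(group_id) |>
      dplyr::summarise(s = sum(production_t))
    expect_equal(tibble::deframe(sums),
                 tibble::deframe(gp |> dplyr::arrange(group_id)),
                 tolerance = 1e-12)
  }
})

test_that("feed demand scales with animal production ratios", {
  w <- analytic()
  b <- prepare_baseline(w)
  items <- b$items |>
    dplyr::transmute(item_id, production_t = baseline_production_t)
  base_feed <- compute_feed_use(
    items, b$feed_attribution,
    tibble::tibble(animal_group_id = "fish", ratio = 1))
  expect_equal(tibble::deframe(base_feed),
               c(fish = 0, maize = 100, wheat = 100))
  none <- compute_feed_use(
    items, b$feed_attribution,
    tibble::tibble(animal_group_id = "fish", ratio = 0))
  expect_equal(none$feed_t, c(0, 0, 0))
  up <- compute_feed_use(
    items, b$feed_attribution,
    tibble::tibble(animal_group_id = "fish", ratio = 1.2))
  expect_equal(tibble::deframe(up), c(fish = 0, maize = 120, wheat = 120))
  expect_error(
    compute_feed_use(items |> dplyr::mutate(production_t = 1),
                     b$feed_attribution,
                     tibble::tibble(animal_group_id = "fish", ratio = 1)),
    class = "deltafood_infeasible_error")
})

test_that("mixed animal ratios reproduce a hand-computed attribution sum", {
  # two animal groups 30 t and 10 t share a 100 t feed item 75/25;
  # meat ratio 0, dairy ratio 1.2 -> feed = 0.75*100*0 + 0.25*100*1.2 = 30
  attribution <- tibble::tibble(item_id = "grain",
                                animal_group_id = c("meat", "dairy"),
                                tons = c(75, 25))
  items <- tibble::tibble(item_id = "grain", production_t = 500)
  out <- compute_feed_use(items, attribution,
                          tibble::tibble(
                            animal_group_id = c("meat", "dairy"),
                            ratio = c(0, 1.2)))
  expect_equal(out$feed_t, 30)
})

test_that("nonfood use follows the selected scaling mode", {
  bn <- tibble::tibble(item_id = "x", nonfood_t = 100)
  expect_equal(compute_nonfood_use(bn, 1000, 2000)$nonfood_t, 200)
  expect_equal(compute_nonfood_use(bn, 1000, 1000)$nonfood_t, 100)
  out <- compute_nonfood_use(
    bn, 1000, 2000, mode = "proportional_to_production",
    nonfood_fraction = tibble::tibble(item_id = "x",
                                      nonfood_fraction = 0.05),
    item_production = tibble::tibble(item_id = "x",
                                     production_t = 1120))
  expect_equal(out$nonfood_t, 0.05 * 1120)
})

test_that("the cascade reproduces the hand-computed single-item example", {
  # production 1000, feed 200, loss 10%, nonfood 50 (equal populations),
  # inedible 10%, in-home 10%:
  # 1000 - 200 - 100 - 50 = 650; x0.9 = 585; x0.9 = 526.5
  w <- one_item_world()
  run <- run_scenario(w)
  crop <- run$mass[run$mass$item_id == "crop", ]
  expect_equal(crop$feed_t, 200)
  expect_equal(crop$supply_chain_loss_t, 100)
  expect_equal(crop$nonfood_t, 50)
  expect_equal(crop$inedible_t, 65)
  expect_equal(crop$in_home_waste_t, 58.5)
  expect_equal(crop$consumed_edible_t, 526.5)

  # zero waste multipliers zero both waste flows for every item
  nw <- run_scenario(w, scenario(supply_chain_waste_multiplier = 0,
                                 in_home_waste_multiplier = 0))
  expect_equal(nw$mass$supply_chain_loss_t, rep(0, nrow(nw$mass)))
  expect_equal(nw$mass$in_home_waste_t, rep(0, nrow(nw$mass)))
})

test_that("per-capita conversion uses grams per person per day", {
  # 7.3 t/yr over 10,000 people is 2.0 g/person/day
  expect_equal(7.3 * 1e6 / 10000 / 365, 2)
  w <- analytic()
  run <- run_scenario(w)
  expect_equal(run$mass$per_capita_g_day,
               run$mass$consumed_edible_t * 1e6 / run$population / 365)
})

test_that("mass is conserved through the cascade on randomized worlds", {
  for (seed in 1:6) {
    w <- make_world(seed = seed, shape = "mini")
    sc <- random_scenario(w, seed = seed + 100)
    run <- tryCatch(run_scenario(w, sc), error = identity)
    if (inherits(run, "error")) {
      expect_s3_class(run, "deltafood_infeasible_error")
      next
    }
    m <- run$mass
    resid <- m$production_t -
      (m$feed_t + m$supply_chain_loss_t + m$nonfood_t + m$inedible_t +
         m$in_home_waste_t + m$consumed_edible_t)
    expect_true(all(abs(resid) <= 1e-6 * pmax(m$production_t, 1)))
    expect_true(all(as.matrix(m[, 3:9]) >= 0))
  }
})

test_that("consumed mass is monotone non-increasing in waste multipliers", {
  w <- make_world(seed = 9, shape = "mini")
  b <- prepare_baseline(w)
  consumed <- function(m_sc, m_ih) {
    run_scenario(w, scenario(supply_chain_waste_multiplier = m_sc,
                             in_home_waste_multiplier = m_ih),
                 baseline = b)$mass$consumed_edible_t
  }
  grid <- c(0, 0.5, 1, 1.5)
  prev <- consumed(grid[1], 1)
  for (m in grid[-1]) {
    cur <- consumed(m, 1)
    expect_true(all(cur <= prev + 1e-9))
    prev <- cur
  }
  prev <- consumed(1, grid[1])
  for (m in grid[-1]) {
    cur <- consumed(1, m)
    expect_true(all(cur <= prev + 1e-9))
    prev <- cur
  }
})

test_that("proportional nonfood mode makes the cascade exactly linear", {
  w <- analytic()
  b <- prepare_baseline(w)
  k <- 1.37
  base <- run_scenario(w, scenario(nonfood_mode =
                                     "proportional_to_production"),
                       baseline = b)
  scaled_sc <- scenario(groups = list(cereals = list(multiplier = k),
                                      fish = list(multiplier = k)),
                        nonfood_mode = "proportional_to_production")
  scaled <- run_scenario(w, scaled_sc, baseline = b)
  for (col in c("production_t", "feed_t", "supply_chain_loss_t",
                "nonfood_t", "inedible_t", "in_home_waste_t",
                "consumed_edible_t")) {
    expect_equal(scaled$mass[[col]], k * base$mass[[col]],
                 tolerance = 1e-12, info = col)
  }
})

test_that("infeasible scenarios error instead of clamping", {
  w <- analytic()
  # feed for cereals stays at baseline while cereal production collapses
  expect_error(
    run_scenario(w, scenario(groups = list(
      cereals = list(multiplier = 0.05)))),
    class = "deltafood_infeasible_error")
  # in-home waste fraction cannot exceed 1
  expect_error(
    run_scenario(w, scenario(in_home_waste_multiplier = 10)),
    class = "deltafood_infeasible_error")
})
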