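test_that("trend extrapolation is exact on constant and affine series", {
  const <- tibble::tibble(item_id = "x", year = 2009:2017,
                          production_t = 50)
  expect_equal(interpolate_production(const, 2018)$production_t, 50)
  expect_equal(interpolate_production(const, 2018,
                                      weights = "uniform")$production_t, 50)

  affine <- tibble::tibble(item_id = "x", year = 1998:2017,
                           production_t = 100 + 2 * (1998:2017 - 1998))
  for (w in list("linear", "uniform", seq(5, 1, length.out = 20))) {
    expect_equal(interpolate_production(affine, 2018,
                                        weights = w)$production_t,
                 140, tolerance = 1e-12)
  }
})

test_that("noisy-series extrapolation matches an independent WLS fit", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      yrs <- 2005:2017
      prod <- 1000 + 30 * (yrs - 2005) + rnorm(length(yrs), sd = 150)
      prod <- pmax(prod, 0)
      hist <- tibble::tibble(item_id = "x", year = yrs,
                             production_t = prod)
      w <- seq(1, 2, length.out = length(yrs))
      fit <- stats::lm(production_t ~ year, data = hist, weights = w)
      expected <- unname(stats::predict(fit,
                                        newdata = data.frame(year = 2018)))
      expect_equal(interpolate_production(hist, 2018)$production_t,
                   max(0, expected), tolerance = 1e-9)
    }
  })
})

test_that("degenerate histories error or clamp as specified", {
  single <- tibble::tibble(item_id = "x", year = 2017L,
                           production_t = 10)
  err <- expect_error(interpolate_production(single, 2018),
                      class = "deltafood_validation_error")
  expect_match(conditionMessage(err), "carry")

  falling <- tibble::tibble(item_id = "x", year = 2014:2017,
                            production_t = c(300, 200, 100, 0))
  expect_warning(out <- interpolate_production(falling, 2018),
                 "clamped")
  expect_equal(out$production_t, 0)

  expect_error(interpolate_production(falling, 2016),
               class = "deltafood_validation_error")
})

test_that("pooled shares and utilization fractions follow the history", {
  bal <- tibble::tibble(
    item_id = rep(c("a", "b", "solo"), each = 2),
    group_id = rep(c("g1", "g1", "g2"), each = 2),
    year = rep(2016:2017, 3),
    production_t = c(40, 35, 15, 10, 60, 40),  # pooled: a 75, b 25
    feed_t = c(8, 7, 0, 0, 12, 8),             # a: 15/75 = 0.2
    supply_chain_loss_t = c(4, 3.5, 0, 0, 6, 4),
    nonfood_t = c(2, 1.75, 0, 0, 0, 0))
  demo <- tibble::tibble(region_id = "w", sex = "F", age_group = "adult",
                         year = 2018L, population = 100)
  b <- derive_shares(bal, demo, 2018)
  shares <- tibble::deframe(b$items[, c("item_id", "item_share")])
  expect_equal(shares[["a"]], 0.75)
  expect_equal(shares[["b"]], 0.25)
  expect_equal(shares[["solo"]], 1)
  a_row <- b$items[b$items$item_id == "a", ]
  expect_equal(a_row$feed_fraction, 0.20)
  expect_equal(a_row$loss_fraction, 0.10)
  expect_equal(a_row$nonfood_fraction, 0.05)

  # invariance to common rescaling of all masses
  bal2 <- bal |>
    dplyr::mutate(dplyr::across(dplyr::ends_with("_t"), \(x) x * 1234.5))
  b2 <- derive_shares(bal2, demo, 2018)
  expect_equal(b2$items$item_share, b$items$item_share, tolerance = 1e-12)
  expect_equal(b2$items$feed_fraction, b$items$feed_fraction,
               tolerance = 1e-12)

  zero <- bal |> dplyr::mutate(
    dplyr::across(dplyr::ends_with("_t"),
                  \(x) ifelse(group_id == "g2", 0, x)))
  expect_error(derive_shares(zero, demo, 2018),
               class = "deltafood_validation_error")
})

test_that("group item shares always sum to one", {
  for (seed in 1:5) {
    w <- make_world(seed = seed, shape = "mini")
    b <- prepare_baseline(w)
    sums <- b$items |>
      dplyr::group_by(group_id) |>
      dplyr::summarise(s = sum(item_share))
    expect_true(all(abs(sums$s - 1) < 1e-9))
    # fraction sums never exceed one
    expect_true(all(b$items$feed_fraction + b$items$loss_fraction +
                      b$items$nonfood_fraction <= 1 + 1e-12))
  }
})

test_that("feed attribution splits tonnage across animal groups", {
  years <- 2016:2017
  bal <- dplyr::bind_rows(
    tibble::tibble(item_id = "grain", group_id = "plants", year = years,
                   production_t = 500, feed_t = 100,
                   supply_chain_loss_t = 0, nonfood_t = 0),
    tibble::tibble(item_id = "beef", group_id = "cattle", year = years,
                   production_t = 30, feed_t = 0,
                   supply_chain_loss_t = 0, nonfood_t = 0),
    tibble::tibble(item_id = "chicken", group_id = "poultry", year = years,
                   production_t = 10, feed_t = 0,
                   supply_chain_loss_t = 0, nonfood_t = 0))
  demo <- tibble::tibble(region_id = "w", sex = "F", age_group = "adult",
                         year = 2018L, population = 100)
  groups <- tibble::tibble(
    group_id = c("plants", "cattle", "poultry"),
    origin = c("plant", "animal", "animal"),
    animal_food_type = c(NA, "meat_fish", "meat_fish"))
  b <- derive_shares(bal, demo, 2018)

  # fallback: proportional to baseline animal production (30 vs 10)
  fb <- derive_feed_attribution(b, groups)
  tons <- tibble::deframe(
    fb$feed_attribution[, c("animal_group_id", "tons")])
  expect_equal(tons[["cattle"]], 75)
  expect_equal(tons[["poultry"]], 25)
  expect_equal(
    fb$feed_attribution$coef_t_per_t[
      fb$feed_attribution$animal_group_id == "cattle"], 75 / 30)

  # single animal group: the whole tonnage, coefficient = feed / animal
  one <- derive_feed_attribution(
    b, groups |> dplyr::filter(group_id != "poultry"))
  expect_equal(one$feed_attribution$tons, 100)
  expect_equal(one$feed_attribution$coef_t_per_t, 100 / 30)

  # explicit 80/20 split, hand-normalized
  ex <- derive_feed_attribution(b, groups, attribution = tibble::tibble(
    item_id = "grain", animal_group_id = c("cattle", "poultry"),
    tons = c(80, 20)))
  tons <- tibble::deframe(
    ex$feed_attribution[, c("animal_group_id", "tons")])
  expect_equal(tons[["cattle"]], 80)
  expect_equal(tons[["poultry"]], 20)
  # weights below the baseline tonnage are scaled up to it
  half <- derive_feed_attribution(b, groups, attribution = tibble::tibble(
    item_id = "grain", animal_group_id = c("cattle", "poultry"),
    tons = c(40, 10)))
  expect_equal(sum(half$feed_attribution$tons), 100)
  expect_equal(half$feed_attribution$tons[
    half$feed_attribution$animal_group_id == "cattle"], 80)

  # rows exceeding the item's baseline feed tonnage are rejected
  expect_error(
    derive_feed_attribution(b, groups, attribution = tibble::tibble(
      item_id = "grain", animal_group_id = "cattle", tons = 150)),
    class = "deltafood_validation_error")
})
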