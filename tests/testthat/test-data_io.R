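test_that("balance reader parses well-formed tables and enforces invariants", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "balance.csv")
  good <- tibble::tibble(
    item_id = c("a", "b", "a"), group_id = "g1",
    year = c(2016L, 2016L, 2017L),
    production_t = c(100, 50, 110), feed_t = c(10, 0, 12),
    supply_chain_loss_t = c(5, 2, 6), nonfood_t = c(1, 0, 1))
  readr::write_csv(good, path)
  tbl <- read_balance_table(path)
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$production_t, good$production_t)

  bad <- good
  bad$feed_t[2] <- 60   # 60 + 2 + 0 > 50
  readr::write_csv(bad, path)
  err <- expect_error(read_balance_table(path),
                      class = "deltafood_validation_error")
  expect_match(conditionMessage(err), "b/2016")

  neg <- good
  neg$production_t[3] <- -1
  neg$feed_t[3] <- 0; neg$supply_chain_loss_t[3] <- 0; neg$nonfood_t[3] <- 0
  readr::write_csv(neg, path)
  err <- expect_error(read_balance_table(path),
                      class = "deltafood_validation_error")
  expect_match(conditionMessage(err), "a/2017")

  readr::write_csv(good |> dplyr::select(-feed_t), path)
  err <- expect_error(read_balance_table(path),
                      class = "deltafood_schema_error")
  expect_match(conditionMessage(err), "feed_t")
})

test_that("a generated world round-trips losslessly through disk", {
  dir <- withr::local_tempdir()
  world <- make_world(seed = 7, shape = "mini", dir = dir)
  back <- read_world(dir)
  for (tbl in names(world)) {
    expect_equal(as.data.frame(back[[tbl]]), as.data.frame(world[[tbl]]),
                 tolerance = 0, info = tbl)
  }
  expect_equal(length(unique(back$balance$item_id)), 8)
})

test_that("scenario documents apply defaults and reject unknown groups", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.yaml")
  writeLines("", empty)
  sc <- read_scenario(empty)
  expect_s3_class(sc, "delta_scenario")
  expect_equal(sc$supply_chain_waste_multiplier, 1)
  expect_equal(sc$in_home_waste_multiplier, 1)
  expect_equal(sc$nonfood_mode, "per_capita_constant")
  expect_equal(sc$diet_mode, "auto")
  expect_length(sc$groups, 0)
  # an empty document resolves to the baseline identity
  w <- analytic()
  b <- prepare_baseline(w)
  resolved <- resolve_scenario(sc, b, w$groups)
  expect_equal(resolved$group_production$production_t,
               b$groups$baseline_production_t)

  half <- file.path(dir, "half.yaml")
  writeLines("waste:\n  in_home: 0.5\n", half)
  sc <- read_scenario(half)
  expect_equal(sc$in_home_waste_multiplier, 0.5)
  expect_equal(sc$supply_chain_waste_multiplier, 1)

  typo <- file.path(dir, "typo.yaml")
  writeLines("groups:\n  suggar:\n    multiplier: 0\n", typo)
  expect_error(read_scenario(typo, known_groups = c("sugar", "cereals")),
               class = "deltafood_validation_error")
  expect_error(resolve_scenario(read_scenario(typo), b, w$groups),
               class = "deltafood_validation_error")

  both <- file.path(dir, "both.yaml")
  writeLines("groups:\n  cereals:\n    tons: 10\n    multiplier: 2\n", both)
  expect_error(read_scenario(both), class = "deltafood_validation_error")
})

test_that("report writing is byte-stable with documented csv columns", {
  run <- run_scenario(analytic())
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_reports(run, d1, format = "csv")
  write_reports(run, d2, format = "csv")
  for (f in c("mass_report.csv", "nutrient_report.csv",
              "waste_report.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  }
  nr <- readr::read_csv(file.path(d1, "nutrient_report.csv"),
                        show_col_types = FALSE)
  expect_identical(names(nr),
                   c("nutrient_id", "unit", "supply", "target",
                     "lower_safe", "upper_safe", "pct_of_target",
                     "gap_pct", "excess_pct", "material"))
  mr <- readr::read_csv(file.path(d1, "mass_report.csv"),
                        show_col_types = FALSE)
  expect_identical(names(mr),
                   c("item_id", "group_id", "production_t", "feed_t",
                     "supply_chain_loss_t", "nonfood_t", "inedible_t",
                     "in_home_waste_t", "consumed_edible_t",
                     "per_capita_g_day"))
  wr <- readr::read_csv(file.path(d1, "waste_report.csv"),
                        show_col_types = FALSE)
  expect_identical(names(wr),
                   c("nutrient_id", "wasted_amount", "pct_of_target",
                     "plant_share_pct", "animal_share_pct"))

  write_reports(run, d1, format = "json")
  doc <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_setequal(names(doc),
                  c("mass_report", "nutrient_report", "waste_report"))
})

test_that("cross-validation catches unit disagreements at load time", {
  w <- analytic()
  w$drv$unit[w$drv$nutrient_id == "calcium"] <- "g"
  expect_error(validate_world(w), class = "deltafood_validation_error")
})

test_that("the CLI drives fixtures, run and compare end to end", {
  root <- withr::local_tempdir()
  data_dir <- file.path(root, "data")
  expect_invisible(delta_cli(c("fixtures", "--out", data_dir,
                               "--seed", "3", "--shape", "mini")))
  out_a <- file.path(root, "a"); out_b <- file.path(root, "b")
  sc_path <- file.path(root, "scale.yaml")
  writeLines("name: scaled\ngroups:\n  plant_g1:\n    multiplier: 1.2\n",
             sc_path)
  suppressMessages({
    delta_cli(c("run", "--data", data_dir, "--out", out_a,
                "--log-level", "quiet"))
    delta_cli(c("run", "--data", data_dir, "--scenario", sc_path,
                "--out", out_b, "--log-level", "quiet"))
  })
  expect_true(file.exists(file.path(out_a, "nutrient_report.csv")))
  cmp_path <- file.path(root, "delta.csv")
  delta_cli(c("compare", "--run-a", out_a, "--run-b", out_b,
              "--out", cmp_path))
  cmp <- readr::read_csv(cmp_path, show_col_types = FALSE)
  expect_identical(names(cmp),
                   c("nutrient_id", "supply_a", "supply_b",
                     "delta_supply", "delta_gap_pct"))
  expect_true(all(cmp$delta_supply >= 0))
})
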