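test_that("the reference country always scores 100", {
  panel <- toy_panel()
  expect_equal(laspeyres_index(panel, toy_weights(), "CY"), 100)
  fx <- worked_example_fixture()
  expect_equal(laspeyres_index(fx$panel, equal_weights_for(fx$panel), "CY"), 100)
})

test_that("the index is the share-weighted mean of price relatives", {
  # two products, relatives 0.5 and 1.5, equal shares: they cancel to parity
  panel <- price_panel(
    tibble::tibble(country = c("CY", "CY", "IT", "IT"),
                   product_id = c("a", "b", "a", "b"),
                   pack_price = c(10, 20, 5, 30)),
    reference_country = "CY"
  )
  expect_equal(laspeyres_index(panel, toy_weights(c(a = 100, b = 100)), "IT"), 100)

  # unequal weights tilt the index toward the heavier product's relative
  expect_equal(laspeyres_index(panel, toy_weights(c(a = 300, b = 100)), "IT"),
               100 * (0.75 * 0.5 + 0.25 * 1.5))
})

test_that("worked-example fixture with equal weights matches the mean of relatives", {
  fx <- worked_example_fixture()
  costs <- fx$costs
  cy <- costs[costs$country == "CY", ]
  # independent oracle: plain mean of the eight printed price relatives
  oracle <- function(cc) {
    tgt <- costs[costs$country == cc, ]
    r <- tgt$monthly_cost[match(cy$product_id, tgt$product_id)] / cy$monthly_cost
    100 * mean(r)
  }
  w <- equal_weights_for(fx$panel)
  for (cc in c("IT", "GR", "ES", "PT")) {
    expect_equal(laspeyres_index(fx$panel, w, cc), oracle(cc), tolerance = 1e-12)
  }
  # frozen spot value, recomputed by hand from the printed Italy/Cyprus costs
  expect_equal(laspeyres_index(fx$panel, w, "IT"), 92.09558, tolerance = 1e-6)
})

test_that("both Laspeyres formulations agree on random small baskets", {
  withr::local_seed(301)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    panel <- random_panel(n, c("CY", "XX"), sigma = 0.3)
    weights <- random_weights(n)
    expect_equal(laspeyres_index(panel, weights, "XX"),
                 oracle_quantity_index(panel, weights, "XX"),
                 tolerance = 1e-9)
  }
})

test_that("weight-scale invariance and price homogeneity hold", {
  withr::local_seed(302)
  for (i in 1:10) {
    n <- 12
    panel <- random_panel(n, c("CY", "XX"), sigma = 0.4)
    weights <- random_weights(n)
    base <- laspeyres_index(panel, weights, "XX")

    scaled_w <- weight_table(tibble::tibble(product_id = weights$product_id,
                                            sales_value = weights$sales_value * 137.5))
    expect_equal(laspeyres_index(panel, scaled_w, "XX"), base)

    k <- runif(1, 0.2, 5)
    tbl <- tibble::as_tibble(panel)
    tbl$pack_price[tbl$country == "XX"] <- k * tbl$pack_price[tbl$country == "XX"]
    expect_equal(laspeyres_index(price_panel(tbl, "CY"), weights, "XX"), k * base)

    # the index is a weighted mean, so it sits between the extreme relatives
    rel <- tbl$pack_price[tbl$country == "XX"] / tbl$pack_price[tbl$country == "CY"]
    idx <- laspeyres_index(price_panel(tbl, "CY"), weights, "XX")
    expect_gte(idx / 100, min(rel) - 1e-12)
    expect_lte(idx / 100, max(rel) + 1e-12)
  }
})

test_that("PPP adjustment scales by the reference-to-target GDP ratio", {
  econ <- toy_economics()
  # equal GDP leaves the index untouched; the reference stays at 100
  eq <- economics_table(tibble::tibble(country = c("CY", "IT"),
                                       gdp_ppp_pc = c(30000, 30000),
                                       min_wage = c(870, 992.4)))
  expect_equal(ppp_adjust(92.1, eq, "IT", "CY"), 92.1)
  expect_equal(ppp_adjust(100, econ, "CY", "CY"), 100)

  # a richer target country gets a lower (more affordable) adjusted index
  expect_lt(ppp_adjust(95.52, econ, "IT", "CY"), 95.52)
  # and the adjustment is exactly raw * gdp_ref / gdp_target
  expect_equal(ppp_adjust(95.52, econ, "IT", "CY"), 95.52 * 30000 / 35000)
  # self-consistency at the implied GDP ratio: raw 95.52 falling to 85.54
  # corresponds to a target/reference GDP ratio of 95.52 / 85.54
  implied <- economics_table(tibble::tibble(
    country = c("CY", "IT"),
    gdp_ppp_pc = c(1, 95.52 / 85.54),
    min_wage = c(870, 992.4)
  ))
  expect_equal(ppp_adjust(95.52, implied, "IT", "CY"), 85.54, tolerance = 1e-10)

  expect_error(ppp_adjust(100, econ, "ZZ", "CY"), "GDP")
})

test_that("the index report covers every country with coverage bookkeeping", {
  panel <- toy_panel()
  weights <- toy_weights()
  rep <- build_index_report(panel, weights, toy_economics())
  expect_identical(rep$country[[1]], "CY")
  expect_identical(rep$raw_index[[1]], 100)
  expect_identical(rep$adjusted_index[[1]], 100)
  expect_true(all(rep$n_products == 3))
  expect_true(all(rep$coverage == 1))
  expect_true(all(rep$raw_index > 0))

  # reference-only panel degenerates to the single parity row
  only_cy <- price_panel(tibble::as_tibble(panel)[panel$country == "CY", ], "CY")
  solo <- build_index_report(only_cy, weights, NULL)
  expect_equal(nrow(solo), 1L)
  expect_identical(solo$raw_index, 100)
  expect_true(is.na(solo$adjusted_index))

  # dropping one product for one country shrinks its basket and coverage
  tbl <- tibble::as_tibble(panel)
  rep2 <- build_index_report(
    price_panel(tbl[!(tbl$country == "IT" & tbl$product_id == "b"), ], "CY"),
    weights, NULL)
  it <- rep2[rep2$country == "IT", ]
  expect_identical(it$n_products, 2L)
  expect_equal(it$coverage, 150 / 250)

  # exact multiplier panels recover 100 * k
  withr::local_seed(303)
  k_panel <- random_panel(20, c("CY", "XX"), mult = c(CY = 1, XX = 1.37))
  rep3 <- build_index_report(k_panel, random_weights(20), NULL)
  expect_equal(rep3$raw_index[rep3$country == "XX"], 137)
})

test_that("index CSV output is rounded to two decimals", {
  dir <- withr::local_tempdir()
  fx <- worked_example_fixture()
  rep <- build_index_report(fx$panel, equal_weights_for(fx$panel), NULL)
  path <- file.path(dir, "index.csv")
  write_index_report(rep, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$raw_index[back$country == "IT"], 92.10)
  expect_equal(back$raw_index, round(rep$raw_index, 2))
})
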