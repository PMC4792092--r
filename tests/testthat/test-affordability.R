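test_that("allowance and residual threshold partition the wage", {
  expect_equal(catastrophic_allowance(992.4, 0.05), 49.62)
  expect_equal(catastrophic_allowance(1000, 0.05), 50)
  expect_equal(residual_threshold(992.4, 0.05), 942.78)

  withr::local_seed(401)
  for (i in 1:25) {
    wage <- runif(1, 300, 3000)
    f <- runif(1, 0.01, 0.6)
    expect_equal(catastrophic_allowance(wage, f) + residual_threshold(wage, f),
                 wage)
  }

  expect_error(catastrophic_allowance(1000, 0), "between 0 and 1")
  expect_error(catastrophic_allowance(1000, 1), "between 0 and 1")
  expect_error(catastrophic_allowance(-5, 0.05), "positive")
})

test_that("threshold display truncates integral wages, rounds decimal ones", {
  wages <- c(992.4, 878, 565, 870, 748)
  expect_equal(format_residual_threshold(wages, 0.05),
               c(942.8, 834, 536, 826, 710))
  # the underlying exact values differ from the display
  expect_equal(residual_threshold(wages, 0.05),
               c(942.78, 834.1, 536.75, 826.5, 710.6))
})

test_that("catastrophic classification uses a strict threshold", {
  # the yearly osteoporosis infusion swamps a 5% minimum-wage allowance
  expect_true(is_catastrophic(590.98, wage = 870, fraction = 0.05))
  # a cheap proton-pump inhibitor does not
  expect_false(is_catastrophic(7.08, wage = 992.4, fraction = 0.05))
  # exactly at the allowance is not "exceeding" it
  expect_false(is_catastrophic(50, wage = 1000, fraction = 0.05))
  expect_true(is_catastrophic(50 + 1e-9, wage = 1000, fraction = 0.05))
  expect_error(is_catastrophic(-1, 1000), "non-negative")
})

test_that("population share matches the lognormal closed form", {
  d <- income_lognormal(mu = log(1000), sigma = 0.5)
  # cost 50 at 5% needs income 1000 = the median, so exactly half the mass
  expect_equal(population_share_catastrophic(50, 0.05, d), 0.5)
  expect_equal(population_share_catastrophic(0, 0.05, d), 0)
  # general closed form at arbitrary points
  for (cost in c(5, 20, 80, 300)) {
    expect_equal(population_share_catastrophic(cost, 0.05, d),
                 pnorm((log(cost / 0.05) - log(1000)) / 0.5))
  }
})

test_that("point-mass incomes reproduce the all-or-nothing classification", {
  w <- 870
  pm <- income_empirical(tibble::tibble(probability = c(0.25, 0.5, 0.75),
                                        income = c(w, w, w)))
  expect_equal(population_share_catastrophic(0.05 * w, 0.05, pm), 0)
  expect_equal(population_share_catastrophic(0.05 * w + 0.01, 0.05, pm), 1)
  expect_equal(population_share_catastrophic(0.01, 0.05, pm), 0)

  # consistency with the boolean classifier for a range of costs
  withr::local_seed(402)
  for (cost in runif(20, 0, 100)) {
    expect_identical(is_catastrophic(cost, w, 0.05),
                     population_share_catastrophic(cost, 0.05, pm) > 0)
  }
})

test_that("population share is monotone in cost and fraction, bounded in [0,1]", {
  withr::local_seed(403)
  d <- income_lognormal(log(800), 0.7)
  emp <- simulate_income_distribution(800, 0.7, seed = 9, n_quantiles = 500)$empirical
  for (dist in list(d, emp)) {
    costs <- sort(runif(30, 0, 400))
    shares <- population_share_catastrophic(costs, 0.05, dist)
    expect_true(all(diff(shares) >= 0))
    expect_true(all(shares >= 0 & shares <= 1))
    s_low <- population_share_catastrophic(60, 0.04, dist)
    s_high <- population_share_catastrophic(60, 0.10, dist)
    expect_gte(s_low, s_high)
  }
})

test_that("empirical shares agree with the closed form within Monte Carlo error", {
  sim <- simulate_income_distribution(900, 0.6, seed = 5, n_quantiles = 1e4)
  for (cost in c(20, 45, 90, 200)) {
    exact <- population_share_catastrophic(cost, 0.05, sim$parametric)
    emp <- population_share_catastrophic(cost, 0.05, sim$empirical)
    se <- sqrt(exact * (1 - exact) / 1e4)
    expect_lt(abs(emp - exact), 3 * se + 1e-12)
  }
})

test_that("affected counts round half-up from shares", {
  expect_equal(affected_count(0, 1e6), 0)
  expect_equal(affected_count(1, 150000), 150000)
  expect_equal(affected_count(0.25, 600000), 150000)
  expect_equal(affected_count(0.5, 3), 2)  # 1.5 rounds up
  expect_error(affected_count(1.2, 10), "\\[0, 1\\]")
  expect_error(affected_count(0.5, -1), "non-negative")
})

test_that("the affordability report classifies a panel against its wages", {
  fx <- worked_example_fixture()
  rep <- build_affordability_report(fx$costs, fx$economics)
  expect_equal(nrow(rep), 40L)
  expect_equal(rep$allowance + rep$residual_threshold,
               fx$economics$min_wage[match(rep$country, fx$economics$country)])

  # brute-force reclassification of every cell
  wages <- fx$economics$min_wage[match(rep$country, fx$economics$country)]
  expect_identical(rep$catastrophic, rep$monthly_cost > 0.05 * wages)
  expect_true(all(is.na(rep$pop_share)))

  # with income distributions the share and count columns fill in
  econ2 <- fx$economics
  econ2$population <- rep(1e6, 5)
  income <- lapply(stats::setNames(nm = econ2$country), function(cc) {
    income_lognormal(log(1200), 0.6)
  })
  rep2 <- build_affordability_report(fx$costs, economics_table(econ2),
                                     income = income)
  expect_true(all(rep2$pop_share >= 0 & rep2$pop_share <= 1))
  expect_equal(rep2$affected_count, affected_count(rep2$pop_share, 1e6))

  # a country without a distribution warns and stays NA
  expect_warning(
    rep3 <- build_affordability_report(fx$costs, economics_table(econ2),
                                       income = income[-1]),
    "no income distribution"
  )
  expect_true(any(is.na(rep3$pop_share)))
})

test_that("income distribution CSVs load in both schemas", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "income_parametric.csv")
  writeLines(c("country,kind,mu,sigma",
               sprintf("CY,lognormal,%.10f,0.5", log(1000)),
               sprintf("IT,lognormal,%.10f,0.6", log(1100))), p1)
  dists <- load_income_distributions(p1)
  expect_named(dists, c("CY", "IT"))
  expect_equal(income_cdf(dists$CY, 1000), 0.5)

  p2 <- file.path(dir, "income_quantiles.csv")
  readr::write_csv(tibble::tibble(country = "CY",
                                  probability = c(0.25, 0.5, 0.75),
                                  income = c(700, 1000, 1500)), p2)
  emp <- load_income_distributions(p2)
  expect_equal(income_cdf(emp$CY, 1000), 0.5)
  expect_equal(income_cdf(emp$CY, 850), 0.25 + 0.25 * 150 / 300)

  p3 <- file.path(dir, "bad.csv")
  writeLines("country,foo\nCY,1", p3)
  expect_error(load_income_distributions(p3), "expected columns")
})
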