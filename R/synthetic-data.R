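#' Seeded random streams
#'
#' Every generator in the package derives its own stream seed from the user
#' seed and a stream label, so adding a generator (or calling them in a
#' different order) never perturbs the draws of another. The derived seed is
#' a 31-bit hash of (seed, label).
#'
#' @noRd
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1
  s <- abs(as.numeric(seed)) %% m
  for (code in utf8ToInt(stream)) {
    s <- (s * 31 + code) %% m
  }
  as.integer(s)
}

#' Simulate a multi-country price panel
#'
#' Generates a panel with the multiplicative structure cross-country price
#' comparisons assume: reference prices drawn log-uniformly over
#' `[1, 600]` EUR (spanning the range from cheap chronic tablets to annual
#' infusions), and each non-reference price equal to the reference price
#' times a country-level multiplier times lognormal product-level noise,
#'
#' \deqn{p_{c,i} = m_c \, p_{\mathrm{ref},i} \, e^{\varepsilon},\quad
#'       \varepsilon \sim N(0, \sigma^2).}
#'
#' The reference country's own prices carry no noise (they are the base
#' prices). With `noise_sigma = 0` every price relative for country `c` is
#' exactly `m_c`, so the index recovers `100 * m_c` exactly; with noise, the
#' expected relative is `m_c * exp(noise_sigma^2 / 2)` (the lognormal mean
#' bias), which a consistency check must account for.
#'
#' @param n_products Number of products.
#' @param countries Character vector of country codes, including the
#'   reference.
#' @param multipliers Named numeric vector of positive country multipliers;
#'   the reference country's multiplier must be 1.
#' @param noise_sigma Standard deviation of log price noise; non-negative.
#' @param seed Integer seed; the same seed reproduces the same panel.
#' @param reference_country Reference country code (default `"CY"`).
#' @return A [price_panel()].
#' @export
#' @examples
#' simulate_price_panel(5, c("CY", "IT"), c(CY = 1, IT = 0.9),
#'                      noise_sigma = 0.1, seed = 1)
simulate_price_panel <- function(n_products, countries, multipliers,
                                 noise_sigma = 0.1, seed = 1,
                                 reference_country = "CY") {
  stopifnot(n_products >= 1, length(countries) >= 1)
  if (!reference_country %in% countries) {
    rlang::abort("`countries` must include the reference country.")
  }
  if (!all(countries %in% names(multipliers))) {
    rlang::abort("every country needs a multiplier.")
  }
  m <- as.numeric(multipliers[countries])
  if (any(!is.finite(m) | m <= 0)) {
    rlang::abort("multipliers must be positive.")
  }
  if (abs(multipliers[[reference_country]] - 1) > 1e-12) {
    rlang::abort("the reference country's multiplier must be 1.")
  }
  if (noise_sigma < 0) rlang::abort("`noise_sigma` must be non-negative.")
  ids <- sprintf("p%04d", seq_len(n_products))
  withr::with_seed(derive_seed(seed, "price_panel"), {
    p_ref <- exp(stats::runif(n_products, log(1), log(600)))
    rows <- lapply(countries, function(cc) {
      if (cc == reference_country) {
        price <- p_ref
      } else {
        eps <- if (noise_sigma == 0) 0 else stats::rnorm(n_products, 0, noise_sigma)
        price <- multipliers[[cc]] * p_ref * exp(eps)
      }
      tibble(country = cc, product_id = ids, pack_price = price)
    })
    price_panel(dplyr::bind_rows(rows), reference_country = reference_country)
  })
}

#' Simulate heavy-tailed sales weights
#'
#' Pharmaceutical markets are strongly concentrated: a top-sellers basket
#' holds much of the total sales value. Pareto-distributed sales values with
#' a small tail index reproduce that concentration (at `alpha = 1.2`, the
#' top decile of products holds a majority of the total weight). The sentinel
#' `alpha = Inf` yields uniform weights.
#'
#' @param n_products Number of products.
#' @param alpha Pareto tail index; positive, or `Inf` for uniform weights.
#' @param seed Integer seed.
#' @return A [weight_table()] with product ids matching
#'   [simulate_price_panel()].
#' @export
simulate_weights <- function(n_products, alpha = 1.2, seed = 1) {
  stopifnot(n_products >= 1)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    rlang::abort("`alpha` must be a positive number (Inf for uniform weights).")
  }
  ids <- sprintf("p%04d", seq_len(n_products))
  if (is.infinite(alpha)) {
    return(weight_table(tibble(product_id = ids, sales_value = 1)))
  }
  withr::with_seed(derive_seed(seed, "weights"), {
    u <- stats::runif(n_products)
    weight_table(tibble(product_id = ids, sales_value = (1 - u)^(-1 / alpha)))
  })
}

#' Simulate a household income distribution
#'
#' A lognormal monthly income distribution parameterized by its median
#' (`mu = log(median)`), returned both as the parametric object and as an
#' empirical quantile table built from seeded draws — the two forms the
#' population-share estimator accepts.
#'
#' @param median Median monthly income, EUR; positive.
#' @param sigma Log-scale standard deviation; positive.
#' @param seed Integer seed for the empirical draws.
#' @param n_quantiles Number of draws behind the empirical table.
#' @return A list with elements `parametric` ([income_lognormal()]) and
#'   `empirical` ([income_empirical()]).
#' @export
simulate_income_distribution <- function(median, sigma, seed = 1,
                                         n_quantiles = 1e4) {
  if (!is.numeric(median) || length(median) != 1L || median <= 0) {
    rlang::abort("`median` must be a single positive number.")
  }
  parametric <- income_lognormal(mu = log(median), sigma = sigma)
  withr::with_seed(derive_seed(seed, "income"), {
    draws <- sort(stats::rlnorm(n_quantiles, log(median), sigma))
  })
  probs <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  list(parametric = parametric,
       empirical = income_empirical(tibble(probability = probs,
                                           income = draws)))
}

#' Worked-example fixture: eight treatments in five euro-area countries
#'
#' Monthly retail treatment costs (EUR, private sector, 2011 price lists)
#' for one branded product from each of eight common chronic conditions —
#' dyspepsia, type II diabetes, osteoarthritis, hypertension,
#' hypercholesterolemia, depression, osteoporosis and asthma — in Italy,
#' Greece, Portugal, Cyprus and Spain, together with each country's lowest
#' official monthly wage. The proton-pump inhibitor, the COX-2 inhibitor and
#' the SSRI are costed as two 28-day packs per month; the annual osteoporosis
#' infusion is spread over twelve months.
#'
#' These figures are monthly costs, not pack prices: the panel's
#' `pack_price` column holds the monthly cost directly (costing is already
#' done), and the `costs` element carries the same values in the schema
#' [build_affordability_report()] expects.
#'
#' @return A list with elements `panel` (a [price_panel()] of monthly costs,
#'   reference `CY`), `costs` (the same as a plain tibble
#'   `country, product_id, monthly_cost`), `economics` (an
#'   [economics_table()]; the GDP column is a unit placeholder since the
#'   example concerns the catastrophic-expenditure analysis), and `products`
#'   (condition labels and regimens).
#' @export
#' @examples
#' fx <- worked_example_fixture()
#' subset(fx$costs, country == "CY" & product_id == "zoledronic_acid")
worked_example_fixture <- function() {
  path <- system.file("extdata", "worked_example_monthly_costs.csv",
                      package = "medafford", mustWork = TRUE)
  costs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  epath <- system.file("extdata", "worked_example_economics.csv",
                       package = "medafford", mustWork = TRUE)
  econ <- economics_table(readr::read_csv(epath, show_col_types = FALSE,
                                          progress = FALSE))
  ppath <- system.file("extdata", "worked_example_products.csv",
                       package = "medafford", mustWork = TRUE)
  products <- readr::read_csv(ppath, show_col_types = FALSE, progress = FALSE)
  panel <- price_panel(tibble(country = costs$country,
                              product_id = costs$product_id,
                              pack_price = costs$monthly_cost),
                       reference_country = "CY")
  list(panel = panel,
       costs = costs[c("country", "product_id", "monthly_cost")],
       economics = econ,
       products = products)
}
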