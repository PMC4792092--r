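# Small in-code fixtures shared across test files.

toy_panel <- function() {
  price_panel(
    tibble::tibble(
      country = rep(c("CY", "IT", "GR"), each = 3),
      product_id = rep(c("a", "b", "c"), 3),
      pack_price = c(10, 20, 5, 5, 30, 4, 8, 14, 6)
    ),
    reference_country = "CY"
  )
}

toy_weights <- function(values = c(a = 100, b = 100, c = 50)) {
  weight_table(values)
}

toy_economics <- function() {
  economics_table(tibble::tibble(
    country = c("CY", "IT", "GR"),
    gdp_ppp_pc = c(30000, 35000, 26000),
    min_wage = c(870, 992.4, 878),
    population = c(850000, 6e7, 1.1e7)
  ))
}

# random valid panel + weights over n products and the given countries;
# country multipliers applied exactly (no noise) unless sigma > 0
random_panel <- function(n, countries = c("CY", "XX"), mult = NULL,
                         sigma = 0, ref = "CY") {
  ids <- sprintf("q%03d", seq_len(n))
  p_ref <- exp(stats::runif(n, log(1), log(600)))
  if (is.null(mult)) {
    mult <- stats::setNames(c(1, stats::runif(length(countries) - 1, 0.5, 1.5)),
                            countries)
  }
  rows <- lapply(countries, function(cc) {
    noise <- if (cc == ref || sigma == 0) 1 else exp(stats::rnorm(n, 0, sigma))
    tibble::tibble(country = cc, product_id = ids,
                   pack_price = mult[[cc]] * p_ref * noise)
  })
  price_panel(dplyr::bind_rows(rows), reference_country = ref)
}

random_weights <- function(n) {
  weight_table(tibble::tibble(product_id = sprintf("q%03d", seq_len(n)),
                              sales_value = stats::runif(n, 1, 1000)))
}

# independent oracle: Laspeyres as ratio of basket costs at fixed reference
# quantities q_i = w_i / p_ref,i (never calls laspeyres_index)
oracle_quantity_index <- function(panel, weights, country) {
  ref <- attr(panel, "reference_country")
  tbl <- as.data.frame(panel)
  ids <- sort(intersect(tbl$product_id[tbl$country == ref],
                        tbl$product_id[tbl$country == country]))
  ids <- intersect(ids, weights$product_id)
  pr <- function(cc) {
    sub <- tbl[tbl$country == cc, ]
    sub$pack_price[match(ids, sub$product_id)]
  }
  w <- weights$sales_value[match(ids, weights$product_id)]
  q <- w / pr(ref)
  100 * sum(pr(country) * q) / sum(pr(ref) * q)
}

equal_weights_for <- function(panel) {
  weight_table(stats::setNames(rep(1, length(unique(panel$product_id))),
                               sort(unique(panel$product_id))))
}
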