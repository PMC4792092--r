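#' Bilateral Laspeyres price index
#'
#' Compares a target country's prices with the reference country's over the
#' bilateral basket, weighting each product by its reference-market sales
#' value (its budget impact). Writing `s_i = w_i / sum_j w_j` for the
#' reference expenditure shares and `r_i = p_target,i / p_ref,i` for the
#' price relatives, the index is
#'
#' \deqn{100 \times \sum_i s_i \, r_i.}
#'
#' This is the classical Laspeyres form: with implicit base-period quantities
#' `q_i = w_i / p_ref,i`, it equals
#' `100 * sum(p_target * q) / sum(p_ref * q)`. Value 100 means parity with
#' the reference country; the reference country itself always scores 100.
#'
#' @param panel A [price_panel()].
#' @param weights A [weight_table()] of reference-country sales values.
#' @param country Target country code.
#' @param basket Optional character vector restricting the basket; defaults
#'   to [intersect_basket()] of the inputs.
#' @return A single number (dimensionless, reference = 100).
#' @export
#' @examples
#' pan <- price_panel(
#'   tibble::tibble(
#'     country = c("CY", "CY", "IT", "IT"),
#'     product_id = c("a", "b", "a", "b"),
#'     pack_price = c(10, 20, 5, 30)
#'   ),
#'   reference_country = "CY"
#' )
#' w <- weight_table(c(a = 100, b = 100))
#' laspeyres_index(pan, w, "IT")  # relatives 0.5 and 1.5, equal shares -> 100
laspeyres_index <- function(panel, weights, country, basket = NULL) {
  ref <- attr(panel, "reference_country")
  if (is.null(basket)) basket <- intersect_basket(panel, weights, country)
  if (!length(basket)) rlang::abort("empty basket; index undefined.")
  p_ref <- panel_prices(panel, ref, basket)
  p_tgt <- panel_prices(panel, country, basket)
  w <- weights$sales_value[match(basket, weights$product_id)]
  if (anyNA(w)) rlang::abort("basket product missing from weight table.")
  total_w <- sum(w)
  if (total_w <= 0) rlang::abort("total basket weight is zero; index undefined.")
  s <- w / total_w
  100 * sum(s * (p_tgt / p_ref))
}

panel_prices <- function(panel, country, basket) {
  rows <- panel$country == country
  p <- panel$pack_price[rows][match(basket, panel$product_id[rows])]
  if (anyNA(p)) {
    rlang::abort(paste0("missing price(s) in ", country, " for basket product(s)."))
  }
  p
}

#' Affordability adjustment by GDP PPP per capita
#'
#' Scales a raw price index by the ratio of GDP at purchasing power parity
#' per capita between the reference and the target country:
#' `raw_index * gdp_ref / gdp_target`. A target country richer than the
#' reference gets a lower adjusted index (the same prices weigh less on its
#' income); a poorer one gets a higher adjusted index.
#'
#' @param raw_index Raw index value (reference = 100).
#' @param econ An [economics_table()].
#' @param country Target country code.
#' @param reference Reference country code.
#' @return The adjusted index (dimensionless, reference = 100).
#' @export
ppp_adjust <- function(raw_index, econ, country, reference) {
  gdp <- function(cc) {
    g <- econ$gdp_ppp_pc[match(cc, econ$country)]
    if (is.na(g)) {
      rlang::abort(paste0("no GDP PPP per capita for country '", cc, "'."))
    }
    g
  }
  raw_index * gdp(reference) / gdp(country)
}

#' Full index report for a panel
#'
#' Computes the raw and (when economics are supplied) PPP-adjusted index for
#' every country in the panel, alongside the basket size and the weight
#' coverage — the share of total reference sales value represented by the
#' products actually compared. Coverage below 1 flags pairwise basket
#' reduction; with a complete panel every country uses the same basket.
#'
#' @param panel A [price_panel()].
#' @param weights A [weight_table()].
#' @param econ Optional [economics_table()]; when `NULL` the adjusted index
#'   column is `NA`.
#' @param config An [analysis_config()] (supplies the reference country if it
#'   differs from the panel's attribute).
#' @return A tibble of class `maff_index` with columns `country, raw_index,
#'   adjusted_index, n_products, coverage`, one row per country, reference
#'   row exactly (100, 100).
#' @export
build_index_report <- function(panel, weights, econ = NULL,
                               config = analysis_config()) {
  ref <- attr(panel, "reference_country")
  countries <- sort(unique(panel$country))
  countries <- c(ref, setdiff(countries, ref))  # reference row first
  total_w <- sum(weights$sales_value)
  rows <- lapply(countries, function(cc) {
    basket <- intersect_basket(panel, weights, cc)
    raw <- laspeyres_index(panel, weights, cc, basket = basket)
    adj <- if (is.null(econ)) NA_real_ else ppp_adjust(raw, econ, cc, ref)
    cov <- sum(weights$sales_value[weights$product_id %in% basket]) / total_w
    tibble(country = cc, raw_index = raw, adjusted_index = adj,
           n_products = length(basket), coverage = cov)
  })
  out <- dplyr::bind_rows(rows)
  # reference comparisons are exact by construction; pin against roundoff
  out$raw_index[out$country == ref] <- 100
  if (!is.null(econ)) out$adjusted_index[out$country == ref] <- 100
  structure(out, reference_country = ref,
            class = c("maff_index", class(out)))
}

#' @export
print.maff_index <- function(x, digits = 2, ...) {
  cat("Bilateral medicine price index (reference ",
      attr(x, "reference_country"), " = 100)\n\n", sep = "")
  fmt <- as.data.frame(x)
  fmt$raw_index <- sprintf(paste0("%.", digits, "f"), fmt$raw_index)
  fmt$adjusted_index <- ifelse(is.na(x$adjusted_index), "",
                               sprintf(paste0("%.", digits, "f"),
                                       x$adjusted_index))
  fmt$coverage <- sprintf("%.3f", x$coverage)
  print(fmt, row.names = FALSE)
  invisible(x)
}

#' Write an index report to CSV
#'
#' Index values are written rounded to two decimals (the conventional
#' reporting precision for price indices); full precision is kept in the
#' in-memory object.
#'
#' @param x A `maff_index` report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_report <- function(x, path) {
  out <- as_tibble(x)
  out$raw_index <- round(out$raw_index, 2)
  out$adjusted_index <- round(out$adjusted_index, 2)
  readr::write_csv(out, path)
  invisible(path)
}

#' Bar chart of raw vs adjusted indices
#'
#' @param x A `maff_index` report with adjusted values.
#' @return A ggplot object.
#' @export
plot_index <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rlang::abort("plot_index() needs the ggplot2 package.")
  }
  long <- tidyr::pivot_longer(as_tibble(x), c("raw_index", "adjusted_index"),
                              names_to = "series", values_to = "index")
  long$series <- ifelse(long$series == "raw_index", "Price index",
                        "Adjusted by GDP PPP per capita")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$country, y = .data$index,
                               fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Index (reference = 100)", fill = NULL) +
    ggplot2::theme_minimal()
}
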