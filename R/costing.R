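#' Price per defined daily dose
#'
#' Normalizes a retail pack price to the cost of one defined daily dose
#' (DDD): the pack price divided by the number of DDDs the pack contains,
#' `pack_size * strength_mg / ddd_mg`. This is the standard way to compare
#' presentations that differ in pack size or unit strength.
#'
#' @param pack_price Retail price of the pack, EUR. Positive.
#' @param pack_size Units per pack. Positive.
#' @param strength_mg Active substance per unit, mg. Positive.
#' @param ddd_mg Defined daily dose, mg. Positive.
#' @return EUR per DDD. Vectorized over all arguments.
#' @export
#' @examples
#' price_per_ddd(15.39, pack_size = 28, strength_mg = 10, ddd_mg = 10)
price_per_ddd <- function(pack_price, pack_size, strength_mg, ddd_mg) {
  args <- vctrs_recycle(pack_price = pack_price, pack_size = pack_size,
                        strength_mg = strength_mg, ddd_mg = ddd_mg)
  with(args, {
    if (any(!is.finite(pack_price) | pack_price <= 0)) {
      rlang::abort("`pack_price` must be positive.")
    }
    if (any(!is.finite(pack_size) | pack_size <= 0) ||
        any(!is.finite(strength_mg) | strength_mg <= 0) ||
        any(!is.finite(ddd_mg) | ddd_mg <= 0)) {
      rlang::abort("`pack_size`, `strength_mg` and `ddd_mg` must be positive.")
    }
    pack_price / (pack_size * strength_mg / ddd_mg)
  })
}

# recycle scalar/vector args to a common length, erroring on mismatch
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- !(lengths(args) %in% c(1L, n))
  if (any(bad)) {
    rlang::abort(paste0("incompatible lengths for: ",
                        paste(names(args)[bad], collapse = ", ")))
  }
  lapply(args, rep_len, n)
}

#' Standardized monthly treatment cost
#'
#' Converts a pack price (and its per-DDD price) to the cost of one month of
#' treatment under the product's dosing regimen:
#'
#' * `standard_30d`: 30 daily doses, i.e. `30 * ddd_price`.
#' * `pack_cycle_28d`: the pack lasts 28 days, so a calendar month requires
#'   starting a second pack; the monthly cost is two pack prices.
#' * `yearly`: one pack covers a year; the monthly cost is `pack_price / 12`.
#'
#' The treatment month is fixed at 30 days for standard chronic regimens.
#'
#' @param pack_price Retail pack price, EUR. Positive.
#' @param regimen One of `"standard_30d"`, `"pack_cycle_28d"`, `"yearly"`.
#' @param ddd_price EUR per DDD (required for `standard_30d`); see
#'   [price_per_ddd()].
#' @return EUR per treatment month. Vectorized.
#' @export
#' @examples
#' monthly_cost(3.54, "pack_cycle_28d")      # two packs per month
#' monthly_cost(120, "yearly")               # annual pack spread over 12 months
#' monthly_cost(30, "standard_30d", ddd_price = 1)
monthly_cost <- function(pack_price, regimen, ddd_price = NULL) {
  args <- vctrs_recycle(pack_price = pack_price, regimen = regimen,
                        ddd_price = if (is.null(ddd_price)) NA_real_ else ddd_price)
  with(args, {
    if (any(!is.finite(pack_price) | pack_price <= 0)) {
      rlang::abort("`pack_price` must be positive.")
    }
    bad <- setdiff(unique(regimen), REGIMENS)
    if (length(bad)) {
      rlang::abort(paste0("unknown regimen(s): ", paste(bad, collapse = ", "), "."))
    }
    need_ddd <- regimen == "standard_30d"
    if (any(need_ddd & (!is.finite(ddd_price) | ddd_price <= 0))) {
      rlang::abort("`ddd_price` must be a positive number for standard_30d regimens.")
    }
    out <- numeric(length(regimen))
    out[need_ddd] <- 30 * ddd_price[need_ddd]
    out[regimen == "pack_cycle_28d"] <- 2 * pack_price[regimen == "pack_cycle_28d"]
    out[regimen == "yearly"] <- pack_price[regimen == "yearly"] / 12
    out
  })
}

#' Monthly treatment costs for a whole panel
#'
#' Joins a price panel with its product catalogue and computes the per-DDD
#' price and the standardized monthly cost for every (country, product) cell.
#' If the panel carries a `monthly_cost` column already (a fixture of printed
#' monthly figures rather than pack prices), those values are kept and
#' costing is bypassed for them.
#'
#' @param panel A [price_panel()].
#' @param products A product table ([product_table()]).
#' @return A tibble `country, product_id, pack_price, ddd_price, monthly_cost`.
#' @export
monthly_cost_table <- function(panel, products) {
  tbl <- as_tibble(panel)
  missing <- setdiff(unique(tbl$product_id), products$product_id)
  if (length(missing)) {
    rlang::abort(paste0("products missing from catalogue: ",
                        paste(missing, collapse = ", "), "."))
  }
  out <- dplyr::left_join(tbl, as_tibble(products), by = "product_id")
  out$ddd_price <- price_per_ddd(out$pack_price, out$pack_size,
                                 out$strength_mg, out$ddd_mg)
  computed <- monthly_cost(out$pack_price, out$regimen, out$ddd_price)
  if ("monthly_cost" %in% names(tbl)) {
    out$monthly_cost <- ifelse(is.na(tbl$monthly_cost), computed, tbl$monthly_cost)
  } else {
    out$monthly_cost <- computed
  }
  out[c("country", "product_id", "pack_price", "ddd_price", "monthly_cost")]
}
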