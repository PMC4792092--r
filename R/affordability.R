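#' Income distributions for population-share estimation
#'
#' An income distribution is any object whose cumulative distribution
#' function over monthly income (EUR) can be evaluated. Two kinds are
#' supported: a parametric lognormal (the conventional shape for household
#' income) and an empirical quantile table.
#'
#' The empirical CDF is evaluated left-continuously, as the population mass
#' with income strictly below the evaluation point, with linear
#' interpolation between tabulated quantiles. This makes the degenerate
#' point-mass table (everyone earns the same wage) agree with the strict
#' per-treatment classification rule: a cost exactly at the threshold is
#' not catastrophic for anyone.
#'
#' @param mu Mean of log monthly income (log-EUR).
#' @param sigma Standard deviation of log income; positive.
#' @return An object of class `maff_income`.
#' @export
#' @examples
#' d <- income_lognormal(mu = log(1000), sigma = 0.5)
#' income_cdf(d, 1000)  # 0.5: the median
income_lognormal <- function(mu, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    rlang::abort("`sigma` must be a single positive number.")
  }
  structure(list(kind = "lognormal", mu = mu, sigma = sigma),
            class = "maff_income")
}

#' @rdname income_lognormal
#' @param quantiles A data frame with columns `probability` (strictly
#'   ascending, in (0,1)) and `income` (non-decreasing, EUR/month).
#' @export
income_empirical <- function(quantiles) {
  q <- as_tibble(quantiles)
  if (!all(c("probability", "income") %in% names(q))) {
    rlang::abort("empirical quantiles need columns `probability` and `income`.")
  }
  p <- as.numeric(q$probability)
  u <- as.numeric(q$income)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1) || is.unsorted(p, strictly = TRUE)) {
    rlang::abort("`probability` must be strictly ascending within (0, 1).")
  }
  if (any(!is.finite(u)) || any(u < 0) || is.unsorted(u)) {
    rlang::abort("`income` must be non-negative and non-decreasing.")
  }
  structure(list(kind = "empirical",
                 quantiles = tibble(probability = p, income = u)),
            class = "maff_income")
}

#' Evaluate an income CDF
#'
#' @param dist A `maff_income` object.
#' @param x Monthly income level(s), EUR.
#' @return Probability in `[0, 1]` for each `x`.
#' @export
income_cdf <- function(dist, x) {
  stopifnot(inherits(dist, "maff_income"))
  if (dist$kind == "lognormal") {
    out <- ifelse(x <= 0, 0, stats::plnorm(x, dist$mu, dist$sigma))
    return(as.numeric(out))
  }
  q <- dist$quantiles
  # left-continuous: mass strictly below x; ties collapse to their lowest
  # tabulated probability (the left limit of the CDF at that income)
  u <- q$income
  p <- q$probability
  first <- !duplicated(u)
  uu <- u[first]
  pp <- p[first]
  vapply(as.numeric(x), function(xi) {
    if (!is.finite(xi)) rlang::abort("income level must be finite.")
    if (xi <= uu[1]) return(0)
    if (xi > uu[length(uu)]) return(1)
    if (length(uu) == 1L) return(1)  # point mass, xi above it
    j <- findInterval(xi, uu)
    if (xi == uu[j]) return(pp[j])
    pj1 <- if (j == length(uu)) 1 else pp[j + 1L]
    pp[j] + (pj1 - pp[j]) * (xi - uu[j]) / (uu[j + 1L] - uu[j])
  }, numeric(1))
}

#' Catastrophic spending allowance
#'
#' The monthly amount above which spending on a single treatment is
#' catastrophic: `fraction * wage`. The conventional medicines-only fraction
#' is 5% of disposable income (40% is the total-health-expenditure analogue).
#'
#' @param wage Monthly income basis, EUR (typically the lowest official
#'   monthly wage). Positive.
#' @param fraction Catastrophic fraction, strictly in (0, 1).
#' @return EUR per month. Vectorized over `wage`.
#' @export
#' @examples
#' catastrophic_allowance(992.4, 0.05)  # 49.62
catastrophic_allowance <- function(wage, fraction = 0.05) {
  check_wage_fraction(wage, fraction)
  fraction * wage
}

check_wage_fraction <- function(wage, fraction) {
  if (any(!is.finite(wage) | wage <= 0)) {
    rlang::abort("`wage` must be positive.")
  }
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0 || fraction >= 1) {
    rlang::abort("`fraction` must be a single number strictly between 0 and 1.")
  }
  invisible(TRUE)
}

#' Residual income threshold
#'
#' The income left once the catastrophic allowance is removed:
#' `wage * (1 - fraction)`. This is the figure conventionally reported next
#' to the wage row in affordability tables.
#'
#' @inheritParams catastrophic_allowance
#' @return EUR per month (exact value). Vectorized over `wage`.
#' @seealso [format_residual_threshold()] for the display convention.
#' @export
residual_threshold <- function(wage, fraction = 0.05) {
  check_wage_fraction(wage, fraction)
  wage * (1 - fraction)
}

#' Display form of the residual threshold
#'
#' Reporting convention for the residual threshold: when the wage is an
#' integer number of euros the threshold is truncated to whole euros; when
#' the wage carries decimals the threshold is rounded half-up to one
#' decimal. (So a 992.40 wage at 5% prints 942.8, while an 878 wage prints
#' 834, not 834.1.)
#'
#' @inheritParams catastrophic_allowance
#' @return Numeric display value. Vectorized over `wage`.
#' @export
format_residual_threshold <- function(wage, fraction = 0.05) {
  t <- residual_threshold(wage, fraction)
  integral <- wage == floor(wage)
  ifelse(integral, floor(t), floor(t * 10 + 0.5) / 10)
}

#' Is a monthly treatment cost catastrophic?
#'
#' A treatment is catastrophic when its monthly cost strictly exceeds the
#' allowance `fraction * wage`. The inequality is strict: spending exactly
#' the allowance does not exceed it.
#'
#' @param monthly_cost Monthly treatment cost, EUR. Non-negative.
#' @inheritParams catastrophic_allowance
#' @return Logical. Vectorized over `monthly_cost` and `wage`.
#' @export
#' @examples
#' is_catastrophic(590.98, wage = 870)  # TRUE: osteoporosis infusion in CY
#' is_catastrophic(7.08, wage = 992.4)  # FALSE
is_catastrophic <- function(monthly_cost, wage, fraction = 0.05) {
  if (any(!is.finite(monthly_cost) | monthly_cost < 0)) {
    rlang::abort("`monthly_cost` must be non-negative.")
  }
  monthly_cost > catastrophic_allowance(wage, fraction)
}

#' Population share facing catastrophic expenditure
#'
#' The share of the population for whom acquiring one treatment would be
#' catastrophic: those whose monthly income is below
#' `monthly_cost / fraction`, the income level at which the treatment costs
#' exactly the catastrophic fraction. This is the income CDF evaluated at
#' that level; for a lognormal income it is
#' `pnorm((log(monthly_cost / fraction) - mu) / sigma)`.
#'
#' @param monthly_cost Monthly treatment cost, EUR. Non-negative. A zero
#'   cost returns share 0.
#' @param fraction Catastrophic fraction, strictly in (0, 1).
#' @param dist A `maff_income` distribution ([income_lognormal()] or
#'   [income_empirical()]).
#' @return Proportion in `[0, 1]`. Vectorized over `monthly_cost`.
#' @export
#' @examples
#' d <- income_lognormal(log(1000), 0.5)
#' population_share_catastrophic(50, 0.05, d)  # required income 1000 -> 0.5
population_share_catastrophic <- function(monthly_cost, fraction, dist) {
  if (any(!is.finite(monthly_cost) | monthly_cost < 0)) {
    rlang::abort("`monthly_cost` must be non-negative.")
  }
  check_wage_fraction(1, fraction)
  required <- monthly_cost / fraction
  out <- income_cdf(dist, required)
  out[monthly_cost == 0] <- 0
  out
}

#' Persons affected, from a share and a base count
#'
#' Rounds `share * count` half-up to whole persons.
#'
#' @param share Proportion in `[0, 1]`.
#' @param count Base population (persons). Non-negative.
#' @return Integer-valued numeric. Vectorized.
#' @export
#' @examples
#' affected_count(0.25, 600000)  # 150000
affected_count <- function(share, count) {
  if (any(!is.finite(share) | share < 0 | share > 1)) {
    rlang::abort("`share` must lie in [0, 1].")
  }
  if (any(!is.finite(count) | count < 0)) {
    rlang::abort("`count` must be non-negative.")
  }
  floor(share * count + 0.5)
}

#' Catastrophic-expenditure report for a panel of monthly costs
#'
#' Classifies every (country, product) monthly cost against the country's
#' minimum-wage allowance, and — when income distributions are supplied —
#' estimates the population share and the affected count for each cell.
#'
#' @param costs A tibble `country, product_id, monthly_cost` (e.g. from
#'   [monthly_cost_table()] or the worked-example fixture).
#' @param econ An [economics_table()] supplying `min_wage` and, optionally,
#'   `population` for affected counts.
#' @param config An [analysis_config()] supplying the catastrophic fraction.
#' @param income Optional named list of `maff_income` objects, one per
#'   country code; when absent the share and count columns are `NA`.
#' @param count_col Name of the count column in `econ` to use as the base
#'   for [affected_count()] (default `"population"`); use an `n_<condition>`
#'   column for condition-specific counts.
#' @return A tibble of class `maff_afford` with columns `country,
#'   product_id, monthly_cost, allowance, residual_threshold, catastrophic,
#'   pop_share, affected_count`.
#' @export
build_affordability_report <- function(costs, econ, config = analysis_config(),
                                       income = NULL, count_col = "population") {
  costs <- as_tibble(costs)
  need <- c("country", "product_id", "monthly_cost")
  if (!all(need %in% names(costs))) {
    rlang::abort(paste0("`costs` needs columns: ", paste(need, collapse = ", "), "."))
  }
  missing <- setdiff(unique(costs$country), econ$country)
  if (length(missing)) {
    rlang::abort(paste0("no economics row for: ", paste(missing, collapse = ", "), "."))
  }
  f <- config$catastrophic_fraction
  out <- dplyr::left_join(costs[need],
                          as_tibble(econ)[c("country", "min_wage",
                                            intersect(count_col, names(econ)))],
                          by = "country")
  out$allowance <- catastrophic_allowance(out$min_wage, f)
  out$residual_threshold <- residual_threshold(out$min_wage, f)
  out$catastrophic <- is_catastrophic(out$monthly_cost, out$min_wage, f)
  out$pop_share <- NA_real_
  out$affected_count <- NA_real_
  if (!is.null(income)) {
    for (cc in unique(out$country)) {
      if (is.null(income[[cc]])) {
        rlang::warn(paste0("no income distribution for ", cc,
                           "; its population share is left NA."))
        next
      }
      rows <- out$country == cc
      out$pop_share[rows] <-
        population_share_catastrophic(out$monthly_cost[rows], f, income[[cc]])
    }
    if (count_col %in% names(out)) {
      ok <- !is.na(out$pop_share) & !is.na(out[[count_col]])
      out$affected_count[ok] <- affected_count(out$pop_share[ok],
                                               out[[count_col]][ok])
    }
  }
  out <- out[c("country", "product_id", "monthly_cost", "allowance",
               "residual_threshold", "catastrophic", "pop_share",
               "affected_count")]
  structure(out, fraction = f, class = c("maff_afford", class(out)))
}

#' Write an affordability report to CSV
#'
#' @param x A `maff_afford` report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_affordability_report <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Read income distributions from CSV
#'
#' Two schemas are accepted. Parametric: `country,kind,mu,sigma` with
#' `kind = "lognormal"`. Empirical: `country,probability,income`, one row
#' per tabulated quantile.
#'
#' @param path Path to the CSV file.
#' @return Named list of `maff_income` objects, one per country.
#' @export
load_income_distributions <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("kind", "mu", "sigma") %in% names(tbl))) {
    bad <- setdiff(unique(tbl$kind), "lognormal")
    if (length(bad)) {
      rlang::abort(paste0("unsupported income kind(s): ",
                          paste(bad, collapse = ", "), "."))
    }
    out <- lapply(seq_len(nrow(tbl)), function(i) {
      income_lognormal(tbl$mu[[i]], tbl$sigma[[i]])
    })
    names(out) <- tbl$country
    return(out)
  }
  if (all(c("probability", "income") %in% names(tbl))) {
    split_tbl <- split(tbl[c("probability", "income")], tbl$country)
    return(lapply(split_tbl, income_empirical))
  }
  rlang::abort(paste0(path, ": expected columns country,kind,mu,sigma or ",
                      "country,probability,income."))
}
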