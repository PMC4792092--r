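#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
NULL

REGIMENS <- c("standard_30d", "pack_cycle_28d", "yearly")

#' Analysis configuration
#'
#' Bundles the knobs shared across the pipeline: the catastrophic spending
#' fraction, the reference country of the bilateral comparison, and the CSV
#' decimal convention of the input files.
#'
#' @param catastrophic_fraction Proportion of monthly income above which
#'   spending on a single treatment is catastrophic. Default 0.05, the
#'   conventional medicines-only threshold; 0.40 expresses the corresponding
#'   total-health-expenditure rule.
#' @param reference_country ISO-3166 alpha-2 code of the reference (weighting)
#'   country. Default `"CY"`.
#' @param decimal_style Either `"point"` or `"comma"`; how numerics are
#'   written in the input CSV files. See [load_price_panel()].
#' @return An object of class `maff_config`.
#' @export
#' @examples
#' analysis_config(catastrophic_fraction = 0.05, reference_country = "CY")
analysis_config <- function(catastrophic_fraction = 0.05,
                            reference_country = "CY",
                            decimal_style = c("point", "comma")) {
  decimal_style <- match.arg(decimal_style)
  if (!is.numeric(catastrophic_fraction) || length(catastrophic_fraction) != 1L ||
      !is.finite(catastrophic_fraction) ||
      catastrophic_fraction <= 0 || catastrophic_fraction >= 1) {
    abort("`catastrophic_fraction` must be a single number strictly between 0 and 1.")
  }
  if (!is.character(reference_country) || length(reference_country) != 1L ||
      is.na(reference_country) || !nzchar(reference_country)) {
    abort("`reference_country` must be a non-empty country code.")
  }
  structure(
    list(
      catastrophic_fraction = catastrophic_fraction,
      reference_country = reference_country,
      decimal_style = decimal_style
    ),
    class = "maff_config"
  )
}

#' Product catalogue constructor
#'
#' A product row carries the pack description needed to normalize a pack
#' price to a defined-daily-dose (DDD) price and a monthly treatment cost:
#' unit strength, pack size, the DDD, and the dosing regimen.
#'
#' Regimens:
#' * `standard_30d` — chronic daily dosing; a treatment month is 30 DDDs.
#' * `pack_cycle_28d` — the pack covers a 28-day cycle; a month costs two packs.
#' * `yearly` — one pack per year (e.g. an annual infusion); monthly cost is
#'   the pack price divided by 12.
#'
#' @param product_id Free-text slug identifying the product.
#' @param name Human-readable name.
#' @param strength_mg Active substance mass per unit, mg. Must be positive.
#' @param pack_size Units per pack. Must be at least 1.
#' @param ddd_mg Defined daily dose, mg. Must be positive.
#' @param regimen One of `"standard_30d"`, `"pack_cycle_28d"`, `"yearly"`.
#' @param condition Condition label (e.g. `"diabetes"`).
#' @return A tibble of class `maff_products`.
#' @export
product_table <- function(product_id, name = product_id, strength_mg, pack_size,
                          ddd_mg, regimen = "standard_30d",
                          condition = NA_character_) {
  tbl <- tibble(
    product_id = as.character(product_id),
    name = as.character(name),
    strength_mg = as.numeric(strength_mg),
    pack_size = as.numeric(pack_size),
    ddd_mg = as.numeric(ddd_mg),
    regimen = as.character(regimen),
    condition = as.character(condition)
  )
  validate_products(tbl)
}

validate_products <- function(tbl) {
  if (anyDuplicated(tbl$product_id)) {
    abort("duplicate `product_id` in product table.")
  }
  if (any(!is.finite(tbl$strength_mg) | tbl$strength_mg <= 0)) {
    abort("`strength_mg` must be positive for every product.")
  }
  if (any(!is.finite(tbl$pack_size) | tbl$pack_size < 1)) {
    abort("`pack_size` must be at least 1 for every product.")
  }
  if (any(!is.finite(tbl$ddd_mg) | tbl$ddd_mg <= 0)) {
    abort("`ddd_mg` must be positive for every product.")
  }
  bad <- setdiff(unique(tbl$regimen), REGIMENS)
  if (length(bad)) {
    abort(paste0("unknown regimen(s): ", paste(bad, collapse = ", "),
                 ". Must be one of: ", paste(REGIMENS, collapse = ", "), "."))
  }
  class(tbl) <- c("maff_products", class(tbl))
  tbl
}

#' Price panel constructor
#'
#' A price panel holds one retail price (EUR) per (country, product) cell,
#' together with the reference country of the comparison. All prices are in a
#' single currency; the five study countries all use the euro, so no
#' conversion is performed.
#'
#' @param entries A data frame with columns `country`, `product_id`,
#'   `pack_price` (EUR, strictly positive).
#' @param reference_country Country code that anchors the comparison; must
#'   have at least one price in `entries`.
#' @return A tibble of class `maff_price_panel` with a `reference_country`
#'   attribute.
#' @export
#' @examples
#' price_panel(
#'   tibble::tibble(
#'     country = c("CY", "IT"),
#'     product_id = c("esomeprazole", "esomeprazole"),
#'     pack_price = c(8.63, 7.08)
#'   ),
#'   reference_country = "CY"
#' )
price_panel <- function(entries, reference_country) {
  entries <- as_tibble(entries)
  need <- c("country", "product_id", "pack_price")
  if (!all(need %in% names(entries))) {
    abort(paste0("price panel needs columns: ", paste(need, collapse = ", "), "."))
  }
  entries <- entries[need]
  entries$country <- as.character(entries$country)
  entries$product_id <- as.character(entries$product_id)
  entries$pack_price <- as.numeric(entries$pack_price)
  if (any(!is.finite(entries$pack_price) | entries$pack_price <= 0)) {
    abort("all prices in a price panel must be positive and finite.")
  }
  if (anyDuplicated(entries[c("country", "product_id")])) {
    abort("duplicate (country, product_id) cell in price panel.")
  }
  if (!reference_country %in% entries$country) {
    abort(paste0("reference country '", reference_country,
                 "' has no prices in the panel."))
  }
  structure(entries,
            reference_country = reference_country,
            class = c("maff_price_panel", class(entries)))
}

#' @export
print.maff_price_panel <- function(x, ...) {
  cat("<price panel> reference:", attr(x, "reference_country"),
      "| countries:", length(unique(x$country)),
      "| products:", length(unique(x$product_id)), "\n")
  NextMethod()
}

#' Reference-country sales weight table
#'
#' Sales values (EUR, reference country) per product. These are budget-impact
#' weights: a product's significance in the index is its share of reference
#' market expenditure, not its unit price.
#'
#' @param weights A data frame with columns `product_id`, `sales_value`
#'   (non-negative, at least one positive), or a named numeric vector.
#' @return A tibble of class `maff_weights`.
#' @export
weight_table <- function(weights) {
  if (is.numeric(weights) && !is.null(names(weights))) {
    weights <- tibble(product_id = names(weights),
                      sales_value = as.numeric(weights))
  }
  weights <- as_tibble(weights)
  need <- c("product_id", "sales_value")
  if (!all(need %in% names(weights))) {
    abort("weight table needs columns: product_id, sales_value.")
  }
  weights <- weights[need]
  weights$product_id <- as.character(weights$product_id)
  weights$sales_value <- as.numeric(weights$sales_value)
  if (anyDuplicated(weights$product_id)) {
    abort("duplicate `product_id` in weight table.")
  }
  if (any(!is.finite(weights$sales_value) | weights$sales_value < 0)) {
    abort("sales values must be finite and non-negative.")
  }
  if (!any(weights$sales_value > 0)) {
    abort("at least one sales value must be positive.")
  }
  structure(weights, class = c("maff_weights", class(weights)))
}

#' Country economics table
#'
#' Per-country GDP at purchasing power parity per capita (for the
#' affordability adjustment), the lowest official monthly wage (the income
#' basis of the catastrophic-expenditure thresholds) and, optionally,
#' population or condition counts used to turn population shares into
#' affected-person counts.
#'
#' @param econ A data frame with columns `country`, `gdp_ppp_pc`, `min_wage`
#'   and optionally `population` plus any number of `n_<condition>` count
#'   columns.
#' @return A tibble of class `maff_economics`.
#' @export
economics_table <- function(econ) {
  econ <- as_tibble(econ)
  need <- c("country", "gdp_ppp_pc", "min_wage")
  if (!all(need %in% names(econ))) {
    abort("economics table needs columns: country, gdp_ppp_pc, min_wage.")
  }
  econ$country <- as.character(econ$country)
  econ$gdp_ppp_pc <- as.numeric(econ$gdp_ppp_pc)
  econ$min_wage <- as.numeric(econ$min_wage)
  if (anyDuplicated(econ$country)) abort("duplicate country in economics table.")
  if (any(!is.finite(econ$gdp_ppp_pc) | econ$gdp_ppp_pc <= 0)) {
    abort("`gdp_ppp_pc` must be positive for every country.")
  }
  if (any(!is.finite(econ$min_wage) | econ$min_wage <= 0)) {
    abort("`min_wage` must be positive for every country.")
  }
  count_cols <- c(intersect("population", names(econ)),
                  grep("^n_", names(econ), value = TRUE))
  for (cc in count_cols) {
    econ[[cc]] <- as.numeric(econ[[cc]])
    if (any(econ[[cc]] < 0, na.rm = TRUE)) {
      abort(paste0("counts in `", cc, "` must be non-negative."))
    }
  }
  structure(econ, class = c("maff_economics", class(econ)))
}

# ---- CSV I/O ---------------------------------------------------------------

# Read a CSV whose numeric columns are written with decimal commas. If the
# separator is ";" this is plain locale parsing. If the separator is itself
# ",", a decimal comma splits a numeric field in two; rows are reconstructed
# only when unambiguous: the text columns come first, and the surplus token
# count must be 0 (no split fields) or equal to the number of numeric columns
# (every numeric field split). Anything else is a parse error naming the line.
read_csv_locale <- function(path, text_cols, num_cols, decimal_style) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (decimal_style == "point") {
    tbl <- read_csv_exact(path)
    tbl <- check_csv_columns(tbl, path, text_cols, num_cols)
    return(convert_numeric_cols(tbl, path, num_cols))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(paste0("empty file: ", path))
  sep <- if (grepl(";", lines[[1]], fixed = TRUE)) ";" else ","
  if (sep == ";") {
    tbl <- readr::read_delim(path, delim = ";", show_col_types = FALSE,
                             progress = FALSE,
                             locale = readr::locale(decimal_mark = ",",
                                                    grouping_mark = "."))
    return(check_csv_columns(tbl, path, text_cols, num_cols))
  }
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  k_text <- length(text_cols)
  k_num <- length(num_cols)
  n_struct <- k_text + k_num
  n_rows <- length(lines) - 1L
  text_mat <- matrix(NA_character_, n_rows, k_text)
  num_mat <- matrix(NA_real_, n_rows, k_num)
  for (i in seq_len(n_rows)) {
    toks <- trimws(strsplit(lines[[i + 1L]], ",", fixed = TRUE)[[1]])
    extra <- length(toks) - n_struct
    if (extra == 0L) {
      nums <- suppressWarnings(as.numeric(sub(",", ".", toks[(k_text + 1L):n_struct])))
    } else if (extra == k_num) {
      tail_toks <- toks[(k_text + 1L):length(toks)]
      nums <- suppressWarnings(as.numeric(
        paste(tail_toks[seq(1L, by = 2L, length.out = k_num)],
              tail_toks[seq(2L, by = 2L, length.out = k_num)], sep = ".")
      ))
    } else {
      abort(paste0("parse error in ", path, ", line ", i + 1L,
                   ": expected ", n_struct, " or ", n_struct + k_num,
                   " comma-separated fields, found ", length(toks), "."))
    }
    if (anyNA(nums)) {
      abort(paste0("parse error in ", path, ", line ", i + 1L,
                   ": non-numeric value in a numeric column."))
    }
    text_mat[i, ] <- toks[seq_len(k_text)]
    num_mat[i, ] <- nums
  }
  tbl <- as_tibble(as.data.frame(text_mat, stringsAsFactors = FALSE))
  names(tbl) <- header[seq_len(k_text)]
  for (j in seq_len(k_num)) tbl[[num_cols[[j]]]] <- num_mat[, j]
  check_csv_columns(tbl, path, text_cols, num_cols)
}

check_csv_columns <- function(tbl, path, text_cols, num_cols) {
  need <- c(text_cols, num_cols)
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(paste0(path, " is missing column(s): ", paste(missing, collapse = ", "), "."))
  }
  tbl
}

# read every column as character; numerics are converted by base R, whose
# decimal parser is correctly rounded, so written values round-trip exactly
read_csv_exact <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

convert_numeric_cols <- function(tbl, path, num_cols) {
  for (nm in intersect(num_cols, names(tbl))) {
    if (is.character(tbl[[nm]])) {
      val <- suppressWarnings(as.numeric(tbl[[nm]]))
      bad <- which(is.na(val) & !is.na(tbl[[nm]]) & nzchar(tbl[[nm]]))
      if (length(bad)) {
        abort(paste0("parse error in ", path, ", line ", bad[[1]] + 1L,
                     ": non-numeric value in column `", nm, "`."))
      }
      tbl[[nm]] <- val
    }
  }
  tbl
}

#' Read a price panel from CSV
#'
#' Expected schema: `country,product_id,pack_price` (header required, UTF-8).
#' With `decimal_style = "comma"` in the configuration, numerics written with
#' a decimal comma are accepted, either in semicolon-separated files or, for
#' comma-separated files, by unambiguous reconstruction of the split price
#' field.
#'
#' @param path Path to the CSV file.
#' @param config An [analysis_config()]; supplies the reference country and
#'   the decimal convention.
#' @return A validated [price_panel()].
#' @export
load_price_panel <- function(path, config = analysis_config()) {
  tbl <- read_csv_locale(path, c("country", "product_id"), "pack_price",
                         config$decimal_style)
  price_panel(tbl, reference_country = config$reference_country)
}

#' Read a sales weight table from CSV
#'
#' Expected schema: `product_id,sales_value`.
#'
#' @inheritParams load_price_panel
#' @return A validated [weight_table()].
#' @export
load_weight_table <- function(path, config = analysis_config()) {
  weight_table(read_csv_locale(path, "product_id", "sales_value",
                               config$decimal_style))
}

#' Read a country economics table from CSV
#'
#' Expected schema: `country,gdp_ppp_pc,min_wage[,population][,n_<condition>...]`.
#'
#' @inheritParams load_price_panel
#' @return A validated [economics_table()].
#' @export
load_economics_table <- function(path, config = analysis_config()) {
  tbl <- read_csv_exact(path)
  check_csv_columns(tbl, path, "country", c("gdp_ppp_pc", "min_wage"))
  num_cols <- c("gdp_ppp_pc", "min_wage",
                intersect("population", names(tbl)),
                grep("^n_", names(tbl), value = TRUE))
  economics_table(convert_numeric_cols(tbl, path, num_cols))
}

#' Read a product catalogue from CSV
#'
#' Expected schema:
#' `product_id,name,strength_mg,pack_size,ddd_mg,regimen,condition`.
#'
#' @inheritParams load_price_panel
#' @return A validated product table.
#' @export
load_product_table <- function(path, config = analysis_config()) {
  tbl <- read_csv_exact(path)
  check_csv_columns(tbl, path, c("product_id", "name", "regimen", "condition"),
                    c("strength_mg", "pack_size", "ddd_mg"))
  validate_products(convert_numeric_cols(tbl, path,
                                         c("strength_mg", "pack_size", "ddd_mg")))
}

#' Write pipeline tables to CSV
#'
#' Writers for the package's CSV schemas. Values round-trip exactly: reading
#' a written file reproduces the numbers bit for bit (point-decimal output).
#'
#' @param x The object to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_price_panel <- function(x, path) {
  write_csv_exact(as_tibble(x)[c("country", "product_id", "pack_price")], path)
  invisible(path)
}

#' @rdname write_price_panel
#' @export
write_weight_table <- function(x, path) {
  write_csv_exact(as_tibble(x)[c("product_id", "sales_value")], path)
  invisible(path)
}

#' @rdname write_price_panel
#' @export
write_economics_table <- function(x, path) {
  write_csv_exact(as_tibble(x), path)
  invisible(path)
}

# write doubles with 17 significant digits so values round-trip bit-exactly
write_csv_exact <- function(tbl, path) {
  for (nm in names(tbl)) {
    if (is.double(tbl[[nm]])) {
      tbl[[nm]] <- ifelse(is.na(tbl[[nm]]), NA_character_,
                          sprintf("%.17g", tbl[[nm]]))
    }
  }
  readr::write_csv(tbl, path, na = "")
  invisible(path)
}

#' Products comparable between the reference and a target country
#'
#' The bilateral basket: products with a positive price in both the reference
#' and the target country and a weight entry. Products missing on either side
#' are dropped (pairwise basket reduction, no imputation), mirroring how
#' cross-country samples shrink when identical presentations cannot be
#' matched everywhere. Returned in lexicographic order so downstream results
#' do not depend on input row order.
#'
#' @param panel A [price_panel()].
#' @param weights A [weight_table()].
#' @param country Target country code.
#' @param verbose Emit a message per dropped product.
#' @return Character vector of product ids (sorted). Errors if empty.
#' @export
intersect_basket <- function(panel, weights, country, verbose = FALSE) {
  ref <- attr(panel, "reference_country")
  in_ref <- panel$product_id[panel$country == ref]
  in_tgt <- panel$product_id[panel$country == country]
  weighted <- weights$product_id[weights$sales_value >= 0]
  basket <- sort(intersect(intersect(in_ref, in_tgt), weighted))
  dropped <- sort(setdiff(intersect(in_ref, weighted), in_tgt))
  if (verbose && length(dropped)) {
    inform(paste0("basket ", ref, " vs ", country, ": dropped ",
                  length(dropped), " product(s) unpriced in ", country, ": ",
                  paste(dropped, collapse = ", ")))
  }
  if (!length(basket)) {
    abort(paste0("no products are priced in both ", ref, " and ", country,
                 " with weights; the bilateral index is undefined."))
  }
  basket
}
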