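#' Disease expenditure table
#'
#' Named direct-healthcare cost categories (AUD million) for one condition
#' and year, e.g. the AIHW disease-expenditure breakdown for colorectal
#' cancer. The total is derived as the sum of the categories.
#'
#' @param condition Condition label, e.g. `"colorectal cancer"`.
#' @param year Calendar year (or a label such as `"2015-16"`).
#' @param categories Character vector of category names.
#' @param amounts Numeric vector of non-negative amounts, AUD million,
#'   parallel to `categories`.
#'
#' @return An object of class `"expenditure_table"` with a `table`
#'   data.frame (`category`, `amount`) and a derived `total`.
#' @examples
#' expenditure_table("demo", 2020, c("hospital", "pharmacy"), c(100, 20))
#' @export
expenditure_table <- function(condition, year, categories, amounts) {
  stopifnot(is.character(condition), length(condition) == 1L)
  categories <- as.character(categories)
  amounts <- as.numeric(amounts)
  if (length(categories) != length(amounts) || length(categories) == 0L) {
    stop("'categories' and 'amounts' must be non-empty and the same length",
         call. = FALSE)
  }
  if (anyNA(amounts) || any(amounts < 0)) {
    stop("all amounts must be non-negative and non-missing", call. = FALSE)
  }
  if (anyDuplicated(categories)) {
    stop("category names must be unique", call. = FALSE)
  }
  structure(
    list(condition = condition, year = year,
         table = data.frame(category = categories, amount = amounts,
                            stringsAsFactors = FALSE),
         total = sum(amounts)),
    class = "expenditure_table"
  )
}

#' @export
print.expenditure_table <- function(x, ...) {
  cat(sprintf("Expenditure: %s, %s (AUD million)\n", x$condition, x$year))
  print(x$table, row.names = FALSE)
  cat(sprintf("  Total: %.1f\n", x$total))
  invisible(x)
}

#' Inflate an expenditure table to another year's prices
#'
#' Multiplies every category amount by a single aggregate price factor
#' (e.g. a CPI Health-group ratio) and relabels the year. Category names
#' and order are preserved.
#'
#' @param table An [expenditure_table()].
#' @param factor Positive inflation factor.
#' @param year Optional new year label; defaults to the old label.
#' @return A new [expenditure_table()].
#' @examples
#' base <- expenditure_table("demo", 2016, "hospital", 100)
#' inflate(base, 1.1384, year = 2020)
#' @export
inflate <- function(table, factor, year = table$year) {
  stopifnot(inherits(table, "expenditure_table"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("'factor' must be a positive finite scalar", call. = FALSE)
  }
  expenditure_table(table$condition, year, table$table$category,
                    table$table$amount * factor)
}

#' Savings cell: a monetary value with confidence bounds
#'
#' @param central,lower,upper AUD million; must satisfy
#'   `lower <= central <= upper`.
#' @return An object of class `"savings_cell"`.
#' @export
savings_cell <- function(central, lower, upper) {
  if (!(lower <= central && central <= upper)) {
    stop("savings cell bounds must satisfy lower <= central <= upper",
         call. = FALSE)
  }
  structure(list(central = central, lower = lower, upper = upper),
            class = "savings_cell")
}

#' @export
print.savings_cell <- function(x, digits = 2, ...) {
  cat(format_cell(x, digits = digits), "\n")
  invisible(x)
}

#' Annual cost savings from a risk reduction under an uptake scenario
#'
#' Applies a fractional risk reduction one-for-one to each expenditure
#' category — a 1% decline in disease risk saves 1% of each cost category
#' — attenuated by the population uptake fraction:
#' `saving = amount * reduction * uptake`, per category and per confidence
#' bound. Totals are computed from unrounded values; rounding happens only
#' at report time.
#'
#' @param table The current-year [expenditure_table()].
#' @param reduction A `"risk_reduction"` from [scale_risk_reduction()].
#' @param uptake Fraction of the population adopting the target intake,
#'   in `[0, 1]`.
#' @param scenario_name Optional label stored in the report.
#'
#' @return An object of class `"savings_report"`: a `per_category`
#'   data.frame (`category`, `central`, `lower`, `upper`), a `total`
#'   [savings_cell()], and metadata (`condition`, `scenario_name`,
#'   `uptake`, `annual` flag).
#' @examples
#' tab <- expenditure_table("demo", 2020, "hospital", 100)
#' rr <- dose_response_rr("demo", 0.9, 0.85, 0.95, dose = 90)
#' compute_savings(tab, scale_risk_reduction(rr, 27), uptake = 0.5)
#' @export
compute_savings <- function(table, reduction, uptake,
                            scenario_name = sprintf("uptake %g%%", 100 * uptake)) {
  stopifnot(inherits(table, "expenditure_table"),
            inherits(reduction, "risk_reduction"))
  if (!is.numeric(uptake) || length(uptake) != 1L || is.na(uptake) ||
      uptake < 0 || uptake > 1) {
    stop("'uptake' must be a fraction in [0, 1]", call. = FALSE)
  }
  if (reduction$central < 0) {
    warning("negative risk reduction: the 'savings' are cost increases",
            call. = FALSE)
  }
  amt <- table$table$amount
  per <- data.frame(
    category = table$table$category,
    central = amt * reduction$central * uptake,
    lower = amt * reduction$lower * uptake,
    upper = amt * reduction$upper * uptake,
    stringsAsFactors = FALSE
  )
  structure(
    list(condition = table$condition, scenario_name = scenario_name,
         uptake = uptake, per_category = per,
         total = savings_cell(sum(per$central), sum(per$lower), sum(per$upper)),
         annual = TRUE),
    class = "savings_report"
  )
}

#' @export
print.savings_report <- function(x, digits = 2, ...) {
  kind <- if (isTRUE(x$annual)) "annual" else "discounted"
  cat(sprintf("Savings (%s, AUD million): %s, scenario %s (uptake %g%%)\n",
              kind, x$condition, x$scenario_name, 100 * x$uptake))
  per <- x$per_category
  disp <- data.frame(
    category = per$category,
    savings = vapply(seq_len(nrow(per)), function(i) {
      format_cell(savings_cell(per$central[i], per$lower[i], per$upper[i]),
                  digits = digits)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  print(disp, row.names = FALSE)
  cat(sprintf("  Total: %s\n", format_cell(x$total, digits = digits)))
  invisible(x)
}
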