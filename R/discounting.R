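#' Discounting specification
#'
#' An annual real discount rate for net-present-value calculations.
#' Year 0 is undiscounted; a saving accruing `n` years into the future is
#' worth `(1 + rate)^(-n)` of its nominal value today.
#'
#' @param rate Annual rate as a fraction; default 0.07 (the 7% real rate
#'   used across Australian jurisdictions). Must exceed -1.
#' @return An object of class `"discount_spec"`.
#' @examples
#' discount_spec()        # 7%
#' discount_spec(0.03)    # 3%
#' @export
discount_spec <- function(rate = 0.07) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= -1) {
    stop("'rate' must be a numeric scalar > -1", call. = FALSE)
  }
  structure(list(rate = rate), class = "discount_spec")
}

#' @export
print.discount_spec <- function(x, ...) {
  cat(sprintf("Discount rate: %g%% per year\n", 100 * x$rate))
  invisible(x)
}

#' Present-value discount factor for year n
#'
#' @param spec A [discount_spec()].
#' @param n Year index (or vector of indices), non-negative integers;
#'   year 0 gives factor 1.
#' @return `(1 + rate)^(-n)`, vectorized over `n`.
#' @examples
#' discount_factor(discount_spec(0.07), 0:4)
#' @export
discount_factor <- function(spec, n) {
  stopifnot(inherits(spec, "discount_spec"))
  if (any(n < 0) || any(n != round(n))) {
    stop("year index 'n' must be a non-negative integer", call. = FALSE)
  }
  (1 + spec$rate)^(-n)
}

annuity_factor <- function(spec, first_year, last_year) {
  sum(discount_factor(spec, first_year:last_year))
}

#' Present value of an annual saving over a year range
#'
#' Sums the discounted value of a constant annual saving over the closed
#' year range `[first_year, last_year]`: each bound of the cell is
#' multiplied by `sum((1 + r)^(-n))` for `n` in the range. Accepts either
#' a single [savings_cell()] or a whole [compute_savings()] report (every
#' category is discounted and the report is re-flagged as discounted).
#'
#' @param annual A `"savings_cell"` or `"savings_report"` of annual values.
#' @param spec A [discount_spec()].
#' @param first_year,last_year Closed integer year range,
#'   `first_year <= last_year`; year 0 is the present.
#' @return The same class as `annual`, discounted.
#' @examples
#' block_sum(savings_cell(10, 8, 12), discount_spec(0.07), 0, 4)
#' @export
block_sum <- function(annual, spec, first_year, last_year) {
  if (first_year > last_year) {
    stop("'first_year' must not exceed 'last_year'", call. = FALSE)
  }
  f <- annuity_factor(spec, first_year, last_year)
  if (inherits(annual, "savings_cell")) {
    return(savings_cell(annual$central * f, annual$lower * f, annual$upper * f))
  }
  if (inherits(annual, "savings_report")) {
    out <- annual
    out$per_category$central <- annual$per_category$central * f
    out$per_category$lower <- annual$per_category$lower * f
    out$per_category$upper <- annual$per_category$upper * f
    out$total <- savings_cell(annual$total$central * f, annual$total$lower * f,
                              annual$total$upper * f)
    out$annual <- FALSE
    return(out)
  }
  stop("'annual' must be a savings_cell or savings_report", call. = FALSE)
}

#' Discounted total over a full horizon
#'
#' Present value of a constant annual saving over years
#' `0 ... horizon_years - 1`.
#'
#' @inheritParams block_sum
#' @param horizon_years Number of years, at least 1.
#' @return Same class as `annual`, discounted over the horizon.
#' @examples
#' horizon_total(savings_cell(37.17, 24.05, 48.11), discount_spec(0.07), 20)
#' @export
horizon_total <- function(annual, spec, horizon_years) {
  if (horizon_years < 1) stop("'horizon_years' must be >= 1", call. = FALSE)
  block_sum(annual, spec, 0L, as.integer(horizon_years) - 1L)
}

#' Staged incremental-adoption present value
#'
#' Present value of a staged adoption path in which each scenario of the
#' schedule occupies its own block of years: the total is the sum over
#' scenarios of that scenario's annual saving discounted over its block.
#' The blocks must tile the horizon exactly (no gaps, no overlap).
#'
#' @param per_scenario_annual Named list of [savings_cell()]s of annual
#'   savings, one per scenario name in the schedule.
#' @param schedule A [scenario_schedule()].
#' @param spec A [discount_spec()].
#' @return A [savings_cell()]: the staged discounted total.
#' @examples
#' sched <- default_schedule()
#' annuals <- setNames(
#'   lapply(sched$scenarios, function(s) {
#'     savings_cell(37.17 * s$uptake, 24.05 * s$uptake, 48.11 * s$uptake)
#'   }),
#'   vapply(sched$scenarios, `[[`, character(1), "name"))
#' incremental_total(annuals, sched, discount_spec(0.07))
#' @export
incremental_total <- function(per_scenario_annual, schedule, spec) {
  stopifnot(inherits(schedule, "scenario_schedule"))
  n_blocks <- length(schedule$scenarios)
  if (n_blocks * schedule$block_length != schedule$horizon) {
    stop("schedule blocks must tile the horizon exactly", call. = FALSE)
  }
  idx <- vapply(schedule$scenarios, `[[`, integer(1), "block_index")
  if (!setequal(idx, seq_len(n_blocks) - 1L)) {
    stop("block indices must cover 0 .. n_blocks - 1 without gaps",
         call. = FALSE)
  }
  total <- savings_cell(0, 0, 0)
  for (s in schedule$scenarios) {
    cell <- per_scenario_annual[[s$name]]
    if (is.null(cell)) {
      stop(sprintf("missing annual savings for scenario '%s'", s$name),
           call. = FALSE)
    }
    yr <- block_years(schedule, s$block_index)
    d <- block_sum(cell, spec, yr[1], yr[2])
    total <- savings_cell(total$central + d$central, total$lower + d$lower,
                          total$upper + d$upper)
  }
  total
}
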