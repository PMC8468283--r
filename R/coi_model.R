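#' Fit a whole-grain cost-of-illness model
#'
#' The central constructor of the package. Three steps are chained for
#' each condition:
#'
#' 1. *Risk scaling* — the pooled dose-response RR is converted to a
#'    fractional risk reduction (with 95% CI) for the intake gap, assuming
#'    linearity ([scale_risk_reduction()]).
#' 2. *Annual savings* — the reduction is applied one-for-one to each
#'    direct-healthcare expenditure category, attenuated by each
#'    scenario's uptake fraction ([compute_savings()]).
#' 3. *Discounting* — annual savings are discounted to present value per
#'    horizon block, over the full horizon, and along the staged
#'    incremental-adoption path in which each scenario occupies its own
#'    block ([block_sum()], [horizon_total()], [incremental_total()]).
#'
#' All intermediate quantities are carried unrounded; rounding is applied
#' only by the print/render methods.
#'
#' @param rr A [dose_response_rr()] or a named list of them (one per
#'   condition).
#' @param expenditure An [expenditure_table()] or a named list of them,
#'   current-year prices, names matching `rr`.
#' @param gap An [intake_gap()]; default the Australian adult gap
#'   21 -> 48 g/day.
#' @param schedule A [scenario_schedule()]; default the four standard
#'   scenarios ([default_schedule()]).
#' @param discount A [discount_spec()]; default 7% per year.
#' @param scaling `"linear"` (default) or `"loglinear"` RR scaling.
#' @param strict_content_units Scale the gap against the reference dose in
#'   content grams rather than product grams (see
#'   [scale_risk_reduction()]).
#' @param report_digits Named vector of display decimal places per
#'   condition (default 2 each).
#'
#' @return An object of class `"coi_model"` with components
#'   `reductions` (per condition), `annual` (condition x scenario
#'   [compute_savings()] reports), `discounted_blocks` (long data.frame),
#'   `horizon_totals`, `incremental`, plus the inputs. Supports
#'   [print()], [summary()], [coef()] (risk-reduction fractions),
#'   [predict()] (savings at new uptakes/horizons) and [plot()].
#' @examples
#' fit <- run_pipeline(coi_example_config())
#' fit
#' @export
coi_model <- function(rr, expenditure, gap = intake_gap(21, 48),
                      schedule = default_schedule(),
                      discount = discount_spec(0.07),
                      scaling = c("linear", "loglinear"),
                      strict_content_units = FALSE,
                      report_digits = NULL) {
  scaling <- match.arg(scaling)
  if (inherits(rr, "dose_response_rr")) rr <- list(rr)
  if (inherits(expenditure, "expenditure_table")) {
    expenditure <- list(expenditure)
  }
  if (is.null(names(rr)) || any(names(rr) == "")) {
    names(rr) <- vapply(expenditure, `[[`, character(1), "condition")
  }
  if (is.null(names(expenditure)) || any(names(expenditure) == "")) {
    names(expenditure) <- vapply(expenditure, `[[`, character(1), "condition")
  }
  conditions <- names(expenditure)
  if (!setequal(conditions, names(rr))) {
    stop("'rr' and 'expenditure' must cover the same condition names",
         call. = FALSE)
  }
  stopifnot(inherits(gap, "intake_gap"),
            inherits(schedule, "scenario_schedule"),
            inherits(discount, "discount_spec"))
  if (gap$gap < 0) {
    stop("negative intake gap: target below current intake", call. = FALSE)
  }
  if (is.null(report_digits)) {
    report_digits <- stats::setNames(rep(2, length(conditions)), conditions)
  }

  scen_names <- vapply(schedule$scenarios, `[[`, character(1), "name")
  outcomes <- list()
  annual <- list()
  blocks_long <- NULL
  horizon_totals <- list()
  incremental <- list()

  for (cond in conditions) {
    red <- scale_risk_reduction(rr[[cond]], gap, scaling = scaling,
                                strict_content_units = strict_content_units)
    tab <- expenditure[[cond]]
    outcomes[[cond]] <- list(
      rr = rr[[cond]], expenditure = tab, reduction = red,
      report_digits = unname(report_digits[cond])
    )
    annual[[cond]] <- stats::setNames(lapply(schedule$scenarios, function(s) {
      compute_savings(tab, red, s$uptake, scenario_name = s$name)
    }), scen_names)

    per_scen_cells <- lapply(annual[[cond]], `[[`, "total")

    # every scenario discounted over every block (the full grid), plus
    # per-scenario horizon totals and the staged incremental path
    for (b in schedule$scenarios) {
      yr <- block_years(schedule, b$block_index)
      for (sn in scen_names) {
        d <- block_sum(per_scen_cells[[sn]], discount, yr[1], yr[2])
        blocks_long <- rbind(blocks_long, data.frame(
          condition = cond, block = b$block_index,
          first_year = yr[1], last_year = yr[2], scenario = sn,
          central = d$central, lower = d$lower, upper = d$upper,
          stringsAsFactors = FALSE))
      }
    }
    horizon_totals[[cond]] <- lapply(per_scen_cells, horizon_total,
                                     spec = discount,
                                     horizon_years = schedule$horizon)
    incremental[[cond]] <- incremental_total(per_scen_cells, schedule,
                                             discount)
  }

  structure(
    list(call = match.call(), gap = gap, schedule = schedule,
         discount = discount, scaling = scaling,
         strict_content_units = strict_content_units,
         outcomes = outcomes, annual = annual,
         discounted_blocks = blocks_long,
         horizon_totals = horizon_totals, incremental = incremental),
    class = "coi_model"
  )
}

#' @export
print.coi_model <- function(x, ...) {
  cat("Whole-grain cost-of-illness model\n")
  cat(sprintf("  Intake gap: %g -> %g g/day (gap %g g/day), %s scaling\n",
              x$gap$current_intake, x$gap$target_intake, x$gap$gap,
              x$scaling))
  cat(sprintf("  Discount rate: %g%%; horizon %d years in %d-year blocks\n",
              100 * x$discount$rate, x$schedule$horizon,
              x$schedule$block_length))
  for (cond in names(x$outcomes)) {
    o <- x$outcomes[[cond]]
    cat(sprintf("  %s: RR %.2f (%.2f-%.2f) per %g g/day -> risk reduction %.1f%% (%.1f-%.1f)\n",
                cond, o$rr$rr_central, o$rr$rr_lower, o$rr$rr_upper,
                o$rr$reference_dose, 100 * o$reduction$central,
                100 * o$reduction$lower, 100 * o$reduction$upper))
  }
  cat("Annual savings totals (AUD million):\n")
  for (cond in names(x$outcomes)) {
    digits <- x$outcomes[[cond]]$report_digits
    cells <- vapply(x$annual[[cond]], function(r) {
      format_cell(r$total, digits)
    }, character(1))
    cat(sprintf("  %s: %s\n", cond,
                paste(sprintf("%s %s", names(cells), cells),
                      collapse = "; ")))
  }
  invisible(x)
}

#' @export
summary.coi_model <- function(object, ...) {
  structure(list(model = object), class = "summary.coi_model")
}

#' @export
print.summary.coi_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nDiscounted savings (AUD million):\n")
  writeLines(paste0("  ", render_discounted(m, "text")))
  invisible(x)
}

#' Risk-reduction fractions of a fitted model
#'
#' @param object A [coi_model()].
#' @param ... Unused.
#' @return Matrix with one row per condition and columns
#'   `central`, `lower`, `upper` (fractional risk reductions for the
#'   model's intake gap).
#' @export
coef.coi_model <- function(object, ...) {
  t(vapply(object$outcomes, function(o) {
    c(central = o$reduction$central, lower = o$reduction$lower,
      upper = o$reduction$upper)
  }, numeric(3)))
}

#' Predict savings at new uptake fractions or horizons
#'
#' Evaluates the fitted model at arbitrary uptake fractions: annual total
#' savings per condition, or, if `years` is given, the present value over
#' that many years at the model's discount rate.
#'
#' @param object A [coi_model()].
#' @param uptake Vector of uptake fractions in `[0, 1]`.
#' @param years Optional horizon in years; `NULL` (default) returns
#'   annual values.
#' @param ... Unused.
#' @return A data.frame with `condition`, `uptake`, `central`, `lower`,
#'   `upper` (AUD million).
#' @examples
#' fit <- run_pipeline(coi_example_config())
#' predict(fit, uptake = c(0.25, 0.75))
#' @export
predict.coi_model <- function(object, uptake = 1, years = NULL, ...) {
  if (any(uptake < 0) || any(uptake > 1)) {
    stop("'uptake' must lie in [0, 1]", call. = FALSE)
  }
  out <- NULL
  for (cond in names(object$outcomes)) {
    o <- object$outcomes[[cond]]
    for (u in uptake) {
      cell <- compute_savings(o$expenditure, o$reduction, u)$total
      if (!is.null(years)) {
        cell <- horizon_total(cell, object$discount, years)
      }
      out <- rbind(out, data.frame(
        condition = cond, uptake = u, central = cell$central,
        lower = cell$lower, upper = cell$upper, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Plot annual savings totals per scenario
#'
#' Bar chart of the annual total savings per scenario for each condition,
#' with 95% CI whiskers; one panel per condition.
#'
#' @param x A [coi_model()].
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, `x`.
#' @export
plot.coi_model <- function(x, ...) {
  conds <- names(x$outcomes)
  old <- graphics::par(mfrow = c(1, length(conds)))
  on.exit(graphics::par(old))
  for (cond in conds) {
    cells <- x$annual[[cond]]
    central <- vapply(cells, function(r) r$total$central, numeric(1))
    lower <- vapply(cells, function(r) r$total$lower, numeric(1))
    upper <- vapply(cells, function(r) r$total$upper, numeric(1))
    mid <- graphics::barplot(central, names.arg = names(cells),
                             ylim = c(0, max(upper) * 1.1),
                             ylab = "Annual savings (AUD million)",
                             main = cond, las = 2, ...)
    graphics::arrows(mid, lower, mid, upper, angle = 90, code = 3,
                     length = 0.04)
  }
  invisible(x)
}
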