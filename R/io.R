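#' Read / write an expenditure table as CSV
#'
#' The on-disk format is a two-column CSV with header `category,amount`
#' (amounts in AUD million); the condition and year are supplied by the
#' caller or a surrounding config file, not stored in the CSV.
#'
#' @param path File path.
#' @param condition,year Labels attached to the table on read.
#' @return [read_expenditure_csv()] returns an [expenditure_table()];
#'   [write_expenditure_csv()] returns the path, invisibly.
#' @export
read_expenditure_csv <- function(path, condition = "unspecified",
                                 year = NA) {
  if (!file.exists(path)) {
    stop(sprintf("expenditure file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("category", "amount") %in% names(df))) {
    stop(sprintf("%s: expected CSV header 'category,amount'", path),
         call. = FALSE)
  }
  expenditure_table(condition, year, df$category, df$amount)
}

#' @param table An [expenditure_table()] to write.
#' @rdname read_expenditure_csv
#' @export
write_expenditure_csv <- function(table, path) {
  stopifnot(inherits(table, "expenditure_table"))
  utils::write.csv(table$table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Path to the bundled Australian cancer analysis config
#'
#' The package ships its worked example as plain-text fixtures: the pooled
#' dose-response RRs for colorectal cancer and total cancer mortality, the
#' 21 -> 48 g/day intake gap, the four uptake scenarios with 7%%
#' discounting, and the AIHW direct health expenditure tables for both
#' conditions in 2015-16 and 2020 prices.
#'
#' @return Path to the YAML config file.
#' @examples
#' cfg <- read_coi_config(coi_example_config())
#' names(cfg$outcomes)
#' @export
coi_example_config <- function() {
  system.file("extdata", "australia_cancer.yaml", package = "grainCOI",
              mustWork = TRUE)
}

#' Read an analysis configuration
#'
#' Loads a YAML config describing a full cost-of-illness analysis:
#' intakes, one block per outcome (RR with CI, reference dose, paths to
#' expenditure CSVs), the scenario schedule, the discount rate and option
#' flags. Relative expenditure paths are resolved against the config
#' file's directory. Validation is exhaustive: every problem found is
#' reported, not just the first.
#'
#' @param path Path to the YAML file.
#' @return A list of class `"coi_config"` with parsed, validated
#'   components: `gap`, `outcomes` (each with `rr`, `expenditure`,
#'   optionally `expenditure_base`, and `report_digits`), `schedule`,
#'   `discount`, `options`.
#' @export
read_coi_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  # intakes
  gap <- NULL
  it <- raw$intakes
  if (is.null(it) || !num(it$current) || !num(it$target)) {
    note("intakes: 'current' and 'target' (g/day) are required numbers")
  } else if (it$current < 0 || it$target < 0) {
    note("intakes: intakes must be non-negative")
  } else {
    ratio <- if (num(it$product_to_content_ratio)) {
      it$product_to_content_ratio
    } else 30 / 16
    gap <- intake_gap(it$current, it$target, ratio)
    if (gap$gap < 0) note("intakes: target below current (negative gap)")
  }

  # outcomes
  outcomes <- list()
  if (is.null(raw$outcomes) || length(raw$outcomes) == 0L) {
    note("outcomes: at least one outcome block is required")
  } else {
    for (i in seq_along(raw$outcomes)) {
      o <- raw$outcomes[[i]]
      where <- sprintf("outcomes[%d]", i)
      if (is.null(o$condition)) {
        note(sprintf("%s: 'condition' label missing", where))
        next
      }
      ok <- TRUE
      for (f in c("rr", "ci_lower", "ci_upper", "dose_g")) {
        if (!num(o[[f]])) {
          note(sprintf("%s (%s): numeric '%s' missing", where, o$condition, f))
          ok <- FALSE
        }
      }
      if (ok && !(o$ci_lower <= o$rr && o$rr <= o$ci_upper)) {
        note(sprintf("%s (%s): CI must bracket the RR", where, o$condition))
        ok <- FALSE
      }
      if (is.null(o$expenditure)) {
        note(sprintf("%s (%s): 'expenditure' CSV path missing", where,
                     o$condition))
        ok <- FALSE
      }
      if (!ok) next
      resolve <- function(p) {
        if (file.exists(p)) p else file.path(base_dir, p)
      }
      exp_path <- resolve(o$expenditure)
      if (!file.exists(exp_path)) {
        note(sprintf("%s (%s): expenditure file not found: %s", where,
                     o$condition, o$expenditure))
        next
      }
      rec <- list(
        rr = dose_response_rr(
          if (is.null(o$outcome)) o$condition else o$outcome,
          o$rr, o$ci_lower, o$ci_upper, o$dose_g,
          if (num(o$n_studies)) o$n_studies else NA_integer_),
        expenditure = read_expenditure_csv(
          exp_path, o$condition,
          if (is.null(o$year)) NA else o$year),
        report_digits = if (num(o$report_digits)) o$report_digits else 2
      )
      if (!is.null(o$expenditure_base)) {
        bp <- resolve(o$expenditure_base)
        if (!file.exists(bp)) {
          note(sprintf("%s (%s): base expenditure file not found: %s", where,
                       o$condition, o$expenditure_base))
        } else {
          rec$expenditure_base <- read_expenditure_csv(
            bp, o$condition,
            if (is.null(o$base_year)) NA else o$base_year)
        }
      }
      outcomes[[o$condition]] <- rec
    }
  }

  # scenarios
  schedule <- NULL
  sc <- raw$scenarios
  if (is.null(sc) || is.null(sc$blocks) || length(sc$blocks) == 0L) {
    note("scenarios: at least one block (name, uptake) is required")
  } else {
    bl <- if (num(sc$block_length)) sc$block_length else 5
    hz <- if (num(sc$horizon)) sc$horizon else 20
    scen <- list()
    for (i in seq_along(sc$blocks)) {
      b <- sc$blocks[[i]]
      if (is.null(b$name) || !num(b$uptake)) {
        note(sprintf("scenarios.blocks[%d]: 'name' and numeric 'uptake' required", i))
      } else if (b$uptake < 0 || b$uptake > 1) {
        note(sprintf("scenarios.blocks[%d] (%s): uptake %g outside [0, 1]",
                     i, b$name, b$uptake))
      } else {
        scen[[length(scen) + 1L]] <- scenario(b$name, b$uptake, i - 1L)
      }
    }
    if (length(scen) == length(sc$blocks)) {
      schedule <- tryCatch(scenario_schedule(scen, bl, hz),
                           error = function(e) {
                             note(paste0("scenarios: ", conditionMessage(e)))
                             NULL
                           })
    }
  }

  # discount
  discount <- NULL
  if (is.null(raw$discount) || !num(raw$discount$rate)) {
    note("discount: numeric 'rate' is required")
  } else {
    discount <- tryCatch(discount_spec(raw$discount$rate),
                         error = function(e) {
                           note(paste0("discount: ", conditionMessage(e)))
                           NULL
                         })
  }

  opts <- raw$options
  scaling <- if (!is.null(opts$scaling)) opts$scaling else "linear"
  if (!scaling %in% c("linear", "loglinear")) {
    note(sprintf("options: unknown scaling '%s' (use linear or loglinear)",
                 scaling))
  }

  if (length(problems) > 0L) {
    stop(sprintf("invalid config %s:\n%s", path,
                 paste0("  - ", problems, collapse = "\n")), call. = FALSE)
  }

  structure(
    list(gap = gap, outcomes = outcomes, schedule = schedule,
         discount = discount,
         options = list(scaling = scaling,
                        strict_content_units =
                          isTRUE(opts$strict_content_units))),
    class = "coi_config"
  )
}

#' Run the full cost-of-illness pipeline from a config
#'
#' Convenience wrapper: [read_coi_config()] the file (or take an already
#' parsed config) and fit the model with [coi_model()].
#'
#' @param config Path to a YAML config, or a `"coi_config"` object.
#' @return A [coi_model()] object.
#' @examples
#' fit <- run_pipeline(coi_example_config())
#' coef(fit)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_coi_config(config)
  stopifnot(inherits(config, "coi_config"))
  coi_model(
    rr = lapply(config$outcomes, `[[`, "rr"),
    expenditure = lapply(config$outcomes, `[[`, "expenditure"),
    gap = config$gap,
    schedule = config$schedule,
    discount = config$discount,
    scaling = config$options$scaling,
    strict_content_units = config$options$strict_content_units,
    report_digits = vapply(config$outcomes, `[[`, numeric(1), "report_digits")
  )
}
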