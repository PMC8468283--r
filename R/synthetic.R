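#' Specification for synthetic model inputs
#'
#' Controls the randomized generation of structurally valid inputs —
#' expenditure tables, dose-response relative risks, intake gaps, uptake
#' sets and discount rates — so every stage of the model can be
#' property-tested without real data. One global seed drives all draws;
#' each generator derives its own sub-seed deterministically from it, so
#' adding a generator does not shift the streams of the others.
#'
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @param n_categories Number of expenditure categories.
#' @param amount_scale Median category amount, AUD million (amounts are
#'   log-normal around this, emulating the heavy-tailed spread of real
#'   expenditure categories).
#' @param rr_range Interval within `(0, 1.2]` for the central RR draw.
#' @param ci_halfwidth_range Interval for the CI half-width on the RR.
#' @param gap_range Interval for the intake gap, grams/day.
#' @param uptake_set Uptake fractions available to scenarios.
#' @param rate_range Interval for the discount rate.
#' @return An object of class `"synthetic_spec"`.
#' @examples
#' synthetic_spec(seed = 1)
#' @export
synthetic_spec <- function(seed, n_categories = 10, amount_scale = 100,
                           rr_range = c(0.7, 1.0),
                           ci_halfwidth_range = c(0.01, 0.1),
                           gap_range = c(5, 60),
                           uptake_set = c(0.05, 0.15, 0.5, 1.0),
                           rate_range = c(0.0, 0.1)) {
  stopifnot(length(seed) == 1L, is.numeric(seed),
            n_categories >= 1,
            length(rr_range) == 2L, rr_range[1] > 0, rr_range[2] <= 1.2,
            rr_range[1] <= rr_range[2],
            length(ci_halfwidth_range) == 2L, all(ci_halfwidth_range >= 0),
            ci_halfwidth_range[1] <= ci_halfwidth_range[2],
            length(gap_range) == 2L, all(gap_range >= 0),
            all(uptake_set >= 0), all(uptake_set <= 1),
            length(rate_range) == 2L, all(rate_range > -1))
  structure(
    list(seed = as.integer(seed), n_categories = as.integer(n_categories),
         amount_scale = amount_scale, rr_range = rr_range,
         ci_halfwidth_range = ci_halfwidth_range, gap_range = gap_range,
         uptake_set = uptake_set, rate_range = rate_range),
    class = "synthetic_spec"
  )
}

# Deterministic sub-seed per generator; keeps streams independent of the
# order in which generators are called. Kept below 2^31 - 1.
sub_seed <- function(spec, offset) {
  (spec$seed * 7919L + offset * 104729L) %% 2147483647L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic expenditure table
#'
#' Category amounts are drawn from a log-normal distribution (sdlog 1.5)
#' around `amount_scale`, emulating the heavy-tailed size spread of real
#' disease-expenditure categories, with auto-generated names.
#'
#' @param spec A [synthetic_spec()].
#' @param condition,year Labels for the generated table.
#' @return A valid [expenditure_table()].
#' @examples
#' generate_expenditure(synthetic_spec(seed = 1))
#' @export
generate_expenditure <- function(spec, condition = "synthetic condition",
                                 year = 2020) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(sub_seed(spec, 1L), {
    amounts <- stats::rlnorm(spec$n_categories,
                             meanlog = log(spec$amount_scale), sdlog = 1.5)
    expenditure_table(condition, year,
                      sprintf("category %02d", seq_len(spec$n_categories)),
                      amounts)
  })
}

#' Generate a synthetic dose-response relative risk
#'
#' The central RR is uniform on `rr_range`; CI half-widths are drawn
#' independently for each side from `ci_halfwidth_range` (truncated so the
#' lower bound stays positive), guaranteeing the bound ordering
#' `lower <= central <= upper`.
#'
#' @param spec A [synthetic_spec()].
#' @param outcome Label for the generated record.
#' @return A valid [dose_response_rr()] anchored at 90 g/day.
#' @examples
#' generate_rr(synthetic_spec(seed = 1))
#' @export
generate_rr <- function(spec, outcome = "synthetic outcome") {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(sub_seed(spec, 2L), {
    rr <- stats::runif(1, spec$rr_range[1], spec$rr_range[2])
    hw <- stats::runif(2, spec$ci_halfwidth_range[1],
                       spec$ci_halfwidth_range[2])
    lower <- max(rr - hw[1], rr / 2, .Machine$double.eps)
    dose_response_rr(outcome, rr, lower, rr + hw[2], dose = 90,
                     n_studies = sample(3:20, 1))
  })
}

#' Generate a full synthetic input bundle
#'
#' Draws an expenditure table, an RR record, an intake gap, a scenario
#' schedule built from `uptake_set` (sorted increasing) and a discount
#' rate — everything needed for an end-to-end model run.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `expenditure`, `rr`, `gap` (an
#'   [intake_gap()]), `schedule` and `discount`.
#' @examples
#' b <- generate_bundle(synthetic_spec(seed = 1))
#' names(b)
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gap_discount <- with_seed(sub_seed(spec, 3L), {
    list(gap = stats::runif(1, spec$gap_range[1], spec$gap_range[2]),
         rate = stats::runif(1, spec$rate_range[1], spec$rate_range[2]))
  })
  uptakes <- sort(unique(spec$uptake_set))
  scen <- lapply(seq_along(uptakes), function(i) {
    scenario(sprintf("scenario %d", i), uptakes[i], i - 1L)
  })
  list(
    expenditure = generate_expenditure(spec),
    rr = generate_rr(spec),
    gap = intake_gap(0, gap_discount$gap),
    schedule = scenario_schedule(scen, block_length = 5,
                                 horizon = 5 * length(scen)),
    discount = discount_spec(gap_discount$rate)
  )
}

#' Write a synthetic input bundle to a directory
#'
#' Emits a config file plus expenditure CSV readable back through
#' [read_coi_config()], so synthetic data can exercise the full I/O path.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path to the written config file.
#' @export
write_synthetic_bundle <- function(spec, dir) {
  bundle <- generate_bundle(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "synthetic_expenditure.csv")
  write_expenditure_csv(bundle$expenditure, csv)
  cfg <- list(
    intakes = list(current = bundle$gap$current_intake,
                   target = bundle$gap$target_intake,
                   product_to_content_ratio = bundle$gap$product_to_content_ratio),
    outcomes = list(list(
      condition = bundle$expenditure$condition,
      outcome = bundle$rr$outcome,
      rr = bundle$rr$rr_central, ci_lower = bundle$rr$rr_lower,
      ci_upper = bundle$rr$rr_upper, dose_g = bundle$rr$reference_dose,
      n_studies = bundle$rr$n_studies,
      expenditure = "synthetic_expenditure.csv",
      year = bundle$expenditure$year, report_digits = 2
    )),
    scenarios = list(
      block_length = bundle$schedule$block_length,
      horizon = bundle$schedule$horizon,
      blocks = lapply(bundle$schedule$scenarios, function(s) {
        list(name = s$name, uptake = s$uptake)
      })
    ),
    discount = list(rate = bundle$discount$rate),
    options = list(scaling = "linear", strict_content_units = FALSE)
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
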