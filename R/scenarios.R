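#' Population-uptake scenario
#'
#' A named uptake fraction bound to one block of a multi-year horizon
#' (block 0 spans years 0 to `block_length - 1`, and so on).
#'
#' @param name Scenario label, e.g. `"optimistic"`.
#' @param uptake Fraction of the population adopting the target intake,
#'   in `[0, 1]`.
#' @param block_index Non-negative integer block position.
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(name, uptake, block_index) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(uptake) || length(uptake) != 1L || is.na(uptake) ||
      uptake < 0 || uptake > 1) {
    stop(sprintf("uptake must be a fraction in [0, 1] (got %s)", uptake),
         call. = FALSE)
  }
  if (!is.numeric(block_index) || block_index < 0 ||
      block_index != round(block_index)) {
    stop("block_index must be a non-negative integer", call. = FALSE)
  }
  structure(list(name = name, uptake = uptake,
                 block_index = as.integer(block_index)),
            class = "scenario")
}

#' Scenario schedule over a planning horizon
#'
#' An ordered set of [scenario()]s, each occupying one block of
#' `block_length` years within a `horizon`-year planning period. Used both
#' to tabulate savings per scenario and to drive the staged
#' incremental-adoption total, where each successive scenario occupies the
#' next block.
#'
#' @param scenarios List of [scenario()] objects with distinct block
#'   indices.
#' @param block_length Years per block (default 5).
#' @param horizon Total planning horizon in years (default 20).
#' @return An object of class `"scenario_schedule"`.
#' @seealso [default_schedule()]
#' @export
scenario_schedule <- function(scenarios, block_length = 5, horizon = 20) {
  stopifnot(is.list(scenarios), length(scenarios) > 0L)
  ok <- vapply(scenarios, inherits, logical(1), what = "scenario")
  if (!all(ok)) stop("'scenarios' must be a list of scenario objects",
                     call. = FALSE)
  idx <- vapply(scenarios, `[[`, integer(1), "block_index")
  if (anyDuplicated(idx)) {
    stop("block indices must be unique within a schedule", call. = FALSE)
  }
  if (block_length < 1 || horizon < 1) {
    stop("'block_length' and 'horizon' must be positive", call. = FALSE)
  }
  if (block_length * length(scenarios) > horizon) {
    stop("schedule does not fit: block_length * n_scenarios exceeds horizon",
         call. = FALSE)
  }
  structure(list(scenarios = scenarios[order(idx)],
                 block_length = block_length, horizon = horizon),
            class = "scenario_schedule")
}

#' The four standard uptake scenarios
#'
#' Very pessimistic (5%), pessimistic (15%), optimistic (50%) and
#' universal (100%) population uptake of the target intake, bound to
#' consecutive 5-year blocks of a 20-year horizon: years 0-4, 5-9, 10-14
#' and 15-19 respectively.
#'
#' @return A [scenario_schedule()] with uptakes 0.05, 0.15, 0.50, 1.00.
#' @examples
#' default_schedule()
#' @export
default_schedule <- function() {
  scenario_schedule(list(
    scenario("very pessimistic", 0.05, 0L),
    scenario("pessimistic", 0.15, 1L),
    scenario("optimistic", 0.50, 2L),
    scenario("universal", 1.00, 3L)
  ), block_length = 5, horizon = 20)
}

#' Year range covered by one block of a schedule
#'
#' @param schedule A [scenario_schedule()].
#' @param block_index Block position, 0-based.
#' @return Integer vector `c(first_year, last_year)` (closed range).
#' @export
block_years <- function(schedule, block_index) {
  stopifnot(inherits(schedule, "scenario_schedule"))
  first <- block_index * schedule$block_length
  c(first, first + schedule$block_length - 1L)
}

#' @export
print.scenario_schedule <- function(x, ...) {
  cat(sprintf("Scenario schedule: %d blocks of %d years, %d-year horizon\n",
              length(x$scenarios), x$block_length, x$horizon))
  for (s in x$scenarios) {
    yr <- block_years(x, s$block_index)
    cat(sprintf("  %-18s uptake %5.1f%%  years %d-%d\n",
                s$name, 100 * s$uptake, yr[1], yr[2]))
  }
  invisible(x)
}
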