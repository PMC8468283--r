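test_that("discount factors follow (1+r)^(-n) with year 0 undiscounted", {
  spec <- discount_spec(0.07)
  expect_equal(discount_factor(spec, 0), 1)
  expect_equal(discount_factor(spec, 1), 1 / 1.07)
  expect_equal(discount_factor(discount_spec(0), 0:30), rep(1, 31))
  expect_error(discount_factor(spec, -1), "non-negative")
  expect_error(discount_spec(-1.5), "> -1")
})

test_that("block sums equal a naive year-by-year accumulation", {
  set.seed(7)
  for (i in 1:200) {
    rate <- runif(1, 0, 0.15)
    first <- sample(0:20, 1)
    last <- first + sample(0:10, 1)
    annual <- runif(1, 0.1, 500)
    cell <- savings_cell(annual, 0.8 * annual, 1.2 * annual)
    got <- block_sum(cell, discount_spec(rate), first, last)
    # independent oracle: explicit loop over years
    acc <- 0
    for (n in first:last) acc <- acc + annual / (1 + rate)^n
    expect_equal(got$central, acc, tolerance = 1e-12)
    expect_equal(got$lower, 0.8 * acc, tolerance = 1e-12)
  }
})

test_that("an undiscounted 5-year block is five times the annual value", {
  cell <- savings_cell(10, 8, 12)
  got <- block_sum(cell, discount_spec(0), 0, 4)
  expect_equal(cell_vec(got), 5 * cell_vec(cell))
  expect_error(block_sum(cell, discount_spec(0.07), 4, 0), "not exceed")
})

test_that("a one-year horizon returns the annual value unchanged", {
  cell <- savings_cell(37.17, 24.05, 48.11)
  expect_equal(cell_vec(horizon_total(cell, discount_spec(0.07), 1)),
               cell_vec(cell))
  expect_error(horizon_total(cell, discount_spec(0.07), 0), ">= 1")
})

test_that("block sums strictly decrease for later blocks at positive rates", {
  cell <- savings_cell(100, 80, 120)
  spec <- discount_spec(0.07)
  sched <- default_schedule()
  vals <- vapply(0:3, function(b) {
    yr <- block_years(sched, b)
    block_sum(cell, spec, yr[1], yr[2])$central
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("as the rate vanishes the horizon total approaches n x annual", {
  cell <- savings_cell(10, 8, 12)
  for (rate in c(1e-4, 1e-6, 1e-8)) {
    got <- horizon_total(cell, discount_spec(rate), 20)
    expect_equal(got$central, 200, tolerance = 100 * rate)
  }
  expect_equal(horizon_total(cell, discount_spec(0), 20)$central, 200)
})

test_that("a single scenario occupying all blocks matches the horizon total", {
  cell <- savings_cell(37.174, 24.054, 48.107)
  sched <- scenario_schedule(
    lapply(0:3, function(i) scenario(paste("s", i), 0.5, i)))
  same <- setNames(rep(list(cell), 4),
                   vapply(sched$scenarios, `[[`, character(1), "name"))
  inc <- incremental_total(same, sched, discount_spec(0.07))
  hor <- horizon_total(cell, discount_spec(0.07), 20)
  expect_equal(inc$central, hor$central, tolerance = 1e-9)
  expect_equal(inc$lower, hor$lower, tolerance = 1e-9)
  expect_equal(inc$upper, hor$upper, tolerance = 1e-9)
})

test_that("incremental totals validate the schedule and scenario coverage", {
  sched <- default_schedule()
  names_ <- vapply(sched$scenarios, `[[`, character(1), "name")
  zeros <- setNames(rep(list(savings_cell(0, 0, 0)), 4), names_)
  expect_equal(cell_vec(incremental_total(zeros, sched, discount_spec(0.07))),
               c(0, 0, 0))
  expect_error(
    incremental_total(zeros[-1], sched, discount_spec(0.07)), "missing")
  # blocks must tile the horizon
  short <- scenario_schedule(list(scenario("only", 0.5, 0L)),
                             block_length = 5, horizon = 20)
  expect_error(incremental_total(zeros, short, discount_spec(0.07)), "tile")
})
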