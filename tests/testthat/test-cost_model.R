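test_that("expenditure tables validate amounts and derive the total", {
  tab <- expenditure_table("demo", 2020, c("a", "b", "c"), c(1, 2, 3.5))
  expect_equal(tab$total, 6.5)
  expect_error(expenditure_table("demo", 2020, "a", -1), "non-negative")
  expect_error(expenditure_table("demo", 2020, c("a", "a"), c(1, 2)),
               "unique")
  expect_error(expenditure_table("demo", 2020, character(0), numeric(0)),
               "non-empty")
})

test_that("inflation scales every category, preserves names, and round-trips", {
  tab <- generate_expenditure(synthetic_spec(seed = 7))
  expect_identical(inflate(tab, 1)$table, tab$table)
  up <- inflate(tab, 1.1384, year = 2020)
  expect_equal(up$table$amount, tab$table$amount * 1.1384)
  expect_identical(up$table$category, tab$table$category)
  expect_equal(up$year, 2020)
  back <- inflate(up, 1 / 1.1384)
  expect_equal(back$table$amount, tab$table$amount)
  expect_error(inflate(tab, 0), "positive")
  expect_error(inflate(tab, -2), "positive")
})

test_that("the bundled base-year tables inflate onto the current-year columns", {
  cfg <- read_coi_config(coi_example_config())
  crc <- cfg$outcomes[["colorectal cancer"]]
  factor <- crc$expenditure$total / crc$expenditure_base$total
  expect_equal(factor, 728.9 / 640.3)
  # aggregate CPI factor reproduces each current-year CRC category; both
  # columns are printed to 0.1, so half a display unit propagates from each
  implied <- inflate(crc$expenditure_base, factor)
  expect_true(all(abs(implied$table$amount - crc$expenditure$table$amount)
                  <= 0.05 * (1 + factor)))
})

test_that("annual savings match the published colorectal-cancer totals", {
  red <- scale_risk_reduction(crc_rr(), adult_gap())
  tab <- read_coi_config(coi_example_config())$outcomes[[
    "colorectal cancer"]]$expenditure
  rep_u <- compute_savings(tab, red, uptake = 1)
  expect_equal(cell_vec(rep_u$total), c(37.17, 24.05, 48.11),
               tolerance = 0.0002)
  pbs <- rep_u$per_category[rep_u$per_category$category ==
                              "Pharmaceutical benefits scheme", ]
  expect_equal(pbs$central, 6.61, tolerance = 0.001)
  # totals equal the sum of unrounded category cells
  expect_equal(rep_u$total$central, sum(rep_u$per_category$central))
})

test_that("uptake zero yields all-zero savings and invalid uptakes error", {
  tab <- generate_expenditure(synthetic_spec(seed = 3))
  red <- scale_risk_reduction(generate_rr(synthetic_spec(seed = 3)), 27)
  rep0 <- compute_savings(tab, red, uptake = 0)
  expect_true(all(rep0$per_category$central == 0))
  expect_equal(cell_vec(rep0$total), c(0, 0, 0))
  expect_error(compute_savings(tab, red, uptake = 1.2), "\\[0, 1\\]")
  expect_error(compute_savings(tab, red, uptake = -0.1), "\\[0, 1\\]")
})

test_that("savings are homogeneous in uptake and amounts, and additive", {
  set.seed(99)
  for (i in 1:50) {
    tab <- generate_expenditure(synthetic_spec(seed = 1000 + i))
    red <- scale_risk_reduction(generate_rr(synthetic_spec(seed = 2000 + i)),
                                runif(1, 0, 60))
    u <- runif(1, 0, 0.5)
    a <- compute_savings(tab, red, u)
    b <- compute_savings(tab, red, 2 * u)
    expect_equal(b$total$central, 2 * a$total$central)
    doubled <- expenditure_table(tab$condition, tab$year,
                                 tab$table$category, 2 * tab$table$amount)
    expect_equal(compute_savings(doubled, red, u)$total$central,
                 2 * a$total$central)
    # additivity: one summed category gives the same total
    lumped <- expenditure_table(tab$condition, tab$year, "all", tab$total)
    expect_equal(compute_savings(lumped, red, u)$total$central,
                 a$total$central)
    expect_true(a$total$lower <= a$total$central &&
                  a$total$central <= a$total$upper)
  }
})

test_that("a negative risk reduction produces a cost-increase warning", {
  tab <- generate_expenditure(synthetic_spec(seed = 5))
  harmful <- dose_response_rr("harmful", 1.1, 1.05, 1.2, 90)
  red <- suppressWarnings(scale_risk_reduction(harmful, 27))
  expect_warning(rep <- compute_savings(tab, red, 0.5), "increase")
  expect_lt(rep$total$central, 0)
})
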