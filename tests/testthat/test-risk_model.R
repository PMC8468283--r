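test_that("intake gap is the simple difference of target and current", {
  expect_equal(intake_gap(21, 48)$gap, 27)
  expect_equal(intake_gap(48, 48)$gap, 0)
  expect_equal(intake_gap(17, 48)$gap, 31)  # children's median as alt population
  expect_error(intake_gap(-1, 48), "non-negative")
  expect_error(intake_gap(21, -5), "non-negative")
})

test_that("dose-response RR constructor enforces its invariants", {
  expect_error(dose_response_rr("x", 0.83, 0.9, 0.95, 90), "lower <= rr")
  expect_error(dose_response_rr("x", 0.83, -0.1, 0.9, 90), "positive")
  expect_error(dose_response_rr("x", 0.83, 0.78, 0.89, 0), "dose")
  rr <- crc_rr()
  expect_s3_class(rr, "dose_response_rr")
  expect_equal(rr$n_studies, 6L)
})

test_that("linear scaling reproduces the published percent risk reductions", {
  red_crc <- scale_risk_reduction(crc_rr(), adult_gap())
  expect_equal(100 * red_crc$central, 5.1)
  expect_equal(100 * red_crc$lower, 3.3)
  expect_equal(100 * red_crc$upper, 6.6)

  red_tc <- scale_risk_reduction(total_cancer_rr(), adult_gap())
  expect_equal(100 * red_tc$central, 4.5)
  expect_equal(100 * red_tc$lower, 2.7)
  expect_equal(100 * red_tc$upper, 6.0)
})

test_that("a null-effect RR yields a zero reduction with zero-width CI", {
  rr <- dose_response_rr("null", 1, 1, 1, 90)
  red <- scale_risk_reduction(rr, 40)
  expect_equal(cell_vec(red), c(0, 0, 0))
})

test_that("gap equal to the reference dose recovers 1 - RR exactly", {
  red <- scale_risk_reduction(crc_rr(), 90)
  expect_identical(red$central, 1 - 0.83)
  expect_identical(red$lower, 1 - 0.89)
  expect_identical(red$upper, 1 - 0.78)
})

test_that("scaling is linear in the gap and preserves bound ordering", {
  set.seed(42)
  for (i in 1:200) {
    rr <- generate_rr(synthetic_spec(seed = i))
    g <- runif(1, 0, 90)
    r1 <- scale_risk_reduction(rr, g)
    # doubling may extrapolate past the reference dose, which warns by design
    r2 <- suppressWarnings(scale_risk_reduction(rr, 2 * g))
    expect_equal(r2$central, 2 * r1$central)
    expect_equal(r2$lower, 2 * r1$lower)
    expect_true(r1$lower <= r1$central && r1$central <= r1$upper)
  }
})

test_that("log-linear scaling agrees with linear to first order", {
  # max |(1-r)t - (1-r^t)| over r in [0.8, 1], t in [0, 0.5] sits at the
  # corner r = 0.8, t = 0.5: 1 - sqrt(0.8) - 0.1 = 0.005573
  worst <- 1 - sqrt(0.8) - 0.1
  for (rr_val in seq(0.80, 1.00, by = 0.02)) {
    for (frac in c(0.1, 0.3, 0.5)) {
      rr <- dose_response_rr("x", rr_val, rr_val, rr_val, dose = 90)
      lin <- scale_risk_reduction(rr, 90 * frac, scaling = "linear")
      log <- scale_risk_reduction(rr, 90 * frac, scaling = "loglinear")
      expect_lte(abs(lin$central - log$central), worst + 1e-12)
    }
  }
  # well inside the domain the two modes agree to under half a percent point
  rr <- dose_response_rr("x", 0.85, 0.85, 0.85, dose = 90)
  lin <- scale_risk_reduction(rr, 27, scaling = "linear")
  log <- scale_risk_reduction(rr, 27, scaling = "loglinear")
  expect_lt(abs(lin$central - log$central), 0.005)
})

test_that("strict content-unit scaling divides by the content-equivalent dose", {
  red <- scale_risk_reduction(crc_rr(), adult_gap(),
                              strict_content_units = TRUE)
  expect_equal(red$scaling_dose, 48)          # 90 g product = 48 g content
  expect_equal(red$central, 0.17 * 27 / 48)
})

test_that("out-of-range inputs are flagged, not silently accepted", {
  expect_warning(scale_risk_reduction(crc_rr(), 120), "extrapolation")
  harmful <- dose_response_rr("harmful", 1.1, 1.05, 1.2, 90)
  expect_warning(red <- scale_risk_reduction(harmful, 27), "harmful")
  expect_true(red$harmful)
  expect_lt(red$central, 0)
  expect_error(scale_risk_reduction(crc_rr(), -5), "non-negative")
})
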