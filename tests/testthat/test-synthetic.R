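test_that("identical spec and seed give identical synthetic inputs", {
  s <- synthetic_spec(seed = 1, n_categories = 10)
  expect_identical(generate_expenditure(s), generate_expenditure(s))
  expect_identical(generate_rr(s), generate_rr(s))
  b1 <- generate_bundle(s)
  b2 <- generate_bundle(s)
  expect_identical(b1$expenditure$table, b2$expenditure$table)
  expect_identical(b1$gap$gap, b2$gap$gap)
  expect_identical(b1$discount$rate, b2$discount$rate)
  # different seeds diverge
  expect_false(identical(
    generate_expenditure(synthetic_spec(seed = 2))$table$amount,
    generate_expenditure(s)$table$amount))
})

test_that("generated inputs always satisfy the type validators", {
  for (seed in 1:100) {
    s <- synthetic_spec(seed = seed, n_categories = sample(1:15, 1))
    tab <- generate_expenditure(s)
    expect_true(all(tab$table$amount > 0))
    expect_equal(tab$total, sum(tab$table$amount))
    rr <- generate_rr(s)
    expect_true(rr$rr_lower > 0 && rr$rr_lower <= rr$rr_central &&
                  rr$rr_central <= rr$rr_upper)
  }
})

test_that("a single-category table's total is the single amount", {
  tab <- generate_expenditure(synthetic_spec(seed = 2, n_categories = 1))
  expect_equal(tab$total, tab$table$amount)
})

test_that("a degenerate CI half-width collapses the RR interval", {
  s <- synthetic_spec(seed = 9, ci_halfwidth_range = c(0, 0))
  rr <- generate_rr(s)
  expect_equal(rr$rr_lower, rr$rr_central)
  expect_equal(rr$rr_upper, rr$rr_central)
})

test_that("sub-seeded generators are insensitive to call order", {
  s <- synthetic_spec(seed = 11)
  rr_first <- generate_rr(s)
  generate_expenditure(s)
  expect_identical(generate_rr(s), rr_first)
})

test_that("any synthetic bundle runs end to end with ordered savings cells", {
  for (seed in 1:25) {
    b <- generate_bundle(synthetic_spec(seed = seed))
    fit <- coi_model(b$rr, b$expenditure, gap = b$gap,
                     schedule = b$schedule, discount = b$discount)
    for (rep in fit$annual[[1]]) {
      expect_true(rep$total$lower <= rep$total$central &&
                    rep$total$central <= rep$total$upper)
    }
    inc <- fit$incremental[[1]]
    expect_true(inc$lower <= inc$central && inc$central <= inc$upper)
  }
})

test_that("a written synthetic bundle reloads through the config reader", {
  dir <- withr::local_tempdir()
  path <- write_synthetic_bundle(synthetic_spec(seed = 4), dir)
  fit <- run_pipeline(path)
  expect_s3_class(fit, "coi_model")
  b <- generate_bundle(synthetic_spec(seed = 4))
  expect_equal(fit$outcomes[[1]]$expenditure$total, b$expenditure$total)
  expect_equal(fit$discount$rate, b$discount$rate)
})
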