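test_that("discounting follows the annual end-of-period convention", {
  expect_equal(discounted_years(10, 0), 10.0)
  expect_equal(discounted_years(10, 0.03), (1 - 1.03^-10) / 0.03,
               tolerance = 1e-12)
  expect_equal(discounted_years(10, 0.03), 8.5302, tolerance = 1e-4)
  expect_equal(discounted_years(0.5, 0.03), 0.5 / 1.03, tolerance = 1e-12)
  expect_equal(discounted_years(0, 0.03), 0)
  expect_error(discounted_years(-1, 0.03), ">= 0")
  # against the explicit year-by-year oracle
  set.seed(21)
  for (i in 1:25) {
    T_years <- runif(1, 0, 40)
    r <- runif(1, 0, 0.1)
    expect_equal(discounted_years(T_years, r), oracle_discounted(T_years, r),
                 tolerance = 1e-10)
  }
  # discounted years never exceed the horizon, equality only at rate 0
  T_years <- runif(20, 0.5, 40)
  expect_true(all(discounted_years(T_years, 0.03) < T_years))
  expect_equal(discounted_years(T_years, 0), T_years)
})

test_that("truncated-normal lifespan draws honor the model", {
  m <- life_expectancy_model()
  # deterministic limit as the dispersion vanishes
  tight <- life_expectancy_model(sd = 1e-6)
  expect_equal(expected_remaining_years(62, "female", tight), 17.0,
               tolerance = 1e-4)
  set.seed(1); expect_equal(draw_remaining_years(62, "female", tight), 17.0,
                            tolerance = 1e-4)
  # reproducibility: same seed, same stream
  set.seed(99); a <- draw_remaining_years(rep(60, 50), rep("male", 50), m)
  set.seed(99); b <- draw_remaining_years(rep(60, 50), rep("male", 50), m)
  expect_identical(a, b)
  # 10,000 draws match the closed-form conditional moments
  set.seed(4)
  d <- draw_remaining_years(60, "male", m, n = 10000)
  mom <- trunc_norm_moments(75, 10, 60)
  expect_equal(mean(d), mom$mean - 60,
               tolerance = 3.5 * sqrt(mom$var / 10000) / (mom$mean - 60))
  expect_equal(expected_remaining_years(60, "male", m), mom$mean - 60,
               tolerance = 1e-12)
  # degenerate truncation
  expect_error(draw_remaining_years(140, "male", m), "degenerate")
  expect_error(expected_remaining_years(139.5, "female", m), "degenerate")
  expect_error(draw_remaining_years(60, "unknown", m), "male")
})

test_that("revision probability compounds per decade", {
  expect_equal(revision_prob(10, 0.05), 0.05, tolerance = 1e-12)
  expect_equal(revision_prob(20, 0.05), 1 - 0.95^2, tolerance = 1e-12)
  T_years <- seq(0, 60, by = 5)
  p <- revision_prob(T_years, 0.05)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p < 1))
})

test_that("QALY gain combines utility change, discounting and revision", {
  # no utility change, no gain, whatever the horizon
  expect_equal(qalys_gained(0.5, 0.5, 25)$qalys_gained, 0)
  # revision-neutral: exactly utility change times discounted years
  out <- qalys_gained(0.4, 0.7, 15, annual_rate = 0.03,
                      disutility_fraction = 0)
  expect_equal(out$qalys_gained, 0.3 * (1 - 1.03^-15) / 0.03,
               tolerance = 1e-12)
  expect_equal(out$qalys_gained, 3.5814, tolerance = 1e-4)
  # undiscounted, revision-neutral: utility change times the horizon
  expect_equal(qalys_gained(0.2, 0.6, 12, annual_rate = 0)$qalys_gained,
               0.4 * 12, tolerance = 1e-12)
})

test_that("QALY gain is monotone in horizon, gain, survival and discount", {
  base <- function(T_years = 15, du = 0.3, r = 0.03, p = 0.05, f = 1)
    qalys_gained(0.4, 0.4 + du, T_years, r, p, f)$qalys_gained
  expect_true(all(diff(sapply(c(5, 10, 15, 25), function(t) base(T_years = t))) > 0))
  expect_true(all(diff(sapply(c(0.1, 0.2, 0.3), function(d) base(du = d))) > 0))
  expect_true(all(diff(sapply(c(0.08, 0.05, 0.02), function(p) base(p = p))) > 0))
  expect_true(all(diff(sapply(c(0, 0.03, 0.06), function(r) base(r = r))) < 0))
})

test_that("cohort QALY engine joins records and respects the seed", {
  b <- generate_cohort(default_cohort_spec(seed = 77))
  cfg <- default_config(seed = 77)
  q1 <- compute_qalys(b$patients, b$womac, cfg)
  expect_equal(nrow(q1), nrow(b$patients))
  expect_true(all(q1$discounted_years < q1$remaining_years))
  expect_true(all(q1$qalys_gained > 0))  # post < pre is enforced upstream
  # Monte-Carlo mode is reproducible and close to the expectation mode
  cfg$simulation$n_draws_per_patient <- 200L
  q2 <- compute_qalys(b$patients, b$womac, cfg)
  q3 <- compute_qalys(b$patients, b$womac, cfg)
  expect_identical(q2, q3)
  expect_equal(mean(q2$qalys_gained), mean(q1$qalys_gained), tolerance = 0.02)
  expect_error(compute_qalys(b$patients, b$womac[-1, ], cfg), "missing WOMAC")
})
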