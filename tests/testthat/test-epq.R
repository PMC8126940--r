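test_that("subscale scores count keyed matches", {
  key <- epq_default_key()
  all_match <- key$keyed_answer
  expect_equal(unname(score_epq(all_match, key)), c(12L, 12L, 12L, 12L))
  none_match <- 1L - key$keyed_answer
  expect_equal(unname(score_epq(none_match, key)), c(0L, 0L, 0L, 0L))
  only_e <- make_sheet(e = 12)
  expect_equal(score_epq(only_e, key),
               c(extroversion = 12L, neuroticism = 0L, psychoticism = 0L,
                 lying = 0L))
  mixed <- make_sheet(e = 7, n = 3, p = 1, l = 11)
  expect_equal(unname(score_epq(mixed, key)), c(7L, 3L, 1L, 11L))
})

test_that("scoring validates sheet and key, naming offenders", {
  key <- epq_default_key()
  expect_error(score_epq(rep(1, 47), key), "48")
  bad <- key$keyed_answer
  bad[17] <- 2
  expect_error(score_epq(bad, key), "item.*17")
  badkey <- key
  badkey$subscale[5] <- "X"
  expect_error(score_epq(rep(1, 48), badkey), "unknown subscale")
  lopsided <- key
  lopsided$subscale[1] <- "N"
  expect_error(score_epq(rep(1, 48), lopsided), "exactly 12")
})

test_that("scoring is invariant to item permutation when the key travels", {
  key <- epq_default_key()
  ans <- make_sheet(e = 5, n = 9, p = 2, l = 6)
  set.seed(11)
  for (i in 1:5) {
    perm <- sample(48)
    expect_equal(score_epq(ans[perm], key[perm, ]), score_epq(ans, key))
  }
})

test_that("temperament quadrants follow the E/N cutoff rule", {
  expect_equal(as.character(classify_trait(12, 0)), "sanguine")
  expect_equal(as.character(classify_trait(0, 12)), "melancholic")
  expect_equal(as.character(classify_trait(7, 7)), "choleric")
  expect_equal(as.character(classify_trait(6, 6)), "phlegmatic")
  expect_error(classify_trait(13, 0), "0, 12")
})

test_that("classification partitions the score grid and is monotone in e_cut", {
  grid <- expand.grid(e = 0:12, n = 0:12)
  tr <- classify_trait(grid$e, grid$n)
  expect_false(any(is.na(tr)))
  expect_equal(length(tr), nrow(grid))
  # raising e_cut can only move patients from extroverted to introverted
  tr_hi <- classify_trait(grid$e, grid$n, e_cut = 9)
  moved <- tr != tr_hi
  expect_true(all(tr[moved] %in% c("choleric", "sanguine")))
  expect_true(all(tr_hi[moved] %in% c("melancholic", "phlegmatic")))
  # cohort-median mode uses the observed medians as cutoffs
  expect_equal(classify_trait(grid$e, grid$n, "median", "median"),
               classify_trait(grid$e, grid$n, 6, 6))
})

test_that("Cronbach's alpha matches closed forms and the covariance oracle", {
  set.seed(42)
  base <- rnorm(30)
  ident <- cbind(base, base, base)
  expect_equal(cronbach_alpha(ident)$alpha, 1.0, tolerance = 1e-12)
  # two items with covariance c and common variance v: alpha = 2c / (v + c)
  x2 <- cbind(base, 0.6 * base + rnorm(30, sd = 0.8))
  x2[, 1] <- x2[, 1] / sd(x2[, 1]); x2[, 2] <- x2[, 2] / sd(x2[, 2])
  cc <- cov(x2)[1, 2]
  expect_equal(cronbach_alpha(x2)$alpha, 2 * cc / (1 + cc), tolerance = 1e-10)
  # independent items in expectation have alpha near 0 at large n
  big <- matrix(rnorm(2000 * 6), ncol = 6)
  expect_lt(abs(cronbach_alpha(big)$alpha), 0.1)
  # agreement with the covariance-matrix oracle on random 5x5 matrices
  for (i in 1:20) {
    m <- matrix(rnorm(25), 5, 5)
    expect_equal(cronbach_alpha(m)$alpha, oracle_alpha(m), tolerance = 1e-10)
  }
})

test_that("alpha diagnostics and degenerate input", {
  set.seed(7)
  m <- matrix(rnorm(40), 10, 4)
  out <- cronbach_alpha(m)
  expect_length(out$alpha_drop, 4)
  for (j in 1:4)
    expect_equal(unname(out$alpha_drop[j]), oracle_alpha(m[, -j]),
                 tolerance = 1e-10)
  const <- matrix(1, 5, 3)
  expect_error(cronbach_alpha(const), "variance")
})

test_that("test-retest ICC agrees with the ANOVA mean-squares oracle", {
  set.seed(9)
  subj <- rnorm(20, sd = 3)
  perfect <- cbind(subj, subj)
  expect_equal(icc_test_retest(perfect)$icc, 1.0, tolerance = 1e-12)
  expect_true(icc_test_retest(perfect)$acceptable)
  noisy <- cbind(rnorm(200), rnorm(200))  # no subject effect at all
  expect_lt(abs(icc_test_retest(noisy)$icc), 0.2)
  hand <- cbind(c(9, 6, 8, 7), c(2, 1, 4, 1))
  expect_equal(icc_test_retest(hand)$icc, oracle_icc(hand), tolerance = 1e-10)
  for (i in 1:20) {
    m <- matrix(rnorm(10, sd = 2), 5, 2) + rnorm(5, sd = 3)
    expect_equal(icc_test_retest(m)$icc, oracle_icc(m), tolerance = 1e-10)
  }
  flat <- cbind(rep(1, 4), rep(1, 4))
  expect_error(icc_test_retest(flat), "variance")
})
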