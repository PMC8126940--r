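test_that("Pearson chi-square reproduces the published sex-by-trait value", {
  sex_tab <- rbind(male = c(26, 37, 14, 28), female = c(15, 33, 32, 26))
  out <- chi_square_test(sex_tab)
  expect_equal(out$statistic, 10.293, tolerance = 5e-4)
  expect_equal(out$df, 3)
  expect_lt(out$p_value, 0.05)
})

test_that("chi-square matches the margin oracle and handles degeneracy", {
  # proportional rows: exact independence, statistic 0
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chi_square_test(prop)$statistic, 0, tolerance = 1e-12)
  set.seed(14)
  for (i in 1:20) {
    m <- matrix(rpois(8, 20) + 1, 2, 4)
    o <- oracle_chisq(m)
    got <- chi_square_test(m)
    expect_equal(got$statistic, o$statistic, tolerance = 1e-10)
    expect_equal(got$df, o$df)
  }
  expect_error(chi_square_test(rbind(c(0, 0), c(3, 4))), "degenerate")
  expect_error(chi_square_test(matrix(5, 1, 3)), "2 x 2")
})

test_that("chi-square holds its nominal type-I error under independence", {
  set.seed(301)
  reps <- 2000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    rows <- sample(2, 200, replace = TRUE)
    cols <- sample(4, 200, replace = TRUE, prob = c(.2, .33, .22, .25))
    rej[i] <- chi_square_test(table(rows, cols))$p_value < 0.05
  }
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.065)
})

test_that("one-way ANOVA and Tukey HSD match the sums-of-squares oracle", {
  set.seed(23)
  # identical groups have F exactly 0
  v <- rnorm(10)
  expect_equal(anova_tukey(c(v, v), rep(c("a", "b"), each = 10))$f, 0,
               tolerance = 1e-12)
  for (i in 1:10) {
    g <- rep(letters[1:4], times = c(8, 12, 9, 11))
    y <- rnorm(length(g), mean = as.integer(factor(g)) * runif(1))
    got <- anova_tukey(y, g)
    o <- oracle_anova(y, g)
    expect_equal(got$f, o$f, tolerance = 1e-10)
    expect_equal(got$p_value, o$p_value, tolerance = 1e-10)
    expect_equal(got$pairwise$p_adj[match(o$comparison,
                                          got$pairwise$comparison)],
                 o$p_adj, tolerance = 1e-8)
  }
  expect_error(anova_tukey(rnorm(3), c("a", "b", "b")), "insufficient")
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(88)
  ps <- vapply(1:400, function(i) {
    y <- rnorm(48)
    anova_tukey(y, rep(letters[1:4], each = 12))$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})

test_that("logistic regression recovers odds ratios", {
  set.seed(5150)
  # null: no association, OR near 1 and CI covering 1
  d0 <- data.frame(mcer = rnorm(2000, 3000, 400), x = rbinom(2000, 1, 0.5))
  r0 <- logistic_mcer(d0, "x")
  expect_lt(abs(log(r0$odds_ratio)), 3 * (log(r0$ci_high) - log(r0$odds_ratio)) / 1.96)
  expect_true(r0$ci_low < 1 && r0$ci_high > 1)
  # 2x2 identity: fitted OR equals the cross-product ratio
  tab <- expand.grid(x = c(0, 1), hi = c(0, 1))
  cnt <- c(40, 25, 20, 35)
  d2 <- tab[rep(seq_len(4), cnt), ]
  d2$mcer <- ifelse(d2$hi == 1, 4000, 2000)
  r2 <- logistic_mcer(d2, "x", outcome_rule = 3000)
  expect_equal(r2$odds_ratio, (35 * 40) / (20 * 25), tolerance = 1e-6)
  # known logit model: coefficients recovered within 3 SE at n = 2000
  n <- 2000
  x1 <- rbinom(n, 1, 0.4); x2 <- rnorm(n)
  eta <- -0.3 + 0.8 * x1 + 0.5 * x2
  y <- rbinom(n, 1, plogis(eta))
  dd <- data.frame(mcer = ifelse(y == 1, 4000, 2000), x1 = x1, x2 = x2)
  rr <- logistic_mcer(dd, c("x1", "x2"), outcome_rule = 3000,
                      mode = "multivariate", alpha = 0.05)
  se <- (log(rr$ci_high) - log(rr$odds_ratio)) / 1.96
  expect_lt(abs(log(rr$odds_ratio[rr$term == "x1"]) - 0.8),
            3 * se[rr$term == "x1"])
  expect_lt(abs(log(rr$odds_ratio[rr$term == "x2"]) - 0.5),
            3 * se[rr$term == "x2"])
})

test_that("logistic regression surfaces separation and degenerate outcomes", {
  d <- data.frame(mcer = c(rep(1000, 20), rep(5000, 20)),
                  x = c(rep(0, 20), rep(1, 20)))
  expect_error(logistic_mcer(d, "x"), "separation")
  dsame <- data.frame(mcer = rep(1000, 10), x = rbinom(10, 1, .5))
  expect_error(logistic_mcer(dsame, "x"), "single class")
})

test_that("trait enters as categorical with choleric reference", {
  set.seed(909)
  b <- generate_cohort(default_cohort_spec(seed = 909))
  res <- base_case_analysis(b)
  d <- data.frame(mcer = res$per_patient$mcer, trait = res$per_patient$trait)
  r <- logistic_mcer(d, "trait")
  expect_setequal(r$term, c("traitsanguine", "traitmelancholic",
                            "traitphlegmatic"))
  # melancholic patients pay more per QALY than the choleric reference
  expect_gt(r$odds_ratio[r$term == "traitmelancholic"], 1)
  # sanguine patients pay less
  expect_lt(r$odds_ratio[r$term == "traitsanguine"], 1)
})

test_that("two-mean sample size follows the normal-approximation formula", {
  expect_equal(sample_size_two_means(delta = 1, sd = 1), 22)
  expect_equal(sample_size_two_means(500, 250, power = 0.90, dropout = 0.2), 7)
  # dropout of 50% doubles the pre-ceiling n
  expect_equal(sample_size_two_means(1, 1, dropout = 0.5), 43)
  # halving the detectable difference quadruples the pre-ceiling n
  expect_equal(sample_size_two_means(0.5, 1), 85)
  expect_error(sample_size_two_means(1, 1, alpha = 0.5, power = 0.4),
               "invalid design")
})
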