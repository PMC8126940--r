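# Cohort statistics: contingency tests, ANOVA with Tukey HSD, logistic
# regression on MCER, sample-size calculation.

#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic sum((O - E)^2 / E) with expected counts from
#' the margins and df = (r - 1)(c - 1); no continuity correction, matching
#' the usual reporting for trait-by-category contingency tables.
#'
#' @param observed Matrix of observed counts, at least 2 x 2.
#' @return List with `statistic`, `df`, `p_value` and `expected`.
#' @export
chi_square_test <- function(observed) {
  m <- as.matrix(observed)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("table must be at least 2 x 2")
  if (any(m < 0)) stop("counts must be >= 0")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = ht$expected)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Classic equal-variance one-way ANOVA (pooled mean-square error), with
#' all pairwise group comparisons adjusted by Tukey's honestly-significant-
#' difference procedure via the studentized-range distribution.
#'
#' @param values Numeric response vector.
#' @param groups Factor (or coercible) of group labels.
#' @return List with `f`, `df`, `p_value` and `pairwise` (data.frame with
#'   `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  n_by <- table(groups)
  if (any(n_by < 2L))
    stop("insufficient data: every group needs at least 2 observations")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"], row.names = NULL)
  list(f = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
       p_value = an[1, "Pr(>F)"], pairwise = pairwise)
}

#' Logistic regression of dichotomized MCER on clinical predictors
#'
#' The continuous MCER endpoint is dichotomized by `outcome_rule` (default:
#' above/below the cohort median -- the source analyses never state their
#' rule, which is this module's loudest caveat) and regressed on clinical
#' predictors by maximum-likelihood logistic regression. In univariate mode
#' each predictor is fitted alone; in multivariate mode all predictors
#' passing the univariate screen (p < `alpha`) enter jointly. Temperament
#' enters as a categorical predictor with choleric as the reference level.
#' With `adjust = TRUE`, the adjustment covariates (default age, sex, BMI)
#' are added to every model. Odds ratios carry Wald 95% confidence
#' intervals.
#'
#' @param data Data.frame containing `mcer`, the predictors, and any
#'   adjustment covariates.
#' @param predictors Character vector of predictor column names (`"trait"`
#'   allowed; expands to its non-reference levels).
#' @param outcome_rule `"median"`, or a numeric cutoff, or a function of
#'   the `mcer` vector returning a logical outcome.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param adjust Add the adjustment covariates to every model.
#' @param adjust_for Adjustment covariate names.
#' @param alpha Univariate screening level for multivariate inclusion.
#' @return Data.frame with `term`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `adjusted`.
#' @export
logistic_mcer <- function(data, predictors,
                          outcome_rule = "median",
                          mode = c("univariate", "multivariate"),
                          adjust = FALSE,
                          adjust_for = c("age", "sex", "bmi"),
                          alpha = 0.05) {
  mode <- match.arg(mode)
  y <- if (is.function(outcome_rule)) {
    outcome_rule(data$mcer)
  } else if (identical(outcome_rule, "median")) {
    data$mcer > stats::median(data$mcer, na.rm = TRUE)
  } else if (is.numeric(outcome_rule)) {
    data$mcer > outcome_rule
  } else stop("unknown outcome_rule")
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("dichotomized outcome has a single class")
  data$.outcome <- y
  if ("trait" %in% names(data))
    data$trait <- stats::relevel(factor(data$trait, levels = trait_levels()),
                                 ref = "choleric")
  extra <- if (adjust) adjust_for else character(0)
  fit_one <- function(terms) {
    fml <- stats::reformulate(c(terms, extra), response = ".outcome")
    fit <- stats::glm(fml, data = data, family = stats::binomial())
    if (!fit$converged)
      stop("logistic fit did not converge (possible separation) for: ",
           paste(terms, collapse = " + "))
    sm <- summary(fit)$coefficients
    if (any(abs(sm[-1, "Estimate"]) > 15) || any(sm[-1, "Std. Error"] > 100))
      stop("quasi-complete separation detected for: ",
           paste(terms, collapse = " + "))
    rows <- setdiff(rownames(sm), "(Intercept)")
    keep <- rows[!rows %in% unlist(lapply(extra, function(a)
      grep(paste0("^", a), rows, value = TRUE)))]
    data.frame(
      term = keep,
      odds_ratio = exp(sm[keep, "Estimate"]),
      ci_low = exp(sm[keep, "Estimate"] - 1.96 * sm[keep, "Std. Error"]),
      ci_high = exp(sm[keep, "Estimate"] + 1.96 * sm[keep, "Std. Error"]),
      p_value = sm[keep, "Pr(>|z|)"],
      adjusted = adjust, row.names = NULL)
  }
  if (mode == "univariate") {
    out <- do.call(rbind, lapply(predictors, fit_one))
  } else {
    uni <- do.call(rbind, lapply(predictors, function(p) {
      r <- fit_one(p); r$predictor <- p; r
    }))
    keep <- unique(uni$predictor[uni$p_value < alpha])
    if (!length(keep))
      stop("no predictor passed the univariate screen at alpha = ", alpha)
    out <- fit_one(keep)
  }
  rownames(out) <- NULL
  out
}

#' Sample size for comparing two means
#'
#' Standard two-sample normal-approximation formula with dropout
#' inflation: n per group =
#' ceiling( 2 (z_{1-alpha/2} + z_{power})^2 (sd / delta)^2 / (1 - dropout) ).
#'
#' @param delta Smallest mean difference to detect (> 0).
#' @param sd Common standard deviation (> 0).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.90).
#' @param dropout Anticipated dropout proportion in [0, 1).
#' @return Integer sample size per group.
#' @export
sample_size_two_means <- function(delta, sd, alpha = 0.05, power = 0.90,
                                  dropout = 0) {
  stopifnot(delta > 0, sd > 0, alpha > 0, alpha < 1, dropout >= 0,
            dropout < 1)
  if (power <= alpha || power >= 1)
    stop("invalid design: power must lie in (alpha, 1)")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  ceiling(2 * z^2 * (sd / delta)^2 / (1 - dropout))
}
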