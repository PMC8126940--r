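# Seeded synthetic-cohort generator calibrated to the published summary
# tables, so the whole pipeline runs and is tested without any real data.

#' Names of the seven TKA cost components
#' @return Character vector of component column names.
#' @export
cost_components <- function() {
  c("surgical_procedures", "hospital_stay", "clinical_tests",
    "medical_treatment", "rehabilitation", "outpatient_checkup",
    "outpatient_travel")
}

#' Recompute cost totals from components
#'
#' The total is always the sum of the seven components; a `total` column in
#' the input is never trusted.
#'
#' @param costs Data.frame with `patient_id` and the seven
#'   [cost_components()] columns.
#' @return Data.frame `patient_id`, `total`.
#' @export
cost_totals <- function(costs) {
  comp <- cost_components()
  miss <- setdiff(comp, names(costs))
  if (length(miss))
    stop("costs table is missing component(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(costs[, comp])
  if (any(m < 0)) stop("cost components must be >= 0")
  data.frame(patient_id = costs$patient_id, total = rowSums(m))
}

comorbidity_names <- function() {
  c("smoking", "heavy_drinking", "hypertension", "cardiac", "copd", "ra",
    "diabetes", "low_albumin")
}

#' Published per-trait cohort parameters
#'
#' The calibration targets of the generator, transcribed from the source
#' study's summary tables: group sizes, demographics, pre/post WOMAC
#' moments and the seven cost-component moments per temperament.
#' Parenthesized dispersions in the printed cost and sensitivity tables are
#' treated as standard deviations throughout (their magnitudes are only
#' consistent with SDs, not confidence-interval half-widths; this reading
#' is required to generate patient-level data and is flagged prominently in
#' the methods vignette).
#'
#' @param seed Integer RNG seed for [generate_cohort()].
#' @param womac_cor Correlation between pre- and post-operative WOMAC
#'   totals (default 0.5), which gives change-score SDs close to the
#'   published 8--11 points.
#' @return List of class `cohort_spec`: `profiles` (one per trait), `seed`,
#'   `womac_cor`.
#' @export
default_cohort_spec <- function(seed = 20180501, womac_cor = 0.5) {
  profile <- function(trait, n, age_mean, age_sd, male_fraction,
                      bmi_mean, bmi_sd, comorb, asa12_fraction,
                      womac_pre_mean, womac_pre_sd,
                      womac_post_mean, womac_post_sd,
                      cost_means, cost_sds) {
    names(comorb) <- comorbidity_names()
    names(cost_means) <- names(cost_sds) <- cost_components()
    list(trait = trait, n = n, age_mean = age_mean, age_sd = age_sd,
         male_fraction = male_fraction, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         comorbidity_prevalences = comorb, asa12_fraction = asa12_fraction,
         womac_pre_mean = womac_pre_mean, womac_pre_sd = womac_pre_sd,
         womac_post_mean = womac_post_mean, womac_post_sd = womac_post_sd,
         cost_means = cost_means, cost_sds = cost_sds)
  }
  spec <- list(
    profiles = list(
      choleric = profile("choleric", 41L, 62.3, 5.3, 26 / 41, 27.1, 3.1,
        c(.244, .098, .268, .122, .098, .122, .195, .073), 39 / 41,
        113.2, 11.2, 42.1, 8.5,
        c(8432.3, 440.2, 350.3, 2502.3, 2320.5, 712.5, 1074.3),
        c(212.3, 70.5, 110.2, 393.2, 379.2, 220.2, 321.2)),
      sanguine = profile("sanguine", 70L, 61.8, 6.1, 37 / 70, 26.8, 2.8,
        c(.271, .114, .286, .143, .086, .143, .229, .071), 68 / 70,
        115.5, 10.3, 37.9, 9.2,
        c(8423.5, 401.2, 309.5, 2322.2, 2132.5, 687.5, 805.2),
        c(200.5, 69.2, 97.4, 360.5, 362.1, 190.2, 266.4)),
      melancholic = profile("melancholic", 46L, 60.4, 5.7, 14 / 46, 27.2, 3.2,
        c(.261, .109, .261, .130, .087, .130, .217, .087), 43 / 46,
        117.5, 8.5, 51.7, 8.2,
        c(8490.5, 696.6, 600.2, 3210.2, 3600.4, 1212.5, 1713.2),
        c(210.2, 80.2, 100.2, 400.2, 413.5, 212.2, 421.5)),
      phlegmatic = profile("phlegmatic", 54L, 63.2, 5.5, 28 / 54, 27.0, 3.0,
        c(.241, .111, .259, .130, .093, .130, .185, .074), 50 / 54,
        114.4, 9.5, 43.2, 8.8,
        c(8432.3, 431.2, 363.2, 2531.4, 2321.3, 777.5, 952.7),
        c(223.4, 92.1, 79.2, 380.2, 354.5, 198.2, 282.4))
    ),
    seed = as.integer(seed), womac_cor = womac_cor,
    age_range = c(46, 71)
  )
  class(spec) <- "cohort_spec"
  spec
}

#' Published base-case summary, for calibration checks
#'
#' The study's base-case per-trait summary (pre/post/change WOMAC, QALYs,
#' MCER, total cost; means with SDs), kept as reference values for
#' calibration and arithmetic-identity checks. Note one internal
#' inconsistency of the printed source carried over verbatim: the sanguine
#' MCER (2264.0) does not equal printed total cost / printed QALYs
#' (15081.6 / 6.9 = 2185.7), while the other three traits match exactly.
#'
#' @return Data.frame, one row per trait.
#' @export
base_case_reference <- function() {
  data.frame(
    trait = trait_levels(),
    n = c(41L, 70L, 46L, 54L),
    n_male = c(26L, 37L, 14L, 28L),
    womac_pre = c(113.2, 115.5, 117.5, 114.4),
    womac_pre_sd = c(11.2, 10.3, 8.5, 9.5),
    womac_post = c(42.1, 37.9, 51.7, 43.2),
    womac_post_sd = c(8.5, 9.2, 8.2, 8.8),
    womac_change = c(71.1, 77.6, 65.8, 71.2),
    womac_change_sd = c(9.3, 11.3, 8.3, 9.2),
    qalys = c(5.8, 6.9, 5.0, 5.6),
    qalys_sd = c(1.1, 1.3, 1.2, 1.2),
    mcer = c(2728.2, 2264.0, 3504.7, 2821.5),
    mcer_sd = c(478.4, 421.6, 576.2, 500.5),
    total_cost = c(15823.4, 15081.6, 17523.6, 15800.6),
    total_cost_sd = c(521.5, 501.0, 682.3, 523.2)
  )
}

# Truncated-Normal sampling by inverse CDF: deterministic in the RNG state,
# no rejection loop.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  if (any(pu - pl <= 0)) stop("infeasible truncation bounds")
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

# Quadrant score ranges for each temperament under cutoffs (6, 6):
# high = 7..12 (strictly above the cutoff), low = 0..6.
quadrant_ranges <- function(trait) {
  high <- 7:12; low <- 0:6
  switch(trait,
    choleric = list(e = high, n = high),
    sanguine = list(e = high, n = low),
    melancholic = list(e = low, n = high),
    phlegmatic = list(e = low, n = low))
}

# Build 48-item answer rows realizing given subscale scores under a key.
sheets_from_scores <- function(scores, key) {
  validate_epq_key(key)
  t(apply(scores, 1, function(s) {
    ans <- integer(48L)
    for (sub in c("E", "N", "P", "L")) {
      idx <- which(key$subscale == sub)
      hit <- sample(idx, s[[sub]])
      ans[hit] <- key$keyed_answer[hit]
      rest <- setdiff(idx, hit)
      ans[rest] <- 1L - key$keyed_answer[rest]
    }
    ans
  }))
}

#' Generate a synthetic cohort
#'
#' Draws a full patient-level cohort from a [default_cohort_spec()]:
#' demographics (age truncated to the study's enrollment range, sex,
#' BMI, comorbidity flags, ASA class), EPQ response sheets whose
#' extroversion/neuroticism scores lie in the quadrant of the assigned
#' temperament, pre/post WOMAC totals drawn jointly with correlation
#' `womac_cor` (post < pre enforced by resampling, both truncated to the
#' instrument range) and the seven cost components (Normal truncated at 0).
#' The result is a deterministic function of `spec$seed`.
#'
#' @param spec A cohort specification from [default_cohort_spec()].
#' @param key EPQ item key, default [epq_default_key()].
#' @param total_max WOMAC instrument maximum (default 240).
#' @return List of class `cohort_bundle` with data.frames `patients`,
#'   `womac`, `costs`, `epq` (one 48-answer row per patient) and
#'   `epq_scores`.
#' @export
generate_cohort <- function(spec = default_cohort_spec(),
                            key = epq_default_key(), total_max = 240) {
  stopifnot(inherits(spec, "cohort_spec"), length(spec$profiles) == 4L)
  set.seed(spec$seed)
  rho <- spec$womac_cor
  patients <- womac <- costs <- scores <- list()
  id0 <- 0L
  for (pr in spec$profiles) {
    n <- pr$n
    ids <- sprintf("P%03d", id0 + seq_len(n)); id0 <- id0 + n
    age <- rtrunc_norm(n, pr$age_mean, pr$age_sd,
                       spec$age_range[1], spec$age_range[2])
    sex <- ifelse(stats::runif(n) < pr$male_fraction, "male", "female")
    bmi <- rtrunc_norm(n, pr$bmi_mean, pr$bmi_sd, 15, 45)
    com <- vapply(pr$comorbidity_prevalences,
                  function(p) as.integer(stats::runif(n) < p), integer(n))
    if (n == 1L) com <- matrix(com, nrow = 1)
    asa <- ifelse(stats::runif(n) < pr$asa12_fraction,
                  sample(c("I", "II"), n, replace = TRUE),
                  sample(c("III", "IV"), n, replace = TRUE, prob = c(.9, .1)))
    # pre/post WOMAC: bivariate Normal with correlation rho, then resample
    # rows violating the instrument range or post < pre
    pre <- post <- rep(NA_real_, n)
    todo <- seq_len(n); guard <- 0L
    while (length(todo)) {
      z1 <- stats::rnorm(length(todo)); z2 <- stats::rnorm(length(todo))
      p1 <- pr$womac_pre_mean + pr$womac_pre_sd * z1
      p2 <- pr$womac_post_mean +
        pr$womac_post_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
      ok <- p1 > 0 & p1 <= total_max & p2 >= 0 & p2 < p1
      pre[todo[ok]] <- p1[ok]; post[todo[ok]] <- p2[ok]
      todo <- todo[!ok]
      guard <- guard + 1L
      if (guard > 1000L) stop("infeasible WOMAC truncation bounds")
    }
    comp <- vapply(cost_components(), function(cc)
      rtrunc_norm(n, pr$cost_means[[cc]], pr$cost_sds[[cc]], lower = 0),
      numeric(n))
    if (n == 1L) comp <- matrix(comp, nrow = 1)
    qr <- quadrant_ranges(pr$trait)
    sc <- data.frame(
      E = sample(qr$e, n, replace = TRUE),
      N = sample(qr$n, n, replace = TRUE),
      P = sample(0:12, n, replace = TRUE),
      L = sample(0:12, n, replace = TRUE)
    )
    patients[[pr$trait]] <- data.frame(
      patient_id = ids, trait = pr$trait, age = age, sex = sex, bmi = bmi,
      asa_class = asa, as.data.frame(com)
    )
    womac[[pr$trait]] <- data.frame(patient_id = ids, pre = pre, post = post)
    costs[[pr$trait]] <- data.frame(patient_id = ids, as.data.frame(comp))
    scores[[pr$trait]] <- data.frame(patient_id = ids, sc)
  }
  patients <- do.call(rbind, patients)
  patients$trait <- factor(patients$trait, levels = trait_levels())
  rownames(patients) <- NULL
  womac <- do.call(rbind, womac); rownames(womac) <- NULL
  costs <- do.call(rbind, costs); rownames(costs) <- NULL
  scores <- do.call(rbind, scores); rownames(scores) <- NULL
  sheets <- sheets_from_scores(scores[, c("E", "N", "P", "L")], key)
  colnames(sheets) <- sprintf("item_%02d", 1:48)
  epq <- data.frame(patient_id = scores$patient_id, administration = 1L,
                    sheets)
  structure(list(patients = patients, womac = womac, costs = costs,
                 epq = epq, epq_scores = scores),
            class = "cohort_bundle")
}

#' Write a cohort bundle to CSV files
#'
#' Writes `patients.csv`, `womac.csv` (long form with a `timepoint`
#' column), `costs.csv` and `epq.csv` into `dir` (UTF-8, headers, empty
#' cells for missing values).
#'
#' @param bundle A `cohort_bundle` from [generate_cohort()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohort_csvs <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  womac_long <- rbind(
    data.frame(patient_id = bundle$womac$patient_id, timepoint = "pre",
               total = bundle$womac$pre),
    data.frame(patient_id = bundle$womac$patient_id, timepoint = "post",
               total = bundle$womac$post))
  paths <- c(
    patients = file.path(dir, "patients.csv"),
    womac = file.path(dir, "womac.csv"),
    costs = file.path(dir, "costs.csv"),
    epq = file.path(dir, "epq.csv"))
  utils::write.csv(bundle$patients, paths["patients"], row.names = FALSE)
  utils::write.csv(womac_long, paths["womac"], row.names = FALSE)
  utils::write.csv(bundle$costs, paths["costs"], row.names = FALSE)
  utils::write.csv(bundle$epq, paths["epq"], row.names = FALSE)
  invisible(paths)
}
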