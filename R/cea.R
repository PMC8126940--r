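# MCER, per-trait summaries, deterministic one-way sensitivity analysis.

#' Marginal cost-effectiveness ratio
#'
#' MCER relates the direct cost of the intervention to the clinical benefit
#' it buys: total cost divided by QALYs gained, in $/QALY. A non-positive
#' QALY gain leaves the ratio undefined; such patients are reported as `NA`
#' (and counted downstream), never silently dropped.
#'
#' @param total_cost Total cost in 2018 USD, >= 0 (vectorized).
#' @param qalys QALYs gained.
#' @param na_undefined If `TRUE` (default) return `NA` where `qalys <= 0`;
#'   if `FALSE`, raise an error instead.
#' @return USD per QALY.
#' @export
mcer <- function(total_cost, qalys, na_undefined = TRUE) {
  if (any(total_cost < 0)) stop("total cost must be >= 0")
  und <- qalys <= 0 | is.na(qalys)
  if (any(und) && !na_undefined)
    stop("undefined MCER: non-positive QALY gain for ", sum(und),
         " patient(s)")
  out <- total_cost / qalys
  out[und] <- NA_real_
  out
}

#' Per-trait summary of QALYs and MCER
#'
#' Means and sample standard deviations of QALYs gained and MCER within
#' each temperament group, computed per patient and then averaged (the
#' printed dispersion of MCER implies a per-patient distribution, so the
#' group MCER is the mean of patient ratios, not the ratio of means).
#' Patients with undefined MCER are excluded from the MCER moments and
#' counted in `n_undefined`.
#'
#' @param trait Factor or character of temperament labels.
#' @param qalys QALYs gained per patient.
#' @param total_cost Total cost per patient, 2018 USD.
#' @param scenario Scenario label attached to every row (default "base").
#' @return Data.frame with one row per trait: `trait`, `scenario`, `n`,
#'   `mean_qalys`, `sd_qalys`, `mean_mcer`, `sd_mcer`, `n_undefined`.
#' @export
cea_group_summary <- function(trait, qalys, total_cost, scenario = "base") {
  trait <- factor(trait, levels = trait_levels())
  if (any(is.na(trait))) stop("unknown trait label")
  n_by <- table(trait)
  if (any(n_by == 0))
    stop("missing trait group(s): ",
         paste(names(n_by)[n_by == 0], collapse = ", "))
  if (any(n_by < 2)) stop("need at least 2 patients per trait group")
  m <- mcer(total_cost, qalys)
  out <- do.call(rbind, lapply(trait_levels(), function(tr) {
    i <- trait == tr
    mi <- m[i]
    data.frame(
      trait = tr, scenario = scenario, n = sum(i),
      mean_qalys = mean(qalys[i]), sd_qalys = stats::sd(qalys[i]),
      mean_mcer = mean(mi, na.rm = TRUE), sd_mcer = stats::sd(mi, na.rm = TRUE),
      n_undefined = sum(is.na(mi))
    )
  }))
  out$trait <- factor(out$trait, levels = trait_levels())
  out
}

#' Base-case cost-effectiveness analysis of a cohort
#'
#' Runs the QALY engine on the cohort and summarizes QALYs and MCER per
#' temperament.
#'
#' @param bundle Cohort bundle with data.frames `patients` (incl. `trait`),
#'   `womac` and `costs`, as produced by [generate_cohort()] or
#'   [validate_inputs()].
#' @param config Pipeline configuration, see [default_config()].
#' @return List with `per_patient` (patient-level QALY/MCER table) and
#'   `summary` (per-trait [cea_group_summary()]).
#' @export
base_case_analysis <- function(bundle, config = default_config()) {
  q <- compute_qalys(bundle$patients, bundle$womac, config)
  cost <- cost_totals(bundle$costs)
  cost <- cost[match(bundle$patients$patient_id, cost$patient_id), ]
  pp <- data.frame(
    patient_id = bundle$patients$patient_id,
    trait = bundle$patients$trait,
    qalys_gained = q$qalys_gained,
    total_cost = cost$total,
    mcer = mcer(cost$total, q$qalys_gained)
  )
  list(per_patient = pp,
       summary = cea_group_summary(pp$trait, pp$qalys_gained, pp$total_cost))
}

#' Default one-way sensitivity scenarios
#'
#' The five-scenario design: the base case plus single-parameter shifts of
#' rest-of-life expectancy (+/- 5 years) and prosthesis survival (+/- 3
#' percentage points, with the per-decade revision probability clamped to
#' [0.02, 0.08]).
#'
#' @param config Pipeline configuration supplying the shift magnitudes.
#' @return List of scenario objects (`name` plus a one-entry `params` list).
#' @export
default_scenarios <- function(config = default_config()) {
  le <- config$sensitivity$le_shift
  sv <- config$sensitivity$surv_shift
  list(
    list(name = "base", params = list()),
    list(name = "le_plus5", params = list(life_expectancy = +le)),
    list(name = "le_minus5", params = list(life_expectancy = -le)),
    list(name = "surv_plus3", params = list(prosthesis_survival = +sv)),
    list(name = "surv_minus3", params = list(prosthesis_survival = -sv))
  )
}

apply_scenario <- function(config, scenario) {
  if (length(scenario$params) > 1)
    stop("invalid scenario '", scenario$name,
         "': a one-way scenario must perturb exactly one parameter, got ",
         length(scenario$params))
  cfg <- config
  # inside the sensitivity analysis the revision term is active, so that
  # prosthesis survival is a live parameter; the same setting applies to
  # every scenario including the base column
  cfg$revision$disutility_fraction <- config$sensitivity$disutility_fraction
  if (length(scenario$params) == 1) {
    par <- names(scenario$params)
    shift <- scenario$params[[1]]
    if (par == "life_expectancy") {
      cfg$life_expectancy$mean_female <- cfg$life_expectancy$mean_female + shift
      cfg$life_expectancy$mean_male <- cfg$life_expectancy$mean_male + shift
    } else if (par == "prosthesis_survival") {
      rng <- config$sensitivity$surv_range
      # +x survival means -x revision probability per decade
      p <- cfg$revision$prob_per_decade - shift
      cfg$revision$prob_per_decade <- min(max(p, rng[1]), rng[2])
    } else {
      stop("invalid scenario '", scenario$name, "': unknown parameter '",
           par, "'")
    }
  }
  cfg
}

#' Deterministic one-way sensitivity analysis
#'
#' Recomputes QALYs and MCER per temperament under each scenario, holding
#' everything else (cohort, seeds, all other parameters) fixed. Within the
#' sensitivity analysis the revision disutility fraction is switched on
#' (`sensitivity.disutility_fraction`, default 1) for every scenario
#' including the base column, so prosthesis survival is an active
#' parameter; the base column is therefore the revision-adjusted base case.
#'
#' @inheritParams base_case_analysis
#' @param scenarios List of scenario objects; default [default_scenarios()].
#' @return Data.frame of per-trait summaries stacked over scenarios (one
#'   row per trait x scenario).
#' @export
one_way_sensitivity <- function(bundle, config = default_config(),
                                scenarios = default_scenarios(config)) {
  cost <- cost_totals(bundle$costs)
  cost <- cost[match(bundle$patients$patient_id, cost$patient_id), ]
  out <- lapply(scenarios, function(sc) {
    cfg <- apply_scenario(config, sc)
    q <- compute_qalys(bundle$patients, bundle$womac, cfg)
    cea_group_summary(bundle$patients$trait, q$qalys_gained, cost$total,
                      scenario = sc$name)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Format per-trait CEA tables for printing
#'
#' Renders a summary table in the familiar "mean (SD)" layout with
#' one-decimal commercial rounding; internal arithmetic stays at full
#' precision.
#'
#' @param summary A data.frame from [cea_group_summary()] or
#'   [one_way_sensitivity()].
#' @return Character vector of report lines.
#' @export
format_cea_report <- function(summary) {
  fmt <- function(m, s) sprintf("%.1f (%.1f)", round_half_up(m, 1),
                                round_half_up(s, 1))
  lines <- c(sprintf("%-12s %-12s %4s %18s %22s", "trait", "scenario", "n",
                     "QALYs gained", "MCER ($/QALY)"))
  for (i in seq_len(nrow(summary))) {
    r <- summary[i, ]
    lines <- c(lines, sprintf(
      "%-12s %-12s %4d %18s %22s", as.character(r$trait), r$scenario, r$n,
      fmt(r$mean_qalys, r$sd_qalys), fmt(r$mean_mcer, r$sd_mcer)))
  }
  lines
}
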