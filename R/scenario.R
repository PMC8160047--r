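#' Per-patient expected cost breakdown of the real-life mixed scenario
#'
#' After LCUS adoption the annual cohort of `n_referred_baseline` suspected
#' DVT patients splits into `n_lcus_initial` handled in primary care (of
#' whom `n_repeat` return for a repeat scan) and `n_referred_after` still
#' referred to hospital. Every patient incurs one primary-care visit, so
#' the municipal visit price and patient fee scale by
#' `(n_referred_baseline + n_repeat) / n_referred_baseline`, and hospital
#' price, fee and stay scale by `n_referred_after / n_referred_baseline`;
#' time and travel components are count-weighted mixtures of the two
#' pathways' episodes unless pinned by `component_overrides` (the default,
#' which reproduces the published reference cells).
#'
#' @inheritParams standard_breakdown
#' @return A `cost_breakdown` (pathway `"real_life"`).
#' @export
#' @examples
#' b <- real_life_breakdown(default_config())
#' round_cents(breakdown_total(b))
real_life_breakdown <- function(config, patient = NULL) {
  patient <- .as_patient(patient, config)
  uc <- config$unit_costs
  ct <- config$counts
  tm <- config$times
  n <- ct$n_referred_baseline
  if (n <= 0) stop("real_life_breakdown: n_referred_baseline must be > 0",
                   call. = FALSE)
  if (!isTRUE(all.equal(ct$n_referred_after + ct$n_lcus_initial, n))) {
    stop("real_life_breakdown: counts must satisfy n_referred_after + n_lcus_initial = n_referred_baseline",
         call. = FALSE)
  }
  w_ref <- ct$n_referred_after / n        # hospital episodes per patient
  w_rep <- ct$n_repeat / n                # repeat visits per patient
  phc_visits <- 1 + w_rep                 # primary-care visits per patient

  tv_std <- .travel_standard(config, patient)
  tv_lcus <- .travel_lcus_visit(config, patient)
  phc_min <- (ct$n_lcus_initial * tm$phc_visit_lcus_min +
                ct$n_referred_after * tm$phc_visit_referred_min +
                ct$n_repeat * tm$phc_followup_min) / n
  travel_min <- (ct$n_referred_after * tv_std$min +
                   (ct$n_lcus_initial + ct$n_repeat) * tv_lcus$min) / n
  travel_eur <- (ct$n_referred_after * tv_std$eur +
                   (ct$n_lcus_initial + ct$n_repeat) * tv_lcus$eur) / n

  amounts <- c(
    phc_time = monetize(phc_min, uc$hourly_wage),
    phc_price = uc$phc_visit_price * phc_visits,
    phc_fee = uc$phc_patient_fee * phc_visits,
    travel_time = monetize(travel_min, uc$hourly_wage),
    travel_expense = travel_eur,
    ed_time = monetize(patient$ed_los_min * w_ref, uc$hourly_wage),
    ed_price = uc$ed_visit_price * w_ref,
    ed_fee = uc$ed_patient_fee * w_ref
  )
  amounts <- .apply_overrides(amounts, config, "real_life")
  .new_breakdown("real_life", amounts)
}

#' One-time LCUS training cost
#'
#' The course fee plus the salary cost of the participating general
#' practitioners: one working day each, valued as the monthly salary
#' divided by the working days per month, times the number of
#' participants, rounded to the nearest euro.
#'
#' @param tp Training parameters (the `training` element of a
#'   `dvt_config`).
#' @return A `training_cost` list with `course_fee`, `salary_cost` and
#'   `total` (EUR).
#' @export
#' @examples
#' training_cost(default_config()$training)
training_cost <- function(tp) {
  salary <- .round_euro(tp$gp_monthly_salary / tp$working_days_per_month *
                          tp$n_participants)
  structure(list(course_fee = tp$course_fee,
                 salary_cost = salary,
                 total = tp$course_fee + salary),
            class = "training_cost")
}

#' Annual cohort cost
#'
#' @param per_patient_total Per-patient cost, EUR. Reports pass the
#'   cent-rounded per-patient total so that the printed annual figure is an
#'   exact multiple of the printed per-patient figure.
#' @param n Patients per year (>= 0).
#' @return EUR.
#' @export
annual_total <- function(per_patient_total, n) {
  if (n < 0) stop("annual_total: n must be >= 0", call. = FALSE)
  per_patient_total * n
}

#' First-year cost including one-time training
#'
#' @param annual Annual cohort cost, EUR.
#' @param training A `training_cost`.
#' @return EUR.
#' @export
first_year_total <- function(annual, training) {
  annual + training$total
}

#' Back-calculate the number of suspected-DVT patients
#'
#' A proportion `p_ruleout` of suspected cases is ruled out upstream by
#' clinical risk assessment (Wells criteria) and D-dimer without any
#' ultrasound, so `n_us_referred` ultrasound referrals imply
#' `n_us_referred / (1 - p_ruleout)` suspected cases, rounded half up to
#' the nearest integer.
#'
#' @param n_us_referred Ultrasound referrals observed (count).
#' @param p_ruleout Rule-out proportion in \[0, 1).
#' @return Integer count.
#' @export
#' @examples
#' estimate_suspected(60, 0.23)
estimate_suspected <- function(n_us_referred, p_ruleout) {
  if (p_ruleout < 0 || p_ruleout >= 1) {
    stop("estimate_suspected: p_ruleout must be in [0, 1)", call. = FALSE)
  }
  as.integer(floor(n_us_referred / (1 - p_ruleout) + 0.5))
}

#' Relative reduction in hospital referrals
#'
#' @param n_before Referrals before LCUS adoption (> 0).
#' @param n_after Referrals after (<= `n_before`).
#' @return Percent reduction (not rounded).
#' @export
#' @examples
#' referral_reduction(60, 16)
referral_reduction <- function(n_before, n_after) {
  if (n_before <= 0) stop("referral_reduction: n_before must be > 0",
                          call. = FALSE)
  if (n_after > n_before) {
    stop("referral_reduction: n_after must be <= n_before", call. = FALSE)
  }
  (n_before - n_after) / n_before * 100
}

#' Full real-life scenario result
#'
#' Bundles the per-patient real-life breakdown, the annual cohort cost (the
#' cent-rounded per-patient total times the annual patient count), the
#' one-time training cost and the first-year total.
#'
#' @param config A `dvt_config`.
#' @param patient Optional patient record, see [real_life_breakdown()].
#' @return A `scenario_result` list: `per_patient`, `annual_total`,
#'   `training`, `first_year_total`, `n_patients`.
#' @export
#' @examples
#' s <- scenario_result(default_config())
#' s$first_year_total
scenario_result <- function(config, patient = NULL) {
  per_patient <- real_life_breakdown(config, patient)
  n <- config$counts$n_referred_baseline
  annual <- annual_total(round_cents(breakdown_total(per_patient)), n)
  training <- training_cost(config$training)
  structure(list(per_patient = per_patient,
                 annual_total = annual,
                 training = training,
                 first_year_total = first_year_total(annual, training),
                 n_patients = n),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> real-life mixed scenario\n")
  cat(sprintf("  per-patient total : %10.2f EUR\n",
              round_cents(breakdown_total(x$per_patient))))
  cat(sprintf("  annual total      : %10.2f EUR (%d patients/year)\n",
              x$annual_total, x$n_patients))
  cat(sprintf("  training          : %10.2f EUR (course %.0f + salaries %.0f)\n",
              x$training$total, x$training$course_fee, x$training$salary_cost))
  cat(sprintf("  first-year total  : %10.2f EUR\n", x$first_year_total))
  invisible(x)
}
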