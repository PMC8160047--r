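#' @keywords internal
"_PACKAGE"

# Canonical per-patient cost components, ordered as they appear in reports.
# Payer: municipal prices and (publicly subsidised taxi) travel expenses are
# public; patient fees and all monetized time are borne privately.
# Cost class: monetized time (lost working/leisure time) is indirect,
# everything else direct.
.component_labels <- c(
  "phc_time", "phc_price", "phc_fee",
  "travel_time", "travel_expense",
  "ed_time", "ed_price", "ed_fee"
)

.component_payer <- c(
  phc_time = "private", phc_price = "public", phc_fee = "private",
  travel_time = "private", travel_expense = "public",
  ed_time = "private", ed_price = "public", ed_fee = "private"
)

.component_class <- c(
  phc_time = "indirect", phc_price = "direct", phc_fee = "direct",
  travel_time = "indirect", travel_expense = "direct",
  ed_time = "indirect", ed_price = "direct", ed_fee = "direct"
)

.pathway_ids <- c("standard", "lcus", "real_life")

#' Canonical cost component labels
#'
#' The eight per-patient cost components of a diagnostic pathway, in report
#' order: primary-health-care visit time (monetized), visit price (paid by
#' municipalities), patient fee, travel time (monetized), travel expenses,
#' emergency-department time (monetized), visit price, and patient fee.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' component_labels()
component_labels <- function() .component_labels

#' Default model configuration
#'
#' Returns the reference parameterisation of the cost-minimization model:
#' 2017 Finnish unit costs (average hourly pay 18.70 EUR/h, emergency
#' department visit price 503.45 EUR and patient fee 41.20 EUR, primary
#' health care visit price 96 EUR and urgent-appointment fee 28.30 EUR),
#' visit-time assumptions (30 min if referred, 35 min for an LCUS visit,
#' 20 min follow-up, 212 min average emergency-department stay, 80 km/h
#' driving speed), annual pathway counts (60 referrals at baseline, of which
#' after LCUS adoption 44 are handled in primary care, 20 need a repeated
#' scan and 16 are still referred), and training parameters (3500 EUR course
#' fee, 6568 EUR monthly GP salary, 21 working days/month, 12 participants).
#'
#' Travel components are calibrated per episode rather than derived from a
#' fare formula: the standard hospital episode carries 145.77 min of travel
#' time and 361.73 EUR of travel expenses, one LCUS visit 24.45 min and
#' 64.0819 EUR. `component_overrides` pins the LCUS and real-life pathway
#' time/travel cells to the published reference values; clear them (see
#' [clear_overrides()]) to compute those components mechanistically from the
#' stated visit times and counts.
#'
#' @return A validated `dvt_config` object (nested list with elements
#'   `unit_costs`, `times`, `counts`, `training`, `overrides`,
#'   `travel_mode`).
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$unit_costs$hourly_wage
default_config <- function() {
  cfg <- list(
    unit_costs = list(
      hourly_wage = 18.70,
      phc_visit_price = 96.00,
      phc_patient_fee = 28.30,
      ed_visit_price = 503.45,
      ed_patient_fee = 41.20,
      travel_time_standard_episode_min = 145.77,
      travel_expense_standard_episode = 361.73,
      travel_time_lcus_visit_min = 24.45,
      travel_expense_lcus_visit = 64.0819,
      taxi_fare_per_km = 1.79
    ),
    times = list(
      phc_visit_referred_min = 30,
      phc_visit_lcus_min = 35,
      phc_followup_min = 20,
      ed_length_of_stay_min = 212,
      driving_speed_kmh = 80
    ),
    counts = list(
      n_referred_baseline = 60L,
      n_referred_after = 16L,
      n_lcus_initial = 44L,
      n_repeat = 20L,
      p_ddimer_ruleout = 0.23,
      p_repeat_literature = 0.459
    ),
    training = list(
      course_fee = 3500,
      gp_monthly_salary = 6568,
      working_days_per_month = 21,
      n_participants = 12L
    ),
    overrides = list(
      lcus = list(
        phc_time = 16.86,
        travel_time = 11.08,
        travel_expense = 93.21
      ),
      real_life = list(
        phc_time = 14.86,
        travel_time = 17.92,
        travel_expense = 148.83,
        ed_time = 16.11
      )
    ),
    travel_mode = "calibrated"
  )
  structure(cfg, class = "dvt_config")
}

#' Remove component overrides from a configuration
#'
#' With overrides cleared, every time and travel component is computed
#' mechanistically from the configured visit durations, calibrated episode
#' travel values (or distances, in `travel_mode = "mechanistic"`) and
#' pathway counts. Used for sensitivity analysis and limiting-case checks.
#'
#' @param config A `dvt_config`.
#' @param pathways Pathways whose overrides to drop (default: all).
#' @return The modified configuration.
#' @export
clear_overrides <- function(config, pathways = .pathway_ids) {
  for (p in pathways) config$overrides[[p]] <- NULL
  config
}

# Recursively merge user values into defaults; unknown keys are an error so
# that typos surface instead of silently falling back to defaults.
.merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    stop(sprintf("config entry '%s' must be a mapping", paste(path, collapse = ".")),
         call. = FALSE)
  }
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (identical(path, "overrides") || (length(path) && path[[1]] == "overrides")) {
      # override keys are validated later against labels/pathways
      defaults[[key]] <- user[[key]]
      next
    }
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown configuration key: '%s'", here), call. = FALSE)
    }
    if (is.list(defaults[[key]]) && key != "overrides") {
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], c(path, key))
    } else if (key == "overrides") {
      defaults[[key]] <- utils::modifyList(defaults[[key]], user[[key]])
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a model configuration from a YAML file
#'
#' Reads a (possibly partial) configuration; fields absent from the file
#' fall back to [default_config()]. Unknown keys are rejected. The loaded
#' configuration is validated and invalid values raise an error naming the
#' offending field.
#'
#' @param path Path to a YAML file. An empty file yields the defaults.
#' @return A validated `dvt_config`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("unit_costs:\n  hourly_wage: 20.0", f)
#' cfg <- load_config(f)
#' cfg$unit_costs$hourly_wage
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  }
  user <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop(sprintf("failed to parse config '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  cfg <- .merge_config(unclass(default_config()), user)
  cfg <- structure(cfg, class = "dvt_config")
  viol <- validate_config(cfg)
  if (length(viol)) {
    stop(paste(c("invalid configuration:", viol), collapse = "\n  "), call. = FALSE)
  }
  cfg
}

#' Serialize a configuration to YAML
#'
#' @param config A `dvt_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    return(sprintf("%s must be a single number", name))
  }
  if (x < 0) return(sprintf("%s must be >= 0 (got %g)", name, x))
  character()
}

.check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    return(sprintf("%s must be a single number", name))
  }
  if (x <= 0) return(sprintf("%s must be > 0 (got %g)", name, x))
  character()
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the model: non-negative unit costs
#' with a strictly positive hourly wage, strictly positive time assumptions,
#' non-negative integer pathway counts satisfying the partition identity
#' `n_referred_after + n_lcus_initial = n_referred_baseline`, proportions in
#' \[0, 1\], strictly positive training parameters, a known `travel_mode`,
#' and override keys drawn from the canonical component labels and pathway
#' ids with non-negative amounts.
#'
#' @param config A `dvt_config`.
#' @return Character vector of violations; empty when the configuration is
#'   valid.
#' @export
#' @examples
#' validate_config(default_config())
validate_config <- function(config) {
  v <- character()
  uc <- config$unit_costs
  for (f in c("phc_visit_price", "phc_patient_fee", "ed_visit_price",
              "ed_patient_fee", "travel_time_standard_episode_min",
              "travel_expense_standard_episode", "travel_time_lcus_visit_min",
              "travel_expense_lcus_visit", "taxi_fare_per_km")) {
    v <- c(v, .check_nonneg(uc[[f]], paste0("unit_costs.", f)))
  }
  v <- c(v, .check_pos(uc$hourly_wage, "unit_costs.hourly_wage"))

  for (f in names(config$times)) {
    v <- c(v, .check_pos(config$times[[f]], paste0("times.", f)))
  }

  ct <- config$counts
  for (f in c("n_referred_baseline", "n_referred_after", "n_lcus_initial",
              "n_repeat")) {
    x <- ct[[f]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 ||
        x != round(x)) {
      v <- c(v, sprintf("counts.%s must be a non-negative integer", f))
    }
  }
  if (is.numeric(ct$n_referred_after) && is.numeric(ct$n_lcus_initial) &&
      is.numeric(ct$n_referred_baseline) &&
      !isTRUE(all.equal(ct$n_referred_after + ct$n_lcus_initial,
                        ct$n_referred_baseline))) {
    v <- c(v, sprintf(
      "counts: n_referred_after (%g) + n_lcus_initial (%g) must equal n_referred_baseline (%g)",
      ct$n_referred_after, ct$n_lcus_initial, ct$n_referred_baseline))
  }
  for (f in c("p_ddimer_ruleout", "p_repeat_literature")) {
    x <- ct[[f]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      v <- c(v, sprintf("counts.%s must be a proportion in [0, 1]", f))
    }
  }

  tr <- config$training
  for (f in c("course_fee", "gp_monthly_salary", "working_days_per_month",
              "n_participants")) {
    v <- c(v, .check_pos(tr[[f]], paste0("training.", f)))
  }
  if (is.numeric(tr$n_participants) &&
      tr$n_participants != round(tr$n_participants)) {
    v <- c(v, "training.n_participants must be an integer")
  }

  if (!is.character(config$travel_mode) ||
      !config$travel_mode %in% c("calibrated", "mechanistic")) {
    v <- c(v, "travel_mode must be 'calibrated' or 'mechanistic'")
  }

  if (!is.null(config$overrides)) {
    bad_path <- setdiff(names(config$overrides), .pathway_ids)
    if (length(bad_path)) {
      v <- c(v, sprintf("overrides: unknown pathway id(s): %s",
                        paste(bad_path, collapse = ", ")))
    }
    for (p in intersect(names(config$overrides), .pathway_ids)) {
      ov <- config$overrides[[p]]
      bad_lab <- setdiff(names(ov), .component_labels)
      if (length(bad_lab)) {
        v <- c(v, sprintf("overrides.%s: unknown component label(s): %s",
                          p, paste(bad_lab, collapse = ", ")))
      }
      for (lab in intersect(names(ov), .component_labels)) {
        v <- c(v, .check_nonneg(ov[[lab]], sprintf("overrides.%s.%s", p, lab)))
      }
    }
  }
  v
}

#' @export
print.dvt_config <- function(x, ...) {
  cat("<dvt_config> cost-minimization model configuration\n")
  cat(sprintf("  hourly wage      : %.2f EUR/h\n", x$unit_costs$hourly_wage))
  cat(sprintf("  ED visit price   : %.2f EUR (fee %.2f EUR)\n",
              x$unit_costs$ed_visit_price, x$unit_costs$ed_patient_fee))
  cat(sprintf("  PHC visit price  : %.2f EUR (fee %.2f EUR)\n",
              x$unit_costs$phc_visit_price, x$unit_costs$phc_patient_fee))
  cat(sprintf("  annual counts    : baseline %d, LCUS %d (+%d repeats), referred %d\n",
              x$counts$n_referred_baseline, x$counts$n_lcus_initial,
              x$counts$n_repeat, x$counts$n_referred_after))
  cat(sprintf("  travel mode      : %s\n", x$travel_mode))
  n_ov <- sum(lengths(x$overrides))
  cat(sprintf("  overrides        : %d component value(s) pinned\n", n_ov))
  invisible(x)
}
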