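.cohort_fields <- c("dist_home_hcc_km", "dist_home_hospital_km",
                    "dist_hcc_hospital_km", "ed_los_min")

#' Cohort simulation parameters
#'
#' Distributional targets for the synthetic suspected-DVT cohort. Defaults
#' emulate the reference cohort of 76 patients referred to hospital:
#' distance from home to the nearest health care centre averaging 16 km
#' (range 1-49 km), from home to the central hospital averaging 85 km
#' (range 30-131 km), and an emergency-department length of stay averaging
#' 212 min (3 h 32 min). The health-care-centre-to-hospital leg, whose
#' distribution is not reported, defaults to the home-to-hospital minus
#' home-to-centre difference perturbed within +/- `hcc_hospital_jitter_km`
#' and clamped to its configured range.
#'
#' @param dist_home_hcc,dist_home_hospital,dist_hcc_hospital Named numeric
#'   triples `c(min=, mean=, max=)` in km; must satisfy min < mean < max.
#' @param ed_los Named numeric `c(mean=, sd=, min=, max=)` in minutes for
#'   the truncated-normal emergency-department stay.
#' @param hcc_hospital_jitter_km Half-width of the uniform perturbation of
#'   the centre-to-hospital leg, km.
#' @param n Number of patients.
#' @param seed Integer seed driving the single pseudo-random stream.
#' @return A `cohort_sim_params` list.
#' @export
cohort_sim_params <- function(dist_home_hcc = c(min = 1, mean = 16, max = 49),
                              dist_home_hospital = c(min = 30, mean = 85, max = 131),
                              dist_hcc_hospital = c(min = 5, mean = 69, max = 125),
                              ed_los = c(mean = 212, sd = 60, min = 30, max = 720),
                              hcc_hospital_jitter_km = 10,
                              n = 76,
                              seed = 1L) {
  p <- list(dist_home_hcc = dist_home_hcc,
            dist_home_hospital = dist_home_hospital,
            dist_hcc_hospital = dist_hcc_hospital,
            ed_los = ed_los,
            hcc_hospital_jitter_km = hcc_hospital_jitter_km,
            n = n, seed = seed)
  viol <- .validate_sim_params(p)
  if (length(viol)) {
    stop(paste(c("invalid simulation parameters:", viol), collapse = "\n  "),
         call. = FALSE)
  }
  structure(p, class = "cohort_sim_params")
}

.validate_sim_params <- function(p) {
  v <- character()
  for (f in c("dist_home_hcc", "dist_home_hospital", "dist_hcc_hospital")) {
    tr <- p[[f]]
    if (!all(c("min", "mean", "max") %in% names(tr))) {
      v <- c(v, sprintf("%s needs named elements min, mean, max", f))
    } else if (!(tr[["min"]] < tr[["mean"]] && tr[["mean"]] < tr[["max"]])) {
      v <- c(v, sprintf("%s must satisfy min < mean < max", f))
    }
  }
  e <- p$ed_los
  if (!all(c("mean", "sd", "min", "max") %in% names(e))) {
    v <- c(v, "ed_los needs named elements mean, sd, min, max")
  } else {
    if (e[["sd"]] <= 0) v <- c(v, "ed_los sd must be > 0")
    if (!(e[["min"]] < e[["mean"]] && e[["mean"]] < e[["max"]])) {
      v <- c(v, "ed_los must satisfy min < mean < max")
    }
  }
  if (p$n < 0 || p$n != round(p$n)) v <- c(v, "n must be a non-negative integer")
  if (p$hcc_hospital_jitter_km < 0) v <- c(v, "hcc_hospital_jitter_km must be >= 0")
  v
}

# Beta on [min, max] with the second shape parameter fixed at 2 and the
# first solved in closed form so that E[X] equals the target mean:
# with mu = (mean - min) / (max - min), a / (a + 2) = mu  =>  a = 2 mu / (1 - mu).
.rbeta_bounded <- function(n, tr) {
  mu <- (tr[["mean"]] - tr[["min"]]) / (tr[["max"]] - tr[["min"]])
  a <- 2 * mu / (1 - mu)
  tr[["min"]] + (tr[["max"]] - tr[["min"]]) * stats::rbeta(n, a, 2)
}

# Truncated normal via inverse-CDF so each record consumes exactly one
# uniform draw (keeps the stream layout stable).
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  pa <- stats::pnorm(lo, mean, sd)
  pb <- stats::pnorm(hi, mean, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mean, sd)
}

#' Simulate a synthetic suspected-DVT cohort
#'
#' Draws `params$n` patient records. Distances use a scaled Beta
#' distribution on the configured \[min, max\] with shapes solved so the
#' expectation hits the target mean; the emergency-department stay is a
#' truncated normal. Fields are drawn in field-major order (all values of
#' one field, then the next) so that adding a field does not reshuffle
#' earlier ones; the caller's RNG state is left untouched.
#'
#' @param params A [cohort_sim_params()] object.
#' @return Data frame with one row per patient and columns
#'   `dist_home_hcc_km`, `dist_home_hospital_km`, `dist_hcc_hospital_km`,
#'   `ed_los_min`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_sim_params(n = 10, seed = 42))
#' colMeans(cohort)
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  n <- as.integer(params$n)
  if (n == 0) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), 4), .cohort_fields))
    return(df)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(params$seed)

  d_hcc <- .rbeta_bounded(n, params$dist_home_hcc)
  d_hosp <- .rbeta_bounded(n, params$dist_home_hospital)
  tr3 <- params$dist_hcc_hospital
  base <- pmax(d_hosp - d_hcc, 0)
  jit <- stats::runif(n, -params$hcc_hospital_jitter_km,
                      params$hcc_hospital_jitter_km)
  d_hh <- pmin(tr3[["max"]], pmax(tr3[["min"]], base + jit))
  e <- params$ed_los
  los <- .rtruncnorm(n, e[["mean"]], e[["sd"]], e[["min"]], e[["max"]])

  data.frame(dist_home_hcc_km = d_hcc,
             dist_home_hospital_km = d_hosp,
             dist_hcc_hospital_km = d_hh,
             ed_los_min = los)
}

.validate_cohort_df <- function(df, where = "cohort") {
  missing <- setdiff(.cohort_fields, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) {
    for (f in .cohort_fields) df[[f]] <- numeric(0)
    return(df[.cohort_fields])
  }
  for (f in .cohort_fields) {
    x <- df[[f]]
    if (!is.numeric(x)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(x)))))
      stop(sprintf("%s: column '%s' is not numeric (first bad row: %d)",
                   where, f, if (length(bad)) bad[1] else 1L), call. = FALSE)
    }
    if (anyNA(x)) {
      stop(sprintf("%s: column '%s' has a missing value at row %d",
                   where, f, which(is.na(x))[1]), call. = FALSE)
    }
    if (any(x < 0)) {
      stop(sprintf("%s: column '%s' has a negative value at row %d",
                   where, f, which(x < 0)[1]), call. = FALSE)
    }
  }
  if (nrow(df) && any(df$ed_los_min <= 0)) {
    stop(sprintf("%s: ed_los_min must be > 0 (row %d)", where,
                 which(df$ed_los_min <= 0)[1]), call. = FALSE)
  }
  df[.cohort_fields]
}

#' Read a patient cohort from CSV
#'
#' Expects a comma-separated file with a header naming the four fields
#' `dist_home_hcc_km`, `dist_home_hospital_km`, `dist_hcc_hospital_km`,
#' `ed_los_min` (decimal point). Values are validated: every field must be
#' numeric and non-negative, and the emergency-department stay strictly
#' positive; violations are reported with the offending column and row.
#'
#' @param path CSV file path.
#' @return Data frame of validated patient records (possibly zero rows).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cohort file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_cohort_df(df, where = sprintf("cohort '%s'", path))
}

#' Write a patient cohort to CSV
#'
#' @param cohort Data frame of patient records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- .validate_cohort_df(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct the standardized patient from a cohort
#'
#' The standardized patient is the field-wise arithmetic mean of the cohort
#' records; all per-patient cost accounting is performed on this synthetic
#' average case.
#'
#' @param records Data frame of patient records (at least one row).
#' @return A `standardized_patient`: list with the four mean fields and
#'   `n_source`, the number of records averaged.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_sim_params(n = 76, seed = 1))
#' standardize(cohort)
standardize <- function(records) {
  records <- .validate_cohort_df(records)
  if (nrow(records) < 1) {
    stop("standardize: need at least one patient record", call. = FALSE)
  }
  sp <- as.list(colMeans(records[.cohort_fields]))
  sp$n_source <- nrow(records)
  structure(sp, class = "standardized_patient")
}

#' @export
print.standardized_patient <- function(x, ...) {
  cat(sprintf("<standardized_patient> mean of %d record(s)\n", x$n_source))
  cat(sprintf("  home -> health care centre : %6.1f km\n", x$dist_home_hcc_km))
  cat(sprintf("  home -> hospital           : %6.1f km\n", x$dist_home_hospital_km))
  cat(sprintf("  centre -> hospital         : %6.1f km\n", x$dist_hcc_hospital_km))
  cat(sprintf("  ED length of stay          : %6.1f min\n", x$ed_los_min))
  invisible(x)
}
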