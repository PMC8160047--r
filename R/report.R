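.log_stage <- function(quiet, stage, detail) {
  if (!quiet) message(sprintf("[dvtcostmin] %-12s %s", stage, detail))
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_config(config, f)
  unname(tools::md5sum(f))
}

# Fixed-format numeric rendering for byte-stable CSV reports.
.fmt2 <- function(x, big_mark = "") {
  formatC(round_cents(x), format = "f", digits = 2, big.mark = big_mark)
}

.comparison_csv_df <- function(tab, extra_rows = NULL, big_mark = "") {
  df <- data.frame(
    component = ifelse(tab$label == "total", "Total costs",
                       unname(.component_titles[tab$label])),
    a = .fmt2(tab$mean_a, big_mark),
    b = .fmt2(tab$mean_b, big_mark),
    difference = .fmt2(tab$difference, big_mark),
    ci_low = .fmt2(tab$ci_low, big_mark),
    ci_high = .fmt2(tab$ci_high, big_mark),
    p = .format_p(tab$p),
    stringsAsFactors = FALSE
  )
  names(df)[2:3] <- c(attr(tab, "pathway_a"), attr(tab, "pathway_b"))
  if (!is.null(extra_rows)) {
    names(extra_rows) <- names(df)
    df <- rbind(df, extra_rows)
  }
  df
}

# The published tables cost the standardized patient: pathway columns and
# the difference column are the model point estimates, while CI and p come
# from the patient-level paired comparison.
.pin_point_estimates <- function(tab, b_a, b_b) {
  stopifnot(identical(tab$label, c(component_labels(), "total")))
  tab$mean_a <- c(b_a$amount, breakdown_total(b_a))
  tab$mean_b <- c(b_b$amount, breakdown_total(b_b))
  tab$difference <- tab$mean_a - tab$mean_b
  tab
}

.comparison_json <- function(tab) {
  list(pathway_a = attr(tab, "pathway_a"),
       pathway_b = attr(tab, "pathway_b"),
       confidence = attr(tab, "confidence"),
       n = attr(tab, "n"),
       rows = as.data.frame(tab))
}

.write_report <- function(obj_csv, obj_json, path_base, format) {
  if (format == "csv") {
    path <- paste0(path_base, ".csv")
    utils::write.csv(obj_csv, path, row.names = FALSE, quote = TRUE)
  } else {
    path <- paste0(path_base, ".json")
    jsonlite::write_json(obj_json, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  path
}

#' Run the full analysis pipeline and emit reports
#'
#' Loads or defaults the configuration, loads or simulates the cohort,
#' then writes four reports plus a run manifest into `out_dir`:
#' the standard-vs-LCUS per-patient comparison with annual totals
#' (`table3`), the standard-vs-real-life comparison with training costs
#' and first-year totals (`table4`), a first-year budget summary
#' (`first_year`), and the raw comparison table (`comparison`). Identical
#' inputs and seed produce byte-identical outputs.
#'
#' @param config A `dvt_config`, a path to a YAML config, or `NULL` for
#'   the defaults.
#' @param cohort A data frame of patient records, a path to a cohort CSV,
#'   or `NULL` to simulate `n` patients with `seed`.
#' @param n Cohort size when simulating.
#' @param seed Simulation seed.
#' @param out_dir Output directory (created if missing).
#' @param format `"csv"` (cent-rounded, fixed format) or `"json"` (full
#'   precision).
#' @param quiet Suppress per-stage log lines on standard error.
#' @return A `run_manifest` list (also written as `manifest.json`).
#' @export
run_all <- function(config = NULL, cohort = NULL, n = 76, seed = 1,
                    out_dir, format = c("csv", "json"), quiet = FALSE) {
  format <- match.arg(format)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir),
                  call. = FALSE)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop(sprintf("output directory '%s' is not writable", out_dir),
         call. = FALSE)
  }

  if (is.null(config)) {
    config <- default_config()
  } else if (is.character(config)) {
    config <- load_config(config)
  }
  .log_stage(quiet, "config", sprintf("hash %s", .config_hash(config)))

  if (is.null(cohort)) {
    cohort_source <- sprintf("simulated(n=%d, seed=%d)", n, as.integer(seed))
    records <- simulate_cohort(cohort_sim_params(n = n, seed = seed))
  } else if (is.character(cohort)) {
    cohort_source <- cohort
    records <- read_cohort_csv(cohort)
  } else {
    cohort_source <- "in-memory"
    records <- .validate_cohort_df(cohort)
  }
  .log_stage(quiet, "cohort", sprintf("%d record(s) from %s",
                                      nrow(records), cohort_source))

  n_year <- config$counts$n_referred_baseline
  tab3 <- .pin_point_estimates(
    comparison_table(records, config, "standard", "lcus"),
    standard_breakdown(config), lcus_breakdown(config))
  tab4 <- .pin_point_estimates(
    comparison_table(records, config, "standard", "real_life"),
    standard_breakdown(config), real_life_breakdown(config))
  scen <- scenario_result(config)
  std_total <- round_cents(breakdown_total(standard_breakdown(config)))
  lcus_total <- round_cents(breakdown_total(lcus_breakdown(config)))
  annual_std <- annual_total(std_total, n_year)
  annual_lcus <- annual_total(lcus_total, n_year)
  .log_stage(quiet, "pathways",
             sprintf("standard %.2f, LCUS %.2f, real-life %.2f EUR/patient",
                     std_total, lcus_total,
                     round_cents(breakdown_total(scen$per_patient))))

  files <- character()
  annual3 <- data.frame(
    component = sprintf("Total costs assuming %d patients per year", n_year),
    a = .fmt2(annual_std), b = .fmt2(annual_lcus),
    difference = .fmt2(annual_std - annual_lcus),
    ci_low = "", ci_high = "", p = "", stringsAsFactors = FALSE)
  files <- c(files, .write_report(
    .comparison_csv_df(tab3, annual3),
    c(.comparison_json(tab3),
      list(annual = list(standard = annual_std, lcus = annual_lcus,
                         difference = annual_std - annual_lcus))),
    file.path(out_dir, "table3"), format))

  tr <- scen$training
  extra4 <- data.frame(
    component = c(sprintf("Total costs assuming %d patients per year", n_year),
                  "Price of education",
                  "Salary of GPs participating in training",
                  "Total education cost",
                  sprintf("Total costs for the first year assuming %d patients per year including one-time training costs", n_year)),
    a = c(.fmt2(annual_std), "0.00", "0.00", "0.00", .fmt2(annual_std)),
    b = c(.fmt2(scen$annual_total), .fmt2(tr$course_fee),
          .fmt2(tr$salary_cost), .fmt2(tr$total),
          .fmt2(scen$first_year_total)),
    difference = c(.fmt2(annual_std - scen$annual_total), "", "", "",
                   .fmt2(annual_std - scen$first_year_total)),
    ci_low = "", ci_high = "", p = "", stringsAsFactors = FALSE)
  files <- c(files, .write_report(
    .comparison_csv_df(tab4, extra4),
    c(.comparison_json(tab4),
      list(annual = list(standard = annual_std,
                         real_life = scen$annual_total),
           training = unclass(tr),
           first_year = list(standard = annual_std,
                             real_life = scen$first_year_total))),
    file.path(out_dir, "table4"), format))

  fy <- data.frame(
    quantity = c("annual_standard", "annual_real_life", "training_total",
                 "first_year_real_life", "first_year_saving"),
    eur = c(.fmt2(annual_std), .fmt2(scen$annual_total), .fmt2(tr$total),
            .fmt2(scen$first_year_total),
            .fmt2(annual_std - scen$first_year_total)),
    stringsAsFactors = FALSE)
  fy_json <- list(annual_standard = annual_std,
                  annual_real_life = scen$annual_total,
                  training_total = tr$total,
                  first_year_real_life = scen$first_year_total,
                  first_year_saving = annual_std - scen$first_year_total)
  files <- c(files, .write_report(fy, fy_json,
                                  file.path(out_dir, "first_year"), format))

  files <- c(files, .write_report(.comparison_csv_df(tab3),
                                  .comparison_json(tab3),
                                  file.path(out_dir, "comparison"), format))

  manifest <- structure(list(
    package = "dvtcostmin",
    version = as.character(utils::packageVersion("dvtcostmin")),
    config_hash = .config_hash(config),
    seed = as.integer(seed),
    cohort_source = cohort_source,
    n_records = nrow(records),
    format = format,
    files = basename(files)
  ), class = "run_manifest")
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  .log_stage(quiet, "reports", sprintf("%d file(s) in %s",
                                       length(files) + 1L, out_dir))
  invisible(manifest)
}
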