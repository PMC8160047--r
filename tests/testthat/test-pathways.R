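test_that("human-capital monetization and travel-time arithmetic", {
  expect_equal(round_cents(monetize(212, 18.70)), 66.07)
  expect_equal(round_cents(monetize(30, 18.70)), 9.35)
  expect_equal(monetize(0, 18.70), 0)
  expect_error(monetize(-1, 18.70), "minutes")
  expect_error(monetize(10, -1), "wage")

  # linearity in both arguments
  expect_equal(monetize(90, 20), 3 * monetize(30, 20))
  expect_equal(monetize(30, 40), 2 * monetize(30, 20))

  expect_equal(travel_time_min(80, 80), 60)
  expect_equal(travel_time_min(0, 80), 0)
  expect_equal(travel_time_min(85, 80), 63.75)
  expect_error(travel_time_min(85, 0), "speed")
  expect_error(travel_time_min(-5, 80), "distance")
})

test_that("standard pathway reproduces the reference per-patient total", {
  cfg <- default_config()
  b <- standard_breakdown(cfg)
  expect_equal(round_cents(breakdown_total(b)), 1151.53)
  expect_equal(round_cents(amt(b, "phc_time")), 9.35)
  expect_equal(round_cents(amt(b, "ed_time")), 66.07)
  expect_equal(amt(b, "ed_price"), 503.45)
  expect_equal(round_cents(amt(b, "travel_time")), 45.43)
  expect_equal(amt(b, "travel_expense"), 361.73)

  # with wage 0 only the pure payments remain
  cfg0 <- cfg
  cfg0$unit_costs$hourly_wage <- 0
  expect_equal(breakdown_total(standard_breakdown(cfg0)),
               96.00 + 28.30 + 361.73 + 503.45 + 41.20)

  expect_equal(breakdown_total(standard_breakdown(zero_config())), 0)
})

test_that("LCUS pathway weights repeat visits by the count ratio", {
  cfg <- default_config()
  b <- lcus_breakdown(cfg)
  expect_equal(round_cents(amt(b, "phc_price")), 139.64)
  expect_equal(round_cents(amt(b, "phc_fee")), 41.16)
  expect_equal(amt(b, "ed_time"), 0)
  expect_equal(amt(b, "ed_price"), 0)
  expect_equal(amt(b, "ed_fee"), 0)
  # full-precision total renders as 301.95 (the cent-rounded component sum)
  expect_equal(round_cents(breakdown_total(b)), 301.95)

  # no-repeat limit: one plain visit
  cfg_nr <- clear_overrides(cfg)
  cfg_nr$counts$n_repeat <- 0L
  b_nr <- lcus_breakdown(cfg_nr)
  expect_equal(amt(b_nr, "phc_price"), 96.00)
  expect_equal(amt(b_nr, "phc_fee"), 28.30)
  expect_equal(amt(b_nr, "phc_time"),
               monetize(cfg$times$phc_visit_lcus_min, cfg$unit_costs$hourly_wage))
})

test_that("payer and cost-class subtotals partition the total", {
  cfg <- default_config()
  cl <- classify(standard_breakdown(cfg))
  expect_equal(round_cents(cl$public), 961.18)
  expect_equal(round_cents(cl$indirect), 120.85)
  expect_equal(cl$public + cl$private, cl$total)
  expect_equal(cl$direct + cl$indirect, cl$total)

  cl0 <- classify(standard_breakdown(zero_config()))
  expect_equal(unlist(cl0), c(public = 0, private = 0, direct = 0,
                              indirect = 0, total = 0))
})

test_that("conservation identities hold on randomized configurations", {
  for (seed in 1:20) {
    cfg <- random_config(seed)
    for (fun in list(standard_breakdown, lcus_breakdown, real_life_breakdown)) {
      b <- fun(cfg)
      expect_equal(sum(b$amount), breakdown_total(b))
      cl <- classify(b)
      expect_equal(cl$public + cl$private, cl$total)
      expect_equal(cl$direct + cl$indirect, cl$total)
    }
  }
})

test_that("costs are monotone in repeat count and unit costs, and LCUS dominates", {
  cfg <- clear_overrides(default_config())
  totals <- vapply(c(0L, 10L, 20L, 44L), function(nr) {
    cfg$counts$n_repeat <- nr
    breakdown_total(lcus_breakdown(cfg))
  }, numeric(1))
  expect_true(all(diff(totals) > 0))

  for (f in c("phc_visit_price", "phc_patient_fee",
              "travel_expense_lcus_visit", "hourly_wage")) {
    lo <- cfg
    hi <- cfg
    hi$unit_costs[[f]] <- hi$unit_costs[[f]] * 2
    expect_gt(breakdown_total(lcus_breakdown(hi)),
              breakdown_total(lcus_breakdown(lo)))
  }

  # doubling the wage doubles every indirect subtotal
  hi <- cfg
  hi$unit_costs$hourly_wage <- 2 * cfg$unit_costs$hourly_wage
  for (fun in list(standard_breakdown, lcus_breakdown, real_life_breakdown)) {
    expect_equal(classify(fun(hi))$indirect, 2 * classify(fun(cfg))$indirect)
  }

  # headline ordering with the defaults
  d <- default_config()
  expect_lt(breakdown_total(lcus_breakdown(d)),
            breakdown_total(standard_breakdown(d)))
})

test_that("mechanistic travel mode derives travel from distances and fares", {
  cfg <- clear_overrides(default_config())
  cfg$travel_mode <- "mechanistic"
  patient <- list(dist_home_hcc_km = 16, dist_home_hospital_km = 85,
                  dist_hcc_hospital_km = 69, ed_los_min = 212)
  b <- standard_breakdown(cfg, patient)
  km <- 2 * 16 + 2 * 85
  expect_equal(amt(b, "travel_expense"), km * cfg$unit_costs$taxi_fare_per_km)
  expect_equal(amt(b, "travel_time"),
               monetize(travel_time_min(km, 80), cfg$unit_costs$hourly_wage))

  bl <- lcus_breakdown(cfg, patient)
  expect_equal(amt(bl, "travel_expense"),
               2 * 16 * cfg$unit_costs$taxi_fare_per_km * (64 / 44))
})
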