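test_that("paired t summary matches hand-computed and stats::t.test oracles", {
  # n = 3, sd = 1, se = 1/sqrt(3), t_crit(0.975, df 2) = 4.302653
  tt <- t_diff(c(1, 2, 3))
  expect_equal(tt$mean, 2)
  expect_equal(tt$ci_low, 2 - 4.30265272991 * (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(tt$ci_high, 2 + 4.30265272991 * (1 / sqrt(3)), tolerance = 1e-9)

  set.seed(42)
  for (n in 2:5) {
    x <- round(rnorm(n, 10, 4), 3)
    got <- t_diff(x, 0.95)
    ref <- t.test(x, conf.level = 0.95)
    expect_equal(got$mean, unname(ref$estimate), tolerance = 1e-9)
    expect_equal(got$ci_low, ref$conf.int[1], tolerance = 1e-9)
    expect_equal(got$ci_high, ref$conf.int[2], tolerance = 1e-9)
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("degenerate difference vectors yield point intervals", {
  tt <- t_diff(c(5, 5, 5, 5))
  expect_equal(tt$mean, 5)
  expect_equal(tt$ci_low, 5)
  expect_equal(tt$ci_high, 5)
  expect_equal(tt$p, 0)  # rendered "<0.001"

  tt0 <- t_diff(c(0, 0))
  expect_equal(c(tt0$mean, tt0$ci_low, tt0$ci_high), c(0, 0, 0))
  expect_equal(tt0$p, 1)

  expect_error(t_diff(numeric(0)), "at least one")
})

test_that("intervals contain the mean and widen monotonically with confidence", {
  set.seed(7)
  x <- rnorm(25, 3, 2)
  widths <- vapply(c(0.80, 0.90, 0.95, 0.99), function(cl) {
    tt <- t_diff(x, cl)
    expect_lte(tt$ci_low, tt$mean)
    expect_gte(tt$ci_high, tt$mean)
    tt$ci_high - tt$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("per-patient cost vectors: constant prices, record-level ED time", {
  cfg <- default_config()
  sp <- tiny_cohort(c(16, 85, 69, 212))
  cv <- per_patient_costs(sp, "standard", cfg)
  expect_equal(cv$totals, breakdown_total(standard_breakdown(cfg)))

  two <- tiny_cohort(c(10, 60, 50, 180), c(10, 60, 50, 180))
  cv2 <- per_patient_costs(two, "standard", cfg)
  expect_equal(cv2$components[1, ], cv2$components[2, ])

  co <- simulate_cohort(cohort_sim_params(n = 40, seed = 5))
  cv3 <- per_patient_costs(co, "standard", cfg)
  expect_equal(rowSums(cv3$components), cv3$totals)
  # prices and fees never vary across patients
  for (lab in c("phc_price", "phc_fee", "ed_price", "ed_fee")) {
    expect_equal(length(unique(cv3$components[, lab])), 1L)
  }
  # monetized hospital time follows each record's own stay
  expect_equal(cv3$components[, "ed_time"],
               monetize(co$ed_los_min, cfg$unit_costs$hourly_wage))

  expect_error(per_patient_costs(co[0, ], "standard", cfg), "at least one")
})

test_that("simulated-cohort mean total stays near the standardized-patient total", {
  cfg <- default_config()
  co <- simulate_cohort(cohort_sim_params(n = 76, seed = 2))
  cv <- per_patient_costs(co, "standard", cfg)
  # only the monetized ED stay varies (sd 60 min -> 18.7 EUR, se ~ 2.1 EUR)
  expect_lt(abs(mean(cv$totals) - breakdown_total(standard_breakdown(cfg))), 7)
})

test_that("comparison table: degenerate rows, paired totals, reference difference", {
  cfg <- default_config()
  co <- simulate_cohort(cohort_sim_params(n = 76, seed = 1))
  tab <- comparison_table(co, cfg)

  const_rows <- tab[tab$label %in% c("phc_price", "phc_fee", "ed_price",
                                     "ed_fee"), ]
  expect_equal(const_rows$ci_low, const_rows$difference)
  expect_equal(const_rows$ci_high, const_rows$difference)

  comp <- tab[tab$label != "total", ]
  tot <- tab[tab$label == "total", ]
  expect_equal(sum(comp$mean_a), tot$mean_a)
  expect_equal(sum(comp$mean_b), tot$mean_b)
  expect_equal(sum(comp$difference), tot$difference)
  expect_true(all(tab$ci_low <= tab$difference + 1e-12) &&
                all(tab$difference <= tab$ci_high + 1e-12))

  point_diff <- breakdown_total(standard_breakdown(cfg)) -
    breakdown_total(lcus_breakdown(cfg))
  expect_lt(abs(tot$difference - point_diff), 7)

  # cohort of identical records: every interval degenerate
  same <- tiny_cohort(c(16, 85, 69, 212), c(16, 85, 69, 212),
                      c(16, 85, 69, 212))
  tab_same <- comparison_table(same, cfg)
  expect_equal(tab_same$ci_low, tab_same$difference)
  expect_equal(tab_same$ci_high, tab_same$difference)
})

test_that("95% intervals achieve nominal coverage over simulated cohorts", {
  cfg <- default_config()
  # true mean difference: all components are constant across patients except
  # the monetized ED stay, whose truth is the truncated-normal mean
  b_std <- standard_breakdown(cfg)
  fixed <- breakdown_total(b_std) - amt(b_std, "ed_time")
  truth <- fixed + monetize(truncnorm_mean(212, 60, 30, 720),
                            cfg$unit_costs$hourly_wage) -
    breakdown_total(lcus_breakdown(cfg))

  n_rep <- 500
  covered <- 0L
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(cohort_sim_params(n = 20, seed = 50000 + r))
    d <- per_patient_costs(co, "standard", cfg)$totals -
      per_patient_costs(co, "lcus", cfg)$totals
    tt <- t_diff(d, 0.95)
    if (tt$ci_low <= truth && truth <= tt$ci_high) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.92)
  expect_lte(covered / n_rep, 0.98)
})
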