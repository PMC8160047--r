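# Shared helpers: component extraction and randomized-but-valid configs.

amt <- function(breakdown, label) {
  breakdown$amount[match(label, breakdown$label)]
}

# A random valid configuration with overrides cleared, for property checks.
random_config <- function(seed) {
  set.seed(seed)
  cfg <- clear_overrides(default_config())
  for (f in names(cfg$unit_costs)) {
    cfg$unit_costs[[f]] <- runif(1, 0, 500)
  }
  cfg$unit_costs$hourly_wage <- runif(1, 1, 50)
  for (f in names(cfg$times)) {
    cfg$times[[f]] <- runif(1, 1, 300)
  }
  n_base <- sample(10:100, 1)
  n_l <- sample(1:n_base, 1)
  cfg$counts$n_referred_baseline <- n_base
  cfg$counts$n_lcus_initial <- n_l
  cfg$counts$n_referred_after <- n_base - n_l
  cfg$counts$n_repeat <- sample(0:n_l, 1)
  cfg
}

# Configuration with every unit cost and visit time set to zero (bypasses
# the user-facing validator on purpose: degenerate limiting case).
zero_config <- function() {
  cfg <- clear_overrides(default_config())
  for (f in names(cfg$unit_costs)) cfg$unit_costs[[f]] <- 0
  for (f in names(cfg$times)) cfg$times[[f]] <- 0
  cfg
}

tiny_cohort <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(dist_home_hcc_km = r[1], dist_home_hospital_km = r[2],
               dist_hcc_hospital_km = r[3], ed_los_min = r[4])
  }))
}

# Mean of a normal(mean, sd) truncated to [lo, hi] -- closed form, used as
# the independent truth for coverage checks on simulated ED stays.
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
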