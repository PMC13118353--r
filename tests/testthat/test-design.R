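test_that("bisection handles trivial brackets without simulating", {
  f_calls <- 0
  f <- function(x) { f_calls <<- f_calls + 1; 50 + x }
  expect_identical(ocutmdd:::bisect_design(f, c(0, 10), target = 0), 0)
  # lower bracket already satisfies the target
  expect_identical(ocutmdd:::bisect_design(function(x) 95, c(2, 10), 90), 2)
  expect_error(ocutmdd:::bisect_design(function(x) 50, c(0, 10), 90),
               "unreachable")
  expect_error(ocutmdd:::bisect_design(f, c(5, 2), 90), "bracket")
})

test_that("optimal release rate agrees with a dense grid scan", {
  crit <- design_criterion()
  f <- function(rate) {
    sch <- build_ivt_schedule(device_spec(rate))
    ocutmdd:::min_red_percent(
      simulate_regimen(phys_default, drug_goli, target_default, sch,
                       horizon_wk = 52), crit)
  }
  bis <- optimize_release_rate(phys_default, drug_goli, target_default,
                               bracket = c(0.05, 1.5))
  oracle <- grid_scan_oracle(f, 0.05, 1.5, 90, by = 0.1)
  expect_lt(abs(bis - oracle), 0.1 + 1e-9)
  # the response is monotone: doubling the optimum keeps the criterion met
  expect_gte(f(2 * bis), 90)
})

test_that("extending the criterion locations never lowers the optimal rate", {
  base_rate <- optimize_release_rate(phys_default, drug_goli, target_default,
                                     bracket = c(0.05, 3))
  strict <- design_criterion(locations = c("AH", "ICB_interstitial",
                                           "ICB_plasma"))
  strict_rate <- optimize_release_rate(phys_default, drug_goli,
                                       target_default, criterion = strict,
                                       bracket = c(0.05, 3))
  expect_gte(strict_rate, base_rate - 1e-9)
})

test_that("failure sweep severity is monotone and rates follow load conservation", {
  dev <- device_spec(1.802)
  fs <- failure_sweep(phys_default, drug_ada, target_default, dev,
                      weeks_early_list = c(0, 1, 4, 10, 16))
  expect_equal(fs$effective_rate_ug_wk,
               round(emptying_rate(1.802, 24, c(0, 1, 4, 10, 16)), 3))
  sev <- as.integer(factor(fs$category, levels = ocutmdd:::OUTCOME_LEVELS,
                           ordered = TRUE))
  expect_true(all(diff(sev) >= 0))
  # nominal device keeps every location below the objective at week 24
  expect_identical(fs$category[1], "all_below_objective")
  # the anterior chamber is the sentinel location once release fails
  expect_identical(fs$triggering_location[fs$weeks_early == 1], "AH")
})

test_that("sensitivity sweep: more synthesis demands faster release", {
  sens <- sensitivity_sweep(phys_default, drug_goli, target_default,
                            parameters = "SF", factors = c(1/2, 2),
                            bracket = c(0.02, 5))
  nominal <- sens$rate_ug_wk[sens$parameter == "nominal"]
  up <- sens$rate_ug_wk[sens$parameter == "SF" & sens$factor == 2]
  down <- sens$rate_ug_wk[sens$parameter == "SF" & sens$factor == 0.5]
  expect_gt(up, nominal)
  expect_lt(down, nominal)
  # weaker binding (larger Kd at fixed koff) never lowers the needed rate
  kd <- sensitivity_sweep(phys_default, drug_goli, target_default,
                          parameters = "Kd_TNF", factors = 10,
                          bracket = c(0.02, 5))
  expect_gte(kd$rate_ug_wk[kd$parameter == "Kd_TNF"], nominal - 1e-9)
})
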