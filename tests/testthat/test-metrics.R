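test_that("percent reduction from pathological levels", {
  expect_identical(red_percent(0.7, 7, 1), 90)
  expect_identical(red_percent(7, 7, 1), 0)
  expect_equal(red_percent(0.679, 7, 1), 90.3)
  expect_identical(red_percent(0, 7, 1), 100)
  # strictly decreasing in the average concentration
  cavg <- seq(0, 7, by = 0.5)
  expect_true(all(diff(red_percent(cavg, 7, 1)) < 0))
  expect_error(red_percent(-1, 7, 1), ">= 0")
})

test_that("fold changes and dose reductions reproduce printed arithmetic", {
  expect_identical(fold_change(2870, 1350), 2.13)
  expect_identical(fold_change(1390, 240), 5.79)
  expect_identical(fold_change(5, 5), 1)
  expect_error(fold_change(1, 0), "positive")
  expect_identical(dose_reduction_percent(661.8, 43.3), 93.5)
  expect_identical(dose_reduction_percent(272.5, 34.6), 87.3)
  expect_identical(dose_reduction_percent(10, 10), 0)
})

test_that("free TNF over free drug ratio is guarded below the drug floor", {
  sim <- simulate_regimen(phys_default, drug_ada, target_default,
                          build_ivt_schedule(device_spec(1.0,
                                                         injection_times = 1)),
                          horizon_wk = 6)
  fr <- free_ratio_series(sim, "AH")
  drg <- sim_series(sim, "AH", "drug")
  tnf <- sim_series(sim, "AH", "tnf_free")
  expect_true(all(is.na(fr$ratio[drg < 1e-6])))
  ok <- drg >= 1e-6
  expect_equal(fr$ratio[ok], tnf[ok] / drg[ok])
  expect_true(any(is.na(fr$ratio)) && any(!is.na(fr$ratio)))
})

test_that("outcome classification thresholds and sentinel location", {
  low <- c(venous_plasma = 0.3, ICB_plasma = 0.3, ICB_interstitial = 0.3,
           AH = 0.5)
  expect_identical(as.character(classify_outcome(low)$category),
                   "all_below_objective")
  one <- c(venous_plasma = 0.3, ICB_plasma = 0.3, ICB_interstitial = 0.3,
           AH = 1.66)
  cls <- classify_outcome(one)
  expect_identical(as.character(cls$category), "first_above_objective")
  expect_identical(cls$triggering_location, "AH")
  above <- c(venous_plasma = 1.2, ICB_plasma = 1.5, ICB_interstitial = 1.1,
             AH = 3)
  expect_identical(as.character(classify_outcome(above)$category),
                   "all_above_baseline")
  path <- c(venous_plasma = 7, ICB_plasma = 7, ICB_interstitial = 7, AH = 7)
  expect_identical(as.character(classify_outcome(path)$category),
                   "all_pathological")
  # tolerance band on the asymptotic pathological plateau
  near <- path - 0.05
  expect_identical(as.character(classify_outcome(near)$category),
                   "all_pathological")
  expect_error(classify_outcome(low[-1]), "venous_plasma")
})

test_that("raising any concentration never lowers the outcome category", {
  set.seed(5)
  for (i in 1:60) {
    x <- stats::setNames(runif(4, 0, 8),
                         c("venous_plasma", "ICB_plasma", "ICB_interstitial",
                           "AH"))
    c1 <- classify_outcome(x)$category
    j <- sample(4, 1)
    x[j] <- x[j] + runif(1, 0, 8 - x[j] + 0.1)
    expect_gte(as.integer(classify_outcome(x)$category), as.integer(c1))
  }
})

test_that("regimen summary reports dose and per-location reductions", {
  sim <- simulate_regimen(phys_default, drug_goli, target_default,
                          build_ivt_schedule(device_spec(0.979)),
                          horizon_wk = 52)
  row <- regimen_summary(sim)
  expect_identical(row$route, "IVT")
  expect_identical(row$n_adm, 2L)
  expect_identical(row$total_dose_ug, 47.0)
  expect_true(all(row[paste0("red_pct_",
                             c("AH", "ICB_interstitial"))] > 90))
})
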