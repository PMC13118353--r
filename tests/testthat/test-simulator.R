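test_that("untreated runs follow the closed-form TNF-alpha relaxation", {
  sim <- simulate_regimen(phys_default, drug_ada, target_default,
                          horizon_wk = 3)
  for (loc in c("venous_plasma", "ICB_plasma", "ICB_interstitial", "AH")) {
    v <- sim_series(sim, loc, "tnf_free")
    pre <- sim$time_h < 0
    expect_equal(max(abs(v[pre] - 1)), 0)
    post <- sim$time_h >= 0
    cf <- 7 - 6 * exp(-0.223 * sim$time_h[post])
    expect_lt(max(abs(v[post] - cf) / cf), 1e-6)
    expect_equal(max(abs(sim_series(sim, loc, "drug"))), 0)
  }
  # SF = 1: permanently flat at baseline
  sf1 <- simulate_regimen(phys_default, drug_ada, target_params(SF = 1),
                          horizon_wk = 2)
  for (loc in c("AH", "ICB_interstitial"))
    expect_equal(max(abs(sim_series(sf1, loc, "tnf_free") - 1)), 0)
})

test_that("isolated venous bolus decays mono-exponentially at CL/V", {
  phys <- phys_closed(CL_sys_mLh = 0.5)
  sch <- ocutmdd:::new_schedule(data.frame(
    time_h = 168, kind = "iv_bolus", amount_ug = 100, rate_ug_wk = NA_real_,
    duration_h = NA_real_))
  sim <- simulate_regimen(phys, drug_inert, target_default, sch,
                          horizon_wk = 6)
  t <- sim$time_h; v <- sim_series(sim, "venous_plasma", "drug")
  after <- t >= 168
  k <- phys$CL_sys / phys$volumes_L[["venous_plasma"]]
  c0 <- ocutmdd:::ug_to_pmol(100, drug_inert$MW) /
    phys$volumes_L[["venous_plasma"]]
  expect_lt(max(abs(v[after] - c0 * exp(-k * (t[after] - 168))) / c0), 1e-6)
})

test_that("trapezoid window averages agree with quadrature closed forms", {
  tm <- ocutmdd:::trapz_mean
  t <- seq(0, 100, by = 0.05)
  expect_equal(tm(t, rep(3.2, length(t)), 10, 90), 3.2)
  # full period of a sinusoid around mean m
  expect_equal(tm(t, 5 + sin(2 * pi * t / 20), 10, 30), 5, tolerance = 1e-4)
  # bolus/first-order-decay sawtooth: analytic interval mean D/V (1-e^{-kT})/(kT)
  k <- 0.15; T_ <- 48
  tt <- seq(0, T_, by = 0.01)
  expect_equal(tm(tt, 10 * exp(-k * tt), 0, T_),
               10 * (1 - exp(-k * T_)) / (k * T_), tolerance = 1e-6)
  expect_error(tm(t, t, 50, 50), "empty")
  expect_error(tm(t, t, 90, 120), "outside")
})

test_that("default steady-state windows follow the regimen structure", {
  expect_equal(steady_state_window(build_iv_soc_schedule(iv_regimen(24.5)), 52),
               c(50, 52))
  expect_equal(steady_state_window(build_ivt_schedule(device_spec(1.802)), 52),
               c(25, 49))
  expect_equal(steady_state_window(empty_schedule(), 52), c(51, 52))
})

test_that("simulation is reproducible and stable under grid refinement", {
  sch <- build_ivt_schedule(device_spec(1.0, injection_times = 1))
  a <- simulate_regimen(phys_default, drug_goli, target_default, sch,
                        horizon_wk = 8)
  b <- simulate_regimen(phys_default, drug_goli, target_default, sch,
                        horizon_wk = 8)
  expect_identical(a$amounts, b$amounts)
  fine <- simulate_regimen(phys_default, drug_goli, target_default, sch,
                           horizon_wk = 8, fine_step_h = 0.5,
                           coarse_step_h = 3)
  for (loc in c("AH", "ICB_interstitial", "venous_plasma")) {
    m1 <- steady_state_average(a, loc, "tnf_free", c(6, 8))
    m2 <- steady_state_average(fine, loc, "tnf_free", c(6, 8))
    expect_lt(abs(m1 - m2) / m2, 1e-3)
  }
})

test_that("events outside the horizon and bad windows are rejected", {
  sch <- build_ivt_schedule(device_spec(1.0))
  expect_error(simulate_regimen(phys_default, drug_goli, target_default, sch,
                                horizon_wk = 10), "within")
  sim <- simulate_regimen(phys_default, drug_goli, target_default,
                          horizon_wk = 2)
  expect_error(steady_state_average(sim, "AH", window_wk = c(1, 5)),
               "outside")
})

test_that("tidy export carries all modelled location/species series", {
  sim <- simulate_regimen(phys_default, drug_ada, target_default,
                          horizon_wk = 2)
  df <- as.data.frame(sim)
  expect_named(df, c("time_h", "compartment", "species", "conc_pM"))
  expect_setequal(unique(df$compartment[df$species == "tnf_free"]),
                  c("venous_plasma", "ICB_plasma", "ICB_interstitial", "AH"))
  expect_setequal(unique(df$compartment[df$species == "drug"]),
                  c("venous_plasma", "ICB_plasma", "ICB_interstitial", "AH",
                    "vitreous"))
  expect_error(sim_series(sim, "vitreous", "tnf_free"), "not modelled")
})
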