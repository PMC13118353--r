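test_that("TNF-alpha turnover vanishes at both steady states", {
  expect_identical(tnf_turnover_rate(1, 1, 0.223, 1), 0)
  expect_identical(tnf_turnover_rate(7, 7, 0.223, 1), 0)
  expect_equal(tnf_turnover_rate(2, 7, 0.223, 1), 1.115)
  expect_error(tnf_turnover_rate(-1, 7, 0.223, 1), ">= 0")
})

test_that("recovery interpolates disease to healthy and stays bounded", {
  p <- modulated_process(10, 4, "AH")
  expect_identical(recovery_value(p, 0), 4)
  expect_identical(recovery_value(p, 1), 10)
  expect_identical(recovery_value(p, 0.5), 7)
  expect_error(recovery_value(p, 1.2), "\\[0, 1\\]")
  set.seed(42)
  for (f in runif(50)) {
    v <- recovery_value(p, f)
    expect_true(v >= 4 && v <= 10)
  }
})

test_that("TMDD fluxes follow mass action with 1:1 stoichiometry", {
  tg <- target_default
  r <- tmdd_rates(0, 5, 3, 2.5e-5, drug_ada, tg)
  expect_identical(unname(r["binding"]), 0)
  expect_equal(unname(r["dissociation"]), drug_ada$koff_TNF * 3)
  r <- tmdd_rates(4, 5, 0, 2.5e-5, drug_ada, tg)
  expect_identical(unname(r["dissociation"]), 0)
  expect_identical(unname(r["degradation"]), 0)
  expect_true(r["binding"] > 0)
  expect_error(tmdd_rates(1, 1, 1, 0, drug_ada, tg), "positive")
})

test_that("binding equilibrium matches the numeric root oracle", {
  # symmetric case: D = T = Kd = 100 pM
  expect_equal(equilibrium_free_target(100, 100, 100), 61.803, tolerance = 1e-4)
  expect_equal(100 - equilibrium_free_target(100, 100, 100), 38.197,
               tolerance = 1e-4)
  set.seed(7)
  for (i in 1:100) {
    D <- runif(1, 0.1, 1000); T_ <- runif(1, 0.1, 1000)
    Kd <- runif(1, 0.1, 500)
    expect_equal(equilibrium_free_target(D, T_, Kd),
                 equilibrium_oracle(D, T_, Kd), tolerance = 1e-9)
  }
})

test_that("release-rate unit bridge matches hand arithmetic", {
  expect_equal(ug_per_week_to_pmol_per_h(1.802, 144190), 0.07439,
               tolerance = 1e-4)
  expect_equal(ug_per_week_to_pmol_per_h(0.979, 146940), 0.03966,
               tolerance = 1e-4)
  expect_identical(ug_per_week_to_pmol_per_h(0, 144190), 0)
  expect_error(ug_per_week_to_pmol_per_h(1, -5), "MW")
})

test_that("assembled derivatives vanish at the two disease-free fixed points", {
  tg <- target_default
  # healthy: SF = 1, baseline TNF, no drug
  y <- ocutmdd:::baseline_state(phys_default, tg, diseased = FALSE)
  pv <- ocutmdd:::rhs_parms(phys_default, drug_ada, tg, sf = 1,
                            disease_active = FALSE, release_pmol_h = 0)
  expect_equal(max(abs(ocular_rhs_r(0, y, pv)[[1]])), 0)
  # pathological plateau: SF = 7, TNF at 7 pM everywhere, no drug
  y7 <- ocutmdd:::baseline_state(phys_default, tg, diseased = TRUE)
  pv7 <- ocutmdd:::rhs_parms(phys_default, drug_ada, tg, sf = 7,
                             disease_active = TRUE, release_pmol_h = 0)
  d7 <- ocular_rhs_r(10, y7, pv7)[[1]]
  expect_equal(max(abs(d7[6:13])), 0)
})

test_that("drug bookkeeping: transport cancels, only input/clearance/complex loss remain", {
  tg <- target_default
  set.seed(11)
  for (i in 1:25) {
    y <- runif(13) * rep(c(1, 0.01, 0.01), c(5, 4, 4))
    rel <- runif(1, 0, 0.1)
    pv <- ocutmdd:::rhs_parms(phys_default, drug_ada, tg, sf = 7,
                              disease_active = TRUE, release_pmol_h = rel)
    dy <- ocular_rhs_r(50, y, pv)[[1]]
    total_drug_rate <- sum(dy[1:5]) + sum(dy[10:13])
    expected <- rel - phys_default$CL_sys * y[1] / phys_default$volumes_L[[1]] -
      tg$kdeg_complex * sum(y[10:13])
    scale <- sum(abs(dy[1:5])) + abs(expected) + 1e-6
    expect_lt(abs(total_drug_rate - unname(expected)) / scale, 1e-12)
  }
})

test_that("compiled and reference right-hand sides integrate identically", {
  sch <- build_iv_soc_schedule(iv_regimen(24.5, horizon = 6))
  s_c <- simulate_regimen(phys_default, drug_ada, target_default, sch,
                          horizon_wk = 6)
  s_r <- simulate_regimen(phys_default, drug_ada, target_default, sch,
                          horizon_wk = 6, engine = "r")
  scale <- apply(abs(s_c$amounts), 2, max)
  diff <- max(abs(s_c$amounts - s_r$amounts) /
                rep(scale, each = nrow(s_c$amounts)))
  expect_lt(diff, 1e-5)
})
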