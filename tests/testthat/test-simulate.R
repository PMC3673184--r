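test_that("zero exposure stays at zero everywhere", {
  p <- test_params()
  sim <- simulate_cd(constant_profile(0, 20), "male", p)
  expect_equal(sim$ucd, rep(0, length(sim$ucd)))
  expect_equal(unname(unclass(sim$state)), rep(0, 9))
  expect_equal(mass_balance(sim), 0)
})

test_that("one absorption step splits intake by the gut fraction", {
  p <- test_params()
  st <- step_day(compartment_state(), 100, 0, p, "male")
  expect_equal(st[["B1"]], 5.0)          # 5% absorbed
  expect_equal(st[["cum_feces"]], 95.0)  # unabsorbed remainder
  stf <- step_day(compartment_state(), 100, 0, p, "female")
  expect_equal(stf[["B1"]], 10.0)

  # inhaled: lung absorption + mucociliary-to-gut + exhaled remainder
  si <- step_day(compartment_state(), 0, 10, p, "male")
  expect_equal(si[["B1"]], 10 * (0.14 + 0.05 * 0.05))
  expect_equal(si[["cum_exhaled"]], 10 * (1 - 0.14 - 0.05))
})

test_that("the daily update is linear in state and intake", {
  p <- test_params()
  st <- compartment_state(B1 = 3, B2 = 1, B3 = 2, L = 40, K = 80, T = 10)
  once <- step_day(st, 7, 2, p, "female")
  twice <- step_day(compartment_state(B1 = 6, B2 = 2, B3 = 4, L = 80,
                                      K = 160, T = 20), 14, 4, p, "female")
  expect_equal(unclass(twice), 2 * unclass(once), tolerance = 1e-14)
})

test_that("simulate_cd agrees with iterated step_day", {
  p <- test_params()
  nd <- 400
  prof <- exposure_profile(rep(30, nd), rep(2, nd), nd / 365)
  sim <- simulate_cd(prof, "male", p)
  st <- compartment_state()
  for (i in seq_len(nd)) st <- step_day(st, 30, 2, p, "male")
  expect_equal(unclass(sim$state), unclass(st), tolerance = 1e-12)
})

test_that("outputs scale exactly with exposure (degree-1 homogeneity)", {
  p <- test_params()
  s1 <- simulate_cd(constant_profile(27, 35, inhaled = 3), "female", p)
  s2 <- simulate_cd(constant_profile(54, 35, inhaled = 6), "female", p)
  expect_equal(s2$ucd, 2 * s1$ucd, tolerance = 1e-12)
  expect_equal(unclass(s2$state), 2 * unclass(s1$state), tolerance = 1e-12)
})

test_that("urinary cadmium rises with age under constant intake", {
  p <- test_params()
  prof <- build_profile(dietary_scenario(100, "MaeSot", "male", 60),
                        params = p)
  sim <- simulate_cd(prof, params = p)
  yearly <- vapply(20:60, function(a) {
    mean(sim$ucd[sim$age_years > a - 1 & sim$age_years <= a])
  }, numeric(1))
  expect_true(all(diff(yearly) > 0))
  expect_gt(cd_gain(50, "male", params = p), cd_gain(30, "male", params = p))
})

test_that("urinary cadmium is strictly increasing in dietary intake", {
  p <- test_params()
  ucd <- vapply(c(10, 50, 100, 200, 300), function(x) {
    simulate_cd(build_profile(dietary_scenario(x, "MaeSot", "male", 50),
                              params = p), params = p)$ucd_final
  }, numeric(1))
  expect_true(all(diff(ucd) > 0))
})

test_that("mass balance closes to 1e-9 on arbitrary exposure histories", {
  p <- test_params()
  sim <- simulate_cd(constant_profile(100, 50), "male", p)
  expect_lt(mass_balance(sim), 1e-9)
  set.seed(42)
  for (rep in 1:5) {
    nd <- round(stats::runif(1, 5, 45) * 365)
    prof <- exposure_profile(stats::runif(nd, 0, 300),
                             stats::runif(nd, 0, 20), nd / 365)
    sim <- simulate_cd(prof, sample(c("male", "female"), 1), p,
                       keep_trajectory = FALSE)
    expect_lt(mass_balance(sim), 1e-9)
  }
})

test_that("degenerate single-pathway model matches the analytic solution", {
  lambda <- 1e-4
  p <- single_pool_params(lambda)
  A <- p$absorption_gut[["male"]]
  r <- 100
  t <- 50 * 365
  sim <- simulate_cd(constant_profile(r, 50), "male", p,
                     keep_trajectory = FALSE)
  expected <- A * r * (t - (1 - exp(-lambda * t)) / lambda)
  expect_equal(sim$state[["cum_urine"]], expected, tolerance = 1e-3)
})

test_that("gain is the urinary cadmium per unit intake", {
  p <- test_params()
  g30f <- cd_gain(30, "female", params = p)
  for (intake in c(1, 27, 224)) {
    ucd <- simulate_cd(build_profile(
      dietary_scenario(intake, "MaeSot", "female", 30), params = p),
      params = p)$ucd_final
    expect_equal(ucd, g30f * intake, tolerance = 1e-9)
  }
  # higher gut absorption and lower creatinine make the female gain larger
  expect_gt(g30f, cd_gain(30, "male", params = p))
})

test_that("trajectory export writes the documented columns", {
  p <- test_params()
  sim <- simulate_cd(constant_profile(50, 2), "male", p)
  f <- tempfile(fileext = ".csv")
  export_trajectory(sim, f)
  df <- read.csv(f)
  expect_named(df, c("age_days", "B1", "B2", "B3", "L", "K", "T",
                     "urine_ug_day", "ucd_ug_per_g_creatinine"))
  expect_equal(nrow(df), 730)
})
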