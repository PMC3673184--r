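test_that("anchoring pins the gain to the anchor pair and is idempotent", {
  p <- anchored_bkk_male()
  expect_equal(cd_gain(30, "male", "Bangkok", p), 0.33 / 56,
               tolerance = 1e-12)
  p2 <- anchor_scale(p, 56, 0.33, 30, "male", "Bangkok")
  expect_equal(p2$gain_scale, p$gain_scale, tolerance = 1e-12)
  expect_error(anchor_scale(p, -1, 0.33, 30, "male", "Bangkok"), "positive")

  # inverse consistency: calibrating the anchor U-Cd returns the intake
  back <- calibrate_dietary_intake(0.33, 30, "male", "Bangkok", p)
  expect_equal(as.numeric(back), 56, tolerance = 1e-9)
})

test_that("dietary calibration round-trips through the forward model", {
  p <- anchored_bkk_male()
  expect_equal(as.numeric(calibrate_dietary_intake(0, 50, "male",
                                                   "Bangkok", p)), 0)
  for (y in c(0.33, 1.04, 3.07)) {
    intake <- calibrate_dietary_intake(y, 50, "male", "Bangkok", p)
    expect_equal(attr(intake, "predicted_ucd"), y, tolerance = 1e-6)
    expect_equal(attr(intake, "iterations"), 1L)  # one-step linear inverse
  }
  expect_error(calibrate_dietary_intake(-1, 50, "male", "Bangkok", p),
               "non-negative")
})

test_that("calibration recovers known intakes to 0.1%", {
  p <- test_params()
  set.seed(2024)
  truth <- stats::runif(100, 5, 300)
  for (x in truth) {
    ucd <- simulate_cd(build_profile(
      dietary_scenario(x, "MaeSot", "female", 50), params = p),
      params = p, keep_trajectory = FALSE)$ucd_final
    est <- as.numeric(calibrate_dietary_intake(ucd, 50, "female", NULL, p))
    expect_equal(est, x, tolerance = 1e-3)
  }
})

test_that("the inverse is monotone in the target", {
  p <- anchored_bkk_male()
  intakes <- vapply(c(0.1, 0.5, 1, 2, 5), function(y) {
    as.numeric(calibrate_dietary_intake(y, 50, "male", "Bangkok", p))
  }, numeric(1))
  expect_true(all(diff(intakes) > 0))
})

test_that("smoking calibration matches its forward prediction", {
  p <- anchored_bkk_male()
  # target below the dietary-only prediction: zero packs, warned
  expect_warning(
    pk0 <- calibrate_packs(0.05, 56, 30, "male", "Bangkok", params = p),
    "dietary-only")
  expect_equal(as.numeric(pk0), 0)

  pk <- calibrate_packs(0.92, 50, 50, "male", "Bangkok", params = p)
  expect_equal(attr(pk, "predicted_ucd"), 0.92, tolerance = 1e-6)
  # the published smoking-rate estimate for this group is 3.7 packs/day
  expect_equal(as.numeric(pk), 3.7, tolerance = 0.1)

  # linearity: doubling the urinary excess doubles the packs
  base <- attr(pk, "ucd_diet")
  pk2 <- calibrate_packs(base + 2 * (0.92 - base), 50, 50, "male",
                         "Bangkok", params = p)
  expect_equal(as.numeric(pk2), 2 * as.numeric(pk), tolerance = 1e-9)
})

test_that("nonlinear kidney-damage hook falls back to verified bisection", {
  p <- anchored_bkk_male()
  p$kidney_damage <- list(enabled = TRUE, threshold_ug = 3000, factor = 3)
  intake <- calibrate_dietary_intake(0.49, 50, "male", "Bangkok", p)
  expect_equal(attr(intake, "predicted_ucd"), 0.49, tolerance = 1e-6)
  expect_gt(attr(intake, "iterations"), 1L)
})

test_that("intake tables are reproduced for calibratable groups only", {
  tab <- reproduce_intake_tables(thai_ucd_table())
  # groups below the size cutoff are omitted (e.g. Bangkok male 13-19)
  expect_false(any(tab$age_band == "13-19" & tab$locality == "Bangkok"))
  expect_equal(nrow(tab[tab$smoking_category == "never", ]), 12)

  # published Mae Sot male dietary series, within the anchored-model band
  msm <- tab[tab$locality == "MaeSot" & tab$sex == "male" &
               tab$smoking_category == "never", ]
  msm <- msm[order(match(msm$age_band, c("13-19", "20-39", "40-59", "60+"))), ]
  published <- c(234, 224, 188, 167)
  expect_true(all(abs(msm$diet_ug_day - published) / published < 0.25))

  # smoker rows carry the per-pack dose product
  smk <- tab[tab$smoking_category != "never", ]
  expect_true(all(!is.na(smk$packs_per_day)))
  expect_true(all(smk$smoking_ug_day > 0))
})

test_that("an all-zero summary table calibrates to zero intake", {
  sm <- data.frame(locality = "Bangkok", sex = "male",
                   age_band = c("20-39", "40-59"),
                   smoking_category = "never", n = c(85, 31), gm = 0)
  tab <- reproduce_intake_tables(sm)
  expect_equal(tab$diet_ug_day, c(0, 0))
})
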