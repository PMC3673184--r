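test_that("the packaged survey spec reproduces the published structure", {
  spec <- thai_survey_spec()
  cells <- spec$cells
  tot <- tapply(cells$n, cells$locality, sum)
  expect_equal(unname(tot[["Bangkok"]]), 399)
  expect_equal(unname(tot[["MaeSot"]]), 6747)

  # heavy-smoker fraction of Mae Sot males is 42.7%
  msm <- cells[cells$locality == "MaeSot" & cells$sex == "male", ]
  expect_equal(100 * sum(msm$n[msm$smoking_category == "heavy"]) / sum(msm$n),
               42.7, tolerance = 0.01)

  # Bangkok has no female smokers
  bf <- cells[cells$locality == "Bangkok" & cells$sex == "female", ]
  expect_true(all(bf$smoking_category == "never"))

  # published per-cell group sizes are preserved
  expect_equal(cells$n[cells$locality == "MaeSot" & cells$sex == "female" &
                         cells$age_band == "40-59" &
                         cells$smoking_category == "never"], 1394L)
})

test_that("generated cohorts match their cell parameterization", {
  spec <- cohort_spec(data.frame(
    locality = "MaeSot", sex = "female", age_band = "all",
    smoking_category = "never", n = 3726, gm = 2.10, sd = 2.91))
  coh <- generate_cohort(spec, seed = 1)
  expect_equal(nrow(coh), 3726)
  expect_equal(geometric_mean(coh$ucd_ug_per_g), 2.10, tolerance = 0.03)
  expect_true(all(coh$age >= 13 & coh$age <= 92))
  expect_true(all(coh$ucd_ug_per_g > 0))
})

test_that("cigarette counts respect the smoking-category bands", {
  spec <- cohort_spec(data.frame(
    locality = "MaeSot", sex = "male", age_band = "40-59",
    smoking_category = c("never", "light_moderate", "heavy"),
    n = c(50, 50, 50), gm = 2, sd = 2))
  coh <- generate_cohort(spec, seed = 3)
  cig <- function(cat) coh$cigarettes_per_day[coh$smoking_category == cat]
  expect_true(all(cig("never") == 0))
  expect_true(all(cig("light_moderate") >= 10 & cig("light_moderate") <= 25))
  expect_true(all(cig("heavy") >= 26 & cig("heavy") <= 80))
  expect_equal(coh$packs_per_day, coh$cigarettes_per_day / 20)
})

test_that("generation is deterministic in the seed and restores RNG state", {
  spec <- thai_survey_spec()
  set.seed(777)
  before <- stats::runif(1)
  set.seed(777)
  c1 <- generate_cohort(spec, seed = 10)
  after <- stats::runif(1)
  expect_equal(before, after)   # caller's stream untouched

  c2 <- generate_cohort(spec, seed = 10)
  expect_identical(c1, c2)
  c3 <- generate_cohort(spec, seed = 11)
  expect_false(identical(c1$ucd_ug_per_g, c3$ucd_ug_per_g))
})

test_that("cohort files regenerate byte-identically from the recorded seed", {
  spec <- cohort_spec(data.frame(
    locality = "Bangkok", sex = "male", age_band = "20-39",
    smoking_category = "never", n = 200, gm = 0.33, sd = 0.36), seed = 5)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(spec), f1)
  meta <- yaml::read_yaml(paste0(f1, ".meta.yaml"))
  write_cohort(generate_cohort(spec, seed = meta$seed), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("empty cells and optional censoring behave", {
  spec <- cohort_spec(data.frame(
    locality = "Bangkok", sex = "male", age_band = "20-39",
    smoking_category = "never", n = 0, gm = 1, sd = 1))
  expect_equal(nrow(generate_cohort(spec, seed = 1)), 0)

  spec2 <- cohort_spec(data.frame(
    locality = "Bangkok", sex = "male", age_band = "20-39",
    smoking_category = "never", n = 500, gm = 0.1, sd = 0.2))
  coh <- generate_cohort(spec2, seed = 2, lod_ug_per_g = 0.05)
  expect_true(any(coh$censored))
  expect_equal(unique(coh$ucd_ug_per_g[coh$censored]), 0.05 / sqrt(2))
})
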