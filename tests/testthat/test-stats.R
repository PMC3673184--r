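test_that("detection-limit substitution replaces only values below the LOD", {
  expect_equal(lod_substitute(0.02), 0.05 / sqrt(2))
  expect_equal(lod_substitute(0.40), 0.40)
  expect_equal(lod_substitute(0.05), 0.05)   # at the LOD: unchanged
  expect_error(lod_substitute(-0.1), "non-negative")
})

test_that("geometric mean matches its definition and bounds", {
  expect_equal(geometric_mean(c(1, 10, 100)), 10)
  expect_equal(geometric_mean(rep(2.7, 5)), 2.7)
  expect_error(geometric_mean(c(1, 0)), "positive")
  set.seed(11)
  x <- exp(stats::rnorm(1e5, log(2.10), 0.8))
  expect_equal(geometric_mean(x), 2.10, tolerance = 0.01)
  # GM <= arithmetic mean, equality only for constant samples
  for (i in 1:20) {
    y <- exp(stats::rnorm(50, 0, stats::runif(1, 0.1, 1)))
    expect_lte(geometric_mean(y), mean(y))
  }
})

test_that("GM/SD inversion yields a lognormal with those moments", {
  par <- lognormal_from_gm_sd(0.40, 0.46)
  expect_equal(par$mu, log(0.40))
  expect_equal(par$sigma, 0.7495, tolerance = 1e-3)
  expect_equal(lognormal_from_gm_sd(3, 0)$sigma, 0)
  expect_error(lognormal_from_gm_sd(0, 1), "positive")

  # closed form: arithmetic SD of the implied lognormal equals the input
  for (case in list(c(0.40, 0.46), c(2.10, 2.91), c(1.65, 2.40))) {
    par <- lognormal_from_gm_sd(case[1], case[2])
    implied_var <- (exp(par$sigma^2) - 1) * exp(2 * par$mu + par$sigma^2)
    expect_equal(sqrt(implied_var), case[2], tolerance = 1e-12)
  }

  # Monte-Carlo round trip
  set.seed(5)
  par <- lognormal_from_gm_sd(2.10, 2.91)
  x <- exp(stats::rnorm(1e6, par$mu, par$sigma))
  expect_equal(geometric_mean(x), 2.10, tolerance = 0.01)
  expect_equal(stats::sd(x), 2.91, tolerance = 0.03)
})

test_that("threshold exceedance is inclusive and matches the analytic tail", {
  expect_equal(pct_over_threshold(c(0.1, 0.2), 1), 0)
  expect_equal(pct_over_threshold(c(1, 1, 1), 1), 100)
  set.seed(8)
  par <- lognormal_from_gm_sd(2.10, 2.91)
  x <- exp(stats::rnorm(2e5, par$mu, par$sigma))
  analytic <- 100 * (1 - stats::pnorm((log(5) - par$mu) / par$sigma))
  expect_equal(pct_over_threshold(x, 5), analytic, tolerance = 0.05)
})

test_that("two-group comparisons pick the right test and detect shifts", {
  set.seed(3)
  a <- exp(stats::rnorm(200, 0, 0.7))
  res_null <- compare_groups(c(a, a), rep(c("g1", "g2"), each = 200))
  expect_false(res_null$significant)

  b <- 10 * exp(stats::rnorm(200, 0, 0.7))
  res_shift <- compare_groups(c(a, b), rep(c("g1", "g2"), each = 200))
  expect_true(res_shift$significant)
  expect_match(res_shift$method, "t-test|Mann-Whitney")
  expect_equal(nrow(res_shift$normality), 2)
})

test_that("multi-group comparison runs Dunnett against the reference", {
  set.seed(4)
  base <- exp(stats::rnorm(60, 0, 0.5))
  vals <- c(base, base * 1.02, base * 8, base * 9)
  grp <- rep(c("never", "former", "light", "heavy"), each = 60)
  res <- compare_groups(vals, grp, reference = "never")
  expect_equal(nrow(res$comparisons), 3)   # k - 1 comparisons
  expect_match(res$method, "Dunnett")
  sig <- res$comparisons$significant[
    grepl("light|heavy", res$comparisons$comparison)]
  expect_true(all(sig))
})

test_that("degenerate zero-variance groups are reported, not fatal", {
  vals <- c(rep(1, 10), stats::rlnorm(10))
  res <- compare_groups(vals, rep(c("a", "b"), each = 10))
  expect_true(is.na(res$normality$p_raw[res$normality$group == "a"]))
  expect_s3_class(res, "cd_group_test")
})

test_that("smoker-to-never ratios reproduce the published calculus", {
  ucd <- thai_ucd_table()
  rr <- ratio_report(ucd)
  pick <- function(loc, sx, band, cat) {
    rr$ratio[rr$locality == loc & rr$sex == sx & rr$age_band == band &
               rr$smoking_category == cat]
  }
  expect_equal(pick("Bangkok", "male", "40-59", "light_moderate"), 1.9)
  expect_equal(pick("MaeSot", "male", "40-59", "heavy"), 1.4)
  expect_equal(pick("MaeSot", "male", "60+", "heavy"), 1.5)
  # identical groups give ratio 1
  same <- data.frame(locality = "x", sex = "male", age_band = "20-39",
                     smoking_category = c("never", "heavy"), gm = c(2, 2))
  expect_equal(ratio_report(same)$ratio, 1.0)
  expect_error(ratio_report(same[2, ]), "reference")
})

test_that("cohort summaries compute group size, GM, SD and exceedances", {
  set.seed(9)
  coh <- data.frame(locality = "MaeSot", sex = "female",
                    age_band = rep(c("20-39", "40-59"), each = 500),
                    smoking_category = "never",
                    ucd_ug_per_g = stats::rlnorm(1000, log(2), 0.8))
  sm <- summarize_cohort(coh)
  expect_equal(nrow(sm), 2)
  expect_equal(sm$n, c(500, 500))
  expect_equal(sm$gm, c(
    geometric_mean(coh$ucd_ug_per_g[1:500]),
    geometric_mean(coh$ucd_ug_per_g[501:1000])))
  expect_true(all(sm$pct_ge_1 > sm$pct_ge_5))
})
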