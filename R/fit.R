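# The model-fitting surface: anchored reverse dosimetry over a table of
# group summaries, in the style of a classed fit with standard methods.

.BAND_AGES <- c("13-19" = 16, "20-39" = 30, "40-59" = 50, "60+" = 70)
.BAND_LOW <- c("13-19" = 13, "20-39" = 20, "40-59" = 40, "60+" = 60)

#' Fit group exposures by anchored reverse dosimetry
#'
#' The central estimator.  Given a table of group summaries (locality, sex,
#' age band, smoking category, group size `n` and geometric-mean urinary
#' cadmium `gm` in ug/g creatinine), the fit
#' \enumerate{
#'   \item anchors the model gain of each (locality, sex) group on a known
#'     (dietary intake, urinary cadmium) pair for the anchor age band,
#'   \item calibrates the dietary intake (ug/day) reproducing the measured
#'     geometric mean of every never-smoker group, and
#'   \item calibrates the smoking rate (packs/day) of current-smoker
#'     groups, taking the matched never-smoker dietary estimate as the
#'     smokers' dietary background.
#' }
#' Each age band is evaluated at its midpoint (16, 30, 50 and 70 years for
#' 13-19, 20-39, 40-59 and 60+).  Groups with fewer than `min_n` subjects
#' are skipped.  Dietary intakes are reported at 1 ug/day resolution and
#' smoking rates at 0.1 packs/day (full precision is kept in `coef()`).
#'
#' @param summaries Data frame with columns `locality`, `sex`, `age_band`,
#'   `smoking_category`, `n`, `gm` (and optionally `sd`).
#' @param anchors Data frame with columns `locality`, `sex`, `intake`
#'   giving the known dietary intake (ug/day) for the anchor band.  The
#'   default uses the packaged Thai survey estimates for the 20-39 band.
#' @param params A `cd_params` object.
#' @param anchor_band Age band of the anchor pair (default `"20-39"`).
#' @param band_ages Named vector mapping age bands to evaluation ages.
#' @param smoker_categories Named character vector mapping locality to the
#'   current-smoker category calibrated there (Bangkok light-to-moderate,
#'   Mae Sot heavy; these are the categories with usable group sizes).
#' @param min_n Minimum group size for calibration (default 5).
#' @return An object of class `cd_reverse_fit` with `print()`,
#'   `summary()`, `coef()`, `fitted()`, `residuals()`, `predict()` and
#'   `plot()` methods.
#' @examples
#' \donttest{
#' fit <- cd_reverse_fit(thai_ucd_table())
#' coef(fit)
#' summary(fit)
#' }
#' @export
cd_reverse_fit <- function(summaries,
                           anchors = thai_anchor_intakes(),
                           params = default_parameters(),
                           anchor_band = "20-39",
                           band_ages = .BAND_AGES,
                           smoker_categories = c(Bangkok = "light_moderate",
                                                 MaeSot = "heavy"),
                           min_n = 5) {
  req <- c("locality", "sex", "age_band", "smoking_category", "n", "gm")
  missing_cols <- setdiff(req, names(summaries))
  if (length(missing_cols)) {
    stop("summaries is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_band <- setdiff(unique(summaries$age_band), names(band_ages))
  if (length(bad_band)) stop("unknown age band: ", bad_band[[1]])

  groups <- unique(summaries[, c("locality", "sex")])
  never <- summaries[summaries$smoking_category == "never", ]

  # 1. anchor each (locality, sex) on its anchor-band never-smoker pair
  for (i in seq_len(nrow(groups))) {
    loc <- groups$locality[i]; sx <- groups$sex[i]
    a <- anchors[anchors$locality == loc & anchors$sex == sx, ]
    nv <- never[never$locality == loc & never$sex == sx &
                  never$age_band == anchor_band, ]
    if (nrow(a) == 1 && nrow(nv) == 1 && a$intake > 0 && nv$gm > 0) {
      params <- anchor_scale(params, a$intake, nv$gm,
                             band_ages[[anchor_band]], sx, loc)
    }
  }

  # 2. dietary calibration for never-smoker groups
  usable <- never[!is.na(never$n) & never$n >= min_n, ]
  diet <- usable[, c("locality", "sex", "age_band", "n", "gm")]
  diet$age <- unname(band_ages[diet$age_band])
  diet$intake_exact <- NA_real_
  for (i in seq_len(nrow(diet))) {
    diet$intake_exact[i] <- as.numeric(calibrate_dietary_intake(
      diet$gm[i], diet$age[i], diet$sex[i], diet$locality[i], params))
  }
  diet$diet_ug_day <- round(diet$intake_exact)

  # 3. smoking calibration for current-smoker groups
  cat_for <- unname(smoker_categories[summaries$locality])
  keep <- !is.na(cat_for) & summaries$smoking_category == cat_for &
    !is.na(summaries$n) & summaries$n >= min_n
  smoking <- summaries[keep, c("locality", "sex", "age_band",
                               "smoking_category", "n", "gm")]
  smoking$age <- unname(band_ages[smoking$age_band])
  smoking$background_ug_day <- rep(NA_real_, nrow(smoking))
  smoking$packs_exact <- rep(NA_real_, nrow(smoking))
  smoking$ucd_diet <- rep(NA_real_, nrow(smoking))
  for (i in seq_len(nrow(smoking))) {
    bg <- diet[diet$locality == smoking$locality[i] &
                 diet$sex == smoking$sex[i] &
                 diet$age_band == smoking$age_band[i], ]
    if (nrow(bg) != 1) {
      stop("missing never-smoker dietary background for smoker group ",
           smoking$locality[i], " ", smoking$sex[i], " ",
           smoking$age_band[i])
    }
    smoking$background_ug_day[i] <- bg$intake_exact
    # smokers already smoking in the youngest band started before the
    # default initiation age; assume the band's lower bound
    start_i <- min(params$smoking_start_age,
                   .BAND_LOW[[smoking$age_band[i]]])
    p <- suppressWarnings(calibrate_packs(
      smoking$gm[i], bg$intake_exact, smoking$age[i], smoking$sex[i],
      smoking$locality[i], start_age = start_i, params = params))
    smoking$packs_exact[i] <- as.numeric(p)
    smoking$ucd_diet[i] <- attr(p, "ucd_diet")
  }
  smoking$packs_per_day <- round(smoking$packs_exact, 1)
  smoking$cd_per_pack <- vapply(smoking$locality, cd_per_pack,
                                numeric(1), params = params,
                                USE.NAMES = FALSE)
  smoking$smoking_ug_day <- round(
    smoking_cd_dose(smoking$packs_per_day, smoking$cd_per_pack), 1)

  # fitted values from the rounded, reported estimates
  diet$fitted_ucd <- vapply(seq_len(nrow(diet)), function(i) {
    diet$diet_ug_day[i] *
      cd_gain(diet$age[i], diet$sex[i], diet$locality[i], params)
  }, numeric(1))
  smoking$fitted_ucd <- vapply(seq_len(nrow(smoking)), function(i) {
    if (smoking$packs_exact[i] == 0) return(smoking$ucd_diet[i])
    marginal <- (smoking$gm[i] - smoking$ucd_diet[i]) / smoking$packs_exact[i]
    smoking$ucd_diet[i] + smoking$packs_per_day[i] * marginal
  }, numeric(1))

  out <- list(call = match.call(),
              params = params,
              anchors = anchors,
              anchor_band = anchor_band,
              band_ages = band_ages,
              diet = diet,
              smoking = smoking)
  class(out) <- "cd_reverse_fit"
  out
}

#' Anchor intakes from the packaged Thai survey tables
#'
#' Dietary intakes (ug/day) of the 20-39-year-old never-smoker groups used
#' as anchor pairs, one per (locality, sex).
#'
#' @return Data frame with columns `locality`, `sex`, `intake`.
#' @export
thai_anchor_intakes <- function() {
  di <- thai_diet_table()
  a <- di[di$age_band == "20-39", c("locality", "sex", "diet_ug_day")]
  names(a)[3] <- "intake"
  rownames(a) <- NULL
  a
}

#' Reproduce the dietary-intake and smoking-rate tables
#'
#' Convenience wrapper around [cd_reverse_fit()] returning one combined
#' table: dietary intake (ug/day) per never-smoker group and packs/day
#' plus the smoking cadmium dose (ug/day) per current-smoker group.
#'
#' @inheritParams cd_reverse_fit
#' @param ... Passed on to [cd_reverse_fit()].
#' @return Data frame with one row per calibrated group.
#' @export
reproduce_intake_tables <- function(summaries,
                                    anchors = thai_anchor_intakes(),
                                    params = default_parameters(), ...) {
  fit <- cd_reverse_fit(summaries, anchors, params, ...)
  d <- fit$diet
  d$smoking_category <- rep("never", nrow(d))
  d$packs_per_day <- rep(NA_real_, nrow(d))
  d$smoking_ug_day <- rep(NA_real_, nrow(d))
  s <- fit$smoking
  s$diet_ug_day <- rep(NA_real_, nrow(s))
  cols <- c("locality", "sex", "age_band", "smoking_category", "n", "gm",
            "diet_ug_day", "packs_per_day", "smoking_ug_day")
  out <- rbind(d[, cols], s[, cols])
  rownames(out) <- NULL
  out
}

#' @export
coef.cd_reverse_fit <- function(object, ...) {
  d <- object$diet
  s <- object$smoking
  stats::setNames(
    c(d$intake_exact, s$packs_exact),
    c(paste(d$locality, d$sex, d$age_band, "diet", sep = "."),
      paste(s$locality, s$sex, s$age_band, "packs", sep = ".")))
}

#' @export
fitted.cd_reverse_fit <- function(object, ...) {
  stats::setNames(
    c(object$diet$fitted_ucd, object$smoking$fitted_ucd),
    c(paste(object$diet$locality, object$diet$sex, object$diet$age_band,
            "diet", sep = "."),
      paste(object$smoking$locality, object$smoking$sex,
            object$smoking$age_band, "packs", sep = ".")))
}

#' @export
residuals.cd_reverse_fit <- function(object, ...) {
  measured <- c(object$diet$gm, object$smoking$gm)
  measured - fitted(object)
}

#' Predict urinary cadmium for new exposure scenarios
#'
#' Forward-simulates each row of `newdata` under the fit's anchored
#' parameters.
#'
#' @param object A `cd_reverse_fit`.
#' @param newdata Data frame with columns `locality`, `sex`, `age`,
#'   `diet_ug_day` and optionally `packs_per_day`.
#' @param ... Unused.
#' @return Predicted urinary cadmium, ug/g creatinine.
#' @export
predict.cd_reverse_fit <- function(object, newdata, ...) {
  if (is.null(newdata$packs_per_day)) newdata$packs_per_day <- 0
  vapply(seq_len(nrow(newdata)), function(i) {
    r <- newdata[i, ]
    smoke <- if (r$packs_per_day > 0) {
      smoking_scenario(r$packs_per_day, r$locality, params = object$params)
    }
    prof <- build_profile(
      dietary_scenario(r$diet_ug_day, r$locality, r$sex, r$age),
      smoke, params = object$params)
    simulate_cd(prof, r$sex, object$params, keep_trajectory = FALSE)$ucd_final *
      gain_scale(object$params, r$locality, r$sex)
  }, numeric(1))
}

#' @export
print.cd_reverse_fit <- function(x, ...) {
  cat("Anchored reverse-dosimetry fit\n")
  cat(sprintf("  anchor band %s; %d dietary and %d smoking groups calibrated\n",
              x$anchor_band, nrow(x$diet), nrow(x$smoking)))
  cat("\nDietary intake (ug/day):\n")
  print(x$diet[, c("locality", "sex", "age_band", "n", "gm", "diet_ug_day")],
        row.names = FALSE)
  if (nrow(x$smoking)) {
    cat("\nSmoking (packs/day; smoking dose ug/day):\n")
    print(x$smoking[, c("locality", "sex", "age_band", "n", "gm",
                        "packs_per_day", "smoking_ug_day")],
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.cd_reverse_fit <- function(object, ...) {
  res <- residuals(object)
  meas <- c(object$diet$gm, object$smoking$gm)
  structure(list(fit = object,
                 max_rel_residual = max(abs(res) / meas),
                 gain_scales = object$params$gain_scale),
            class = "summary.cd_reverse_fit")
}

#' @export
print.summary.cd_reverse_fit <- function(x, ...) {
  print(x$fit)
  cat("\nAnchored gain scales:\n")
  print(round(x$gain_scales, 4))
  cat(sprintf("\nMax relative residual of reported (rounded) estimates: %.3g\n",
              x$max_rel_residual))
  invisible(x)
}

#' @export
plot.cd_reverse_fit <- function(x, ...) {
  meas <- c(x$diet$gm, x$smoking$gm)
  fit <- fitted(x)
  graphics::plot(meas, fit, log = "xy",
                 xlab = "measured GM U-Cd (ug/g creatinine)",
                 ylab = "model U-Cd at reported estimates",
                 main = "Reverse-dosimetry fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
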