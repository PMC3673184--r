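# Reverse dosimetry: anchoring and inversion of the forward model.

#' Anchor the model gain on a known (intake, urinary cadmium) pair
#'
#' The absolute level of the model gain depends on coefficients that cannot
#' be measured directly, so each (locality, sex) group is calibrated on one
#' known pair: the calibration scale is set such that
#' `cd_gain(age, sex, locality) * anchor_intake == anchor_ucd` exactly.
#' Re-anchoring with the same pair is idempotent.
#'
#' @param params A `cd_params` object.
#' @param anchor_intake Known dietary intake, ug/day (> 0).
#' @param anchor_ucd Measured geometric-mean urinary cadmium for the same
#'   group, ug/g creatinine (> 0).
#' @param age Age at which the pair applies, years.
#' @param sex `"male"` or `"female"`.
#' @param locality Locality name.
#' @return The updated `cd_params`.
#' @export
anchor_scale <- function(params, anchor_intake, anchor_ucd, age, sex,
                         locality) {
  if (anchor_intake <= 0 || anchor_ucd <= 0) {
    stop("anchor intake and urinary cadmium must be positive")
  }
  sex <- match.arg(sex, c("male", "female"))
  g0 <- .unit_gain(age, sex, params)
  key <- paste(locality, sex, sep = ".")
  params$gain_scale[[key]] <- anchor_ucd / (g0 * anchor_intake)
  params
}

#' Calibrate dietary intake from a target urinary cadmium level
#'
#' Inverts the forward model: finds the constant adult dietary intake whose
#' model-predicted urinary cadmium at the given age matches the target
#' within a relative tolerance of 1e-6.  For the (default) linear model the
#' answer is `target / gain` in a single step, verified by a forward run;
#' if the kidney-damage nonlinearity is enabled the inverse falls back to
#' bisection on `[0, 10 * target / gain]`.
#'
#' @param target_ucd Target urinary cadmium, ug/g creatinine (>= 0).
#' @param age Evaluation age, years.
#' @param sex `"male"` or `"female"`.
#' @param locality Locality name (applies the anchored gain scale).
#' @param params A `cd_params` object.
#' @param tol Relative matching tolerance (default 1e-6).
#' @return Intake in ug/day at full precision, with attributes `iterations`
#'   and `predicted_ucd`.  Round to whole ug/day for table reporting.
#' @export
calibrate_dietary_intake <- function(target_ucd, age, sex, locality = NULL,
                                     params = default_parameters(),
                                     tol = 1e-6) {
  if (target_ucd < 0) stop("target_ucd must be non-negative")
  if (target_ucd == 0) {
    return(structure(0, iterations = 0L, predicted_ucd = 0))
  }
  sex <- match.arg(sex, c("male", "female"))
  g <- cd_gain(age, sex, locality, params)
  predict1 <- function(intake) {
    prof <- build_profile(dietary_scenario(intake, locality %||% "unit",
                                           sex, age), params = params)
    sc <- if (is.null(locality)) 1 else gain_scale(params, locality, sex)
    simulate_cd(prof, sex, params, keep_trajectory = FALSE)$ucd_final * sc
  }
  if (!params$kidney_damage$enabled) {
    intake <- target_ucd / g
    pred <- predict1(intake)
    if (abs(pred - target_ucd) / target_ucd > tol) {
      stop("linear inversion failed verification; enable the bisection path")
    }
    return(structure(intake, iterations = 1L, predicted_ucd = pred))
  }
  lo <- 0; hi <- 10 * target_ucd / g
  pred <- NA_real_
  for (it in seq_len(100)) {
    mid <- (lo + hi) / 2
    pred <- predict1(mid)
    if (abs(pred - target_ucd) / target_ucd <= tol) {
      return(structure(mid, iterations = it, predicted_ucd = pred))
    }
    if (pred < target_ucd) lo <- mid else hi <- mid
  }
  stop("calibration did not converge after 100 bisection steps")
}

#' Calibrate smoking rate from a target urinary cadmium level
#'
#' Finds the packs/day that, added to a known dietary background, reproduce
#' the measured urinary cadmium of a smoker group.  The dietary-only
#' prediction is subtracted from the target and the remainder divided by
#' the marginal urinary cadmium per pack/day (from a unit-pack forward run;
#' exact for the linear model), then verified by a combined forward
#' simulation.  If the target does not exceed the dietary-only prediction
#' the smoking rate is 0, with a warning.
#'
#' @param target_ucd Measured urinary cadmium of the smoker group, ug/g
#'   creatinine.
#' @param dietary_background Dietary intake of the group, ug/day (the
#'   matched never-smoker estimate; >= 0).
#' @param age Evaluation age, years.
#' @param sex `"male"` or `"female"`.
#' @param locality Locality (sets the per-pack dose and the gain scale).
#' @param start_age Smoking start age, years (default from the catalogue).
#' @param params A `cd_params` object.
#' @param tol Relative matching tolerance.
#' @return Packs/day at full precision with attributes `iterations`,
#'   `predicted_ucd` and `ucd_diet` (the dietary-only prediction).  Round
#'   to 0.1 packs for table reporting.
#' @export
calibrate_packs <- function(target_ucd, dietary_background, age, sex,
                            locality, start_age = NULL,
                            params = default_parameters(), tol = 1e-6) {
  if (dietary_background < 0) stop("dietary_background must be non-negative")
  if (target_ucd < 0) stop("target_ucd must be non-negative")
  sex <- match.arg(sex, c("male", "female"))
  if (is.null(start_age)) start_age <- params$smoking_start_age
  sc <- gain_scale(params, locality, sex)
  cdpp <- cd_per_pack(locality, params)

  predict_both <- function(intake, packs) {
    prof <- build_profile(
      dietary_scenario(intake, locality, sex, age),
      smoking_scenario(packs, locality, start_age, cdpp, params),
      params = params)
    simulate_cd(prof, sex, params, keep_trajectory = FALSE)$ucd_final * sc
  }
  ucd_diet <- predict_both(dietary_background, 0)
  if (target_ucd <= ucd_diet) {
    if (target_ucd < ucd_diet) {
      warning("target urinary cadmium does not exceed the dietary-only ",
              "prediction; returning 0 packs/day")
    }
    return(structure(0, iterations = 0L, predicted_ucd = ucd_diet,
                     ucd_diet = ucd_diet))
  }
  g_smoke <- predict_both(0, 1)   # marginal U-Cd per pack/day
  if (!params$kidney_damage$enabled) {
    packs <- (target_ucd - ucd_diet) / g_smoke
    pred <- predict_both(dietary_background, packs)
    if (abs(pred - target_ucd) / target_ucd > tol) {
      stop("linear smoking inversion failed verification")
    }
    return(structure(packs, iterations = 1L, predicted_ucd = pred,
                     ucd_diet = ucd_diet))
  }
  lo <- 0; hi <- 10 * (target_ucd - ucd_diet) / g_smoke
  for (it in seq_len(100)) {
    mid <- (lo + hi) / 2
    pred <- predict_both(dietary_background, mid)
    if (abs(pred - target_ucd) / target_ucd <= tol) {
      return(structure(mid, iterations = it, predicted_ucd = pred,
                       ucd_diet = ucd_diet))
    }
    if (pred < target_ucd) lo <- mid else hi <- mid
  }
  stop("smoking calibration did not converge after 100 bisection steps")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
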