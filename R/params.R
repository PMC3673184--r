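# Model parameter catalogue: loading, validation, derived curves.

.cdtk_env <- new.env(parent = emptyenv())

.TRANSFER_KEYS <- c("k_B1B2", "k_B2B1", "k_B1B3", "k_B1L", "k_B1K", "k_B1T",
                    "k_TB1", "k_B1F", "k_B3K", "k_B3U", "k_LB3", "k_LF",
                    "k_KU", "k_KB1")

#' Load and validate the toxicokinetic parameter catalogue
#'
#' Reads the full coefficient set of the cadmium compartment model from a
#' structured YAML file: gut/lung absorption fractions, the first-order
#' daily transfer coefficients between blood pools (B1 fast, B2 slowly
#' exchanging, B3 plasma metallothionein), liver, kidney and other tissue,
#' the age- and sex-dependent creatinine excretion curve (g/day), the
#' age-scaling multiplier on adult dietary intake, and the per-pack inhaled
#' cadmium doses.  The schema is strict: a missing coefficient raises a
#' configuration error naming the key and unknown keys are rejected.
#'
#' Validation enforces explicit-step stability (for every compartment the
#' sum of outgoing daily fractions times the timestep must not exceed 1),
#' positivity of the creatinine curve over ages 1-100, and a dietary scaling
#' multiplier in (0, 1] that equals 1 from age 18 onward.
#'
#' @param config Path to a YAML parameter file.  `NULL` (default) loads the
#'   catalogue shipped with the package.
#' @return An object of class `cd_params`.
#' @examples
#' p <- default_parameters()
#' p$k[["k_KU"]]   # kidney-to-urine elimination, per day
#' @export
default_parameters <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "params_default.yaml", package = "cdtk")
  }
  if (!file.exists(config)) {
    stop("configuration error: parameter file not found: ", config)
  }
  raw <- yaml::read_yaml(config)

  top_required <- c("absorption", "transfer", "creatinine",
                    "diet_age_scaling", "smoking", "timestep")
  .check_keys(raw, top_required, "top level")
  .check_keys(raw$absorption,
              c("gut_male", "gut_female", "lung", "mucociliary_to_gut"),
              "absorption")
  .check_keys(raw$transfer, .TRANSFER_KEYS, "transfer")
  .check_keys(raw$creatinine, c("male", "female"), "creatinine")
  for (s in c("male", "female")) {
    .check_keys(raw$creatinine[[s]], c("age", "value"),
                paste0("creatinine$", s))
  }
  .check_keys(raw$diet_age_scaling, c("age", "value"), "diet_age_scaling")
  .check_keys(raw$smoking, c("start_age", "cd_per_pack"), "smoking")

  params <- structure(list(
    absorption_gut = c(male = as.numeric(raw$absorption$gut_male),
                       female = as.numeric(raw$absorption$gut_female)),
    absorption_lung = as.numeric(raw$absorption$lung),
    mucociliary_to_gut = as.numeric(raw$absorption$mucociliary_to_gut),
    k = vapply(raw$transfer[.TRANSFER_KEYS], as.numeric, numeric(1)),
    creatinine = lapply(raw$creatinine, function(cc)
      list(age = as.numeric(cc$age), value = as.numeric(cc$value))),
    diet_scaling = list(age = as.numeric(raw$diet_age_scaling$age),
                        value = as.numeric(raw$diet_age_scaling$value)),
    smoking_start_age = as.numeric(raw$smoking$start_age),
    cd_per_pack = vapply(raw$smoking$cd_per_pack, as.numeric, numeric(1)),
    timestep = as.numeric(raw$timestep),
    gain_scale = numeric(0),
    kidney_damage = list(enabled = FALSE, threshold_ug = Inf, factor = 1)
  ), class = "cd_params")

  validate_parameters(params)
  params
}

.check_keys <- function(x, required, where) {
  if (is.null(x)) stop("configuration error: missing section '", where, "'")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("configuration error: missing key '", missing[[1]],
         "' in ", where)
  }
  unknown <- setdiff(names(x), required)
  if (length(unknown)) {
    stop("configuration error: unknown key '", unknown[[1]],
         "' in ", where)
  }
  invisible(TRUE)
}

#' Validate a toxicokinetic parameter set
#'
#' Checks every fraction lies in \[0, 1\], that each compartment satisfies the
#' explicit-step stability condition (outgoing daily fractions times the
#' timestep sum to at most 1), that the creatinine curve is positive for
#' ages 1-100, and that the diet age-scaling multiplier lies in (0, 1] and
#' equals 1 for ages >= 18.
#'
#' @param params A `cd_params` object.
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending coefficient or compartment.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "cd_params"))
  frac <- c(params$absorption_gut, lung = params$absorption_lung,
            mucociliary = params$mucociliary_to_gut, params$k)
  bad <- names(frac)[!is.finite(frac) | frac < 0 | frac > 1]
  if (length(bad)) {
    stop("validation error: fraction out of [0,1]: ", bad[[1]])
  }
  if (params$absorption_lung + params$mucociliary_to_gut > 1) {
    stop("validation error: absorption_lung + mucociliary_to_gut exceeds 1")
  }
  dt <- params$timestep
  if (!is.finite(dt) || dt <= 0) stop("validation error: timestep must be > 0")
  k <- params$k
  outgoing <- list(
    B1 = c("k_B1B2", "k_B1B3", "k_B1L", "k_B1K", "k_B1T", "k_B1F"),
    B2 = "k_B2B1",
    B3 = c("k_B3K", "k_B3U"),
    L  = c("k_LB3", "k_LF"),
    K  = c("k_KU", "k_KB1"),
    T  = "k_TB1")
  for (comp in names(outgoing)) {
    if (sum(k[outgoing[[comp]]]) * dt > 1) {
      stop("validation error: stability violated in compartment ", comp,
           " (outgoing fractions x timestep exceed 1)")
    }
  }
  for (s in c("male", "female")) {
    cr <- creatinine_excretion(1:100, s, params)
    if (any(!is.finite(cr) | cr <= 0)) {
      stop("validation error: creatinine curve (", s,
           ") not positive over ages 1-100")
    }
  }
  sc <- diet_age_scaling(seq(0.5, 100, by = 0.5), params)
  if (any(sc <= 0 | sc > 1)) {
    stop("validation error: diet_age_scaling outside (0, 1]")
  }
  if (any(abs(diet_age_scaling(c(18, 30, 60, 90), params) - 1) > 1e-12)) {
    stop("validation error: diet_age_scaling must equal 1 for ages >= 18")
  }
  invisible(params)
}

#' Daily creatinine excretion by age and sex
#'
#' Piecewise-linear interpolation of the configured creatinine curve; used
#' to convert urinary cadmium excretion (ug/day) into a creatinine-adjusted
#' concentration (ug/g creatinine).
#'
#' @param age Age(s) in years.
#' @param sex `"male"` or `"female"`.
#' @param params A `cd_params` object.
#' @return Creatinine excretion in g/day.
#' @export
creatinine_excretion <- function(age, sex, params) {
  sex <- match.arg(sex, c("male", "female"))
  cc <- params$creatinine[[sex]]
  stats::approx(cc$age, cc$value, xout = age, rule = 2)$y
}

#' Age multiplier on adult dietary intake
#'
#' Children eat less than adults; dietary cadmium intake is assumed to scale
#' with caloric intake.  Piecewise linear in age, equal to 1 from age 18.
#'
#' @param age Age(s) in years.
#' @param params A `cd_params` object.
#' @return Unitless multiplier in (0, 1].
#' @export
diet_age_scaling <- function(age, params) {
  ds <- params$diet_scaling
  stats::approx(ds$age, ds$value, xout = age, rule = 2)$y
}

#' Per-group multiplicative gain calibration scale
#'
#' @param params A `cd_params` object.
#' @param locality Locality name.
#' @param sex `"male"` or `"female"`.
#' @return The calibration scale for the (locality, sex) group (1 if the
#'   group has not been anchored).
#' @seealso [anchor_scale()]
#' @export
gain_scale <- function(params, locality, sex) {
  key <- paste(locality, sex, sep = ".")
  if (key %in% names(params$gain_scale)) params$gain_scale[[key]] else 1.0
}

#' @export
print.cd_params <- function(x, ...) {
  cat("Cadmium toxicokinetic parameter set\n")
  cat(sprintf("  gut absorption: male %.3f, female %.3f; lung %.3f (+%.3f mucociliary to gut)\n",
              x$absorption_gut[["male"]], x$absorption_gut[["female"]],
              x$absorption_lung, x$mucociliary_to_gut))
  cat(sprintf("  kidney elimination half-life: %.1f y; liver release half-life: %.1f y\n",
              log(2) / (x$k[["k_KU"]] + x$k[["k_KB1"]]) / 365,
              log(2) / (x$k[["k_LB3"]] + x$k[["k_LF"]]) / 365))
  cat(sprintf("  timestep: %g day(s); cd per pack: %s\n", x$timestep,
              paste(sprintf("%s %.1f ug", names(x$cd_per_pack), x$cd_per_pack),
                    collapse = ", ")))
  if (length(x$gain_scale)) {
    cat("  anchored gain scales:\n")
    for (k in names(x$gain_scale)) {
      cat(sprintf("    %s: %.4f\n", k, x$gain_scale[[k]]))
    }
  } else {
    cat("  gain scales: none anchored (all 1.0)\n")
  }
  invisible(x)
}
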