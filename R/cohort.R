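# Packaged survey tables and the synthetic cohort generator.

.read_extdata <- function(file) {
  utils::read.csv(system.file("extdata", file, package = "cdtk"),
                  stringsAsFactors = FALSE)
}

#' Packaged Thai survey tables
#'
#' Transcriptions of the published group summaries for the Bangkok
#' (low-exposure, n = 399) and Mae Sot (high-exposure, n = 6,747) survey
#' populations:
#' \describe{
#'   \item{`thai_ucd_table()`}{Measured geometric-mean urinary cadmium
#'     (GM, with arithmetic SD, ug/g creatinine) by locality, sex, age band
#'     and smoking category, with group sizes where published.}
#'   \item{`thai_population_table()`}{Locality x sex totals, age
#'     mean and SD, smoking-category prevalences (percent) and overall
#'     GM/SD of urinary cadmium.}
#'   \item{`thai_diet_table()`}{Published model-based dietary cadmium
#'     estimates (ug/day) for never smokers; the 20-39 rows are the anchor
#'     pairs.}
#'   \item{`thai_packs_table()`}{Published model-based smoking-rate
#'     estimates (packs/day) for current smokers.}
#' }
#'
#' @return A data frame.
#' @export
thai_ucd_table <- function() {
  ucd <- .read_extdata("thai_ucd_by_group.csv")
  nn <- .read_extdata("thai_group_n.csv")
  out <- merge(ucd, nn, all.x = TRUE, sort = FALSE)
  out[, c("locality", "sex", "age_band", "smoking_category", "n", "gm", "sd")]
}

#' @rdname thai_ucd_table
#' @export
thai_population_table <- function() .read_extdata("thai_population.csv")

#' @rdname thai_ucd_table
#' @export
thai_diet_table <- function() .read_extdata("thai_diet_estimates.csv")

#' @rdname thai_ucd_table
#' @export
thai_packs_table <- function() .read_extdata("thai_packs_estimates.csv")

# Largest-remainder rounding of a positive allocation to a fixed total.
.largest_remainder <- function(raw, total) {
  fl <- floor(raw)
  rem <- total - sum(fl)
  if (rem > 0) {
    extra <- order(raw - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' Build a cohort specification
#'
#' @param cells Data frame with columns `locality`, `sex`, `age_band`,
#'   `smoking_category`, `n`, `gm`, `sd`.
#' @param seed Default random seed recorded with the spec.
#' @param age_ranges Named list mapping age bands to `c(lo, hi)` sampling
#'   ranges in years.
#' @return An object of class `cd_cohort_spec`.
#' @export
cohort_spec <- function(cells, seed = 1L,
                        age_ranges = list("13-19" = c(13, 19),
                                          "20-39" = c(20, 39),
                                          "40-59" = c(40, 59),
                                          "60+" = c(60, 92),
                                          "all" = c(13, 92))) {
  req <- c("locality", "sex", "age_band", "smoking_category", "n", "gm", "sd")
  miss <- setdiff(req, names(cells))
  if (length(miss)) stop("spec cells missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(cells$age_band), names(age_ranges))
  if (length(bad)) stop("no age range for band ", bad[[1]])
  if (any(cells$n < 0)) stop("cell n must be non-negative")
  if (any(cells$n > 0 & (is.na(cells$gm) | cells$gm <= 0))) {
    stop("cells with n > 0 need a positive gm")
  }
  structure(list(cells = cells, seed = seed, age_ranges = age_ranges),
            class = "cd_cohort_spec")
}

#' Cohort specification emulating the Thai survey structure
#'
#' Returns a full individual-level sampling specification for the Bangkok
#' and Mae Sot populations: one cell per (locality, sex, age band, smoking
#' category) with its group size, geometric mean and arithmetic SD of
#' urinary cadmium.  Where group sizes are published they are used as is;
#' the remaining cells (former and light-to-moderate smokers in Mae Sot,
#' and the small residual cells) are completed deterministically from the
#' published smoking prevalences by largest-remainder allocation
#' proportional to the never-smoker age distribution, so locality totals
#' (399 and 6,747) are reproduced exactly.  Cells published without a
#' geometric mean (fewer than ~5 subjects) are omitted.
#'
#' @param seed Seed recorded in the spec (default 1).
#' @return A `cd_cohort_spec`.
#' @export
thai_survey_spec <- function(seed = 1L) {
  ucd <- thai_ucd_table()
  pop <- thai_population_table()
  cats <- c(never = "pct_never", former = "pct_former",
            light_moderate = "pct_light_moderate", heavy = "pct_heavy")
  cells <- NULL
  for (i in seq_len(nrow(pop))) {
    loc <- pop$locality[i]; sx <- pop$sex[i]; n_tot <- pop$n_total[i]
    grp <- ucd[ucd$locality == loc & ucd$sex == sx, ]
    never <- grp[grp$smoking_category == "never", ]
    assigned <- 0L
    for (cat in names(cats)) {
      sub <- grp[grp$smoking_category == cat, ]
      if (!nrow(sub)) next
      target <- round(pop[[cats[[cat]]]][i] / 100 * n_tot)
      if (any(!is.na(sub$n))) {
        # published cells kept; any remainder goes to the unpublished cells
        rest <- max(target, sum(sub$n, na.rm = TRUE)) -
          sum(sub$n, na.rm = TRUE)
        open <- which(is.na(sub$n))
        if (length(open) && rest > 0) {
          share <- never$n[match(sub$age_band[open], never$age_band)]
          share[is.na(share)] <- 1
          sub$n[open] <- .largest_remainder(rest * share / sum(share), rest)
        }
        sub$n[is.na(sub$n)] <- 0L
      } else {
        # no published n at all: allocate the prevalence total across
        # bands proportionally to the never-smoker age distribution
        share <- never$n[match(sub$age_band, never$age_band)]
        share[is.na(share)] <- mean(never$n)
        sub$n <- .largest_remainder(target * share / sum(share), target)
      }
      assigned <- assigned + sum(sub$n)
      cells <- rbind(cells, sub)
    }
    # rounding drift (at most a few records) is absorbed by the largest cell
    drift <- n_tot - assigned
    if (drift != 0) {
      big <- which(cells$locality == loc & cells$sex == sx)
      big <- big[which.max(cells$n[big])]
      cells$n[big] <- cells$n[big] + drift
    }
  }
  rownames(cells) <- NULL
  cohort_spec(cells, seed = seed)
}

#' Generate a synthetic individual-level cohort
#'
#' Draws, for every cell of the specification, `n` urinary cadmium values
#' from the lognormal distribution matching the cell's geometric mean and
#' arithmetic SD (see [lognormal_from_gm_sd()]), ages uniformly within the
#' cell's age band, and cigarettes/day uniformly within the smoking
#' category's range (10-25 light-to-moderate, 26-80 heavy; 0 for never and
#' former smokers).  Generation is deterministic given the seed and leaves
#' the caller's random-number state untouched.
#'
#' @param spec A `cd_cohort_spec`.
#' @param seed Integer seed (default the spec's recorded seed).
#' @param lod_ug_per_g Optional left-censoring cut in ug/g creatinine:
#'   values below it are replaced by `lod_ug_per_g / sqrt(2)` and flagged.
#'   Default `NULL` (the generator works in the analysis unit, where the
#'   published detection limit in ug/L has no fixed equivalent).
#' @return Data frame with columns `id`, `locality`, `sex`, `age`,
#'   `smoking_category`, `cigarettes_per_day`, `packs_per_day`,
#'   `ucd_ug_per_g`, `censored`.
#' @examples
#' spec <- cohort_spec(data.frame(locality = "MaeSot", sex = "female",
#'                                age_band = "all",
#'                                smoking_category = "never",
#'                                n = 1000, gm = 2.10, sd = 2.91))
#' round(geometric_mean(generate_cohort(spec, seed = 7)$ucd_ug_per_g), 2)
#' @export
generate_cohort <- function(spec, seed = spec$seed, lod_ug_per_g = NULL) {
  stopifnot(inherits(spec, "cd_cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  cig_range <- list(never = c(0, 0), former = c(0, 0),
                    light_moderate = c(10, 25), heavy = c(26, 80))
  cells <- spec$cells
  ord <- order(cells$locality, cells$sex, cells$age_band,
               cells$smoking_category)
  cells <- cells[ord, ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    if (cell$n == 0) next
    par <- lognormal_from_gm_sd(cell$gm, cell$sd)
    ucd <- exp(stats::rnorm(cell$n, par$mu, par$sigma))
    ar <- spec$age_ranges[[cell$age_band]]
    age <- round(stats::runif(cell$n, ar[1], ar[2]), 1)
    cr <- cig_range[[cell$smoking_category]]
    cig <- if (cr[2] > 0) {
      sample(seq(cr[1], cr[2]), cell$n, replace = TRUE)
    } else rep(0L, cell$n)
    out[[i]] <- data.frame(
      locality = cell$locality, sex = cell$sex, age = age,
      age_band = cell$age_band,
      smoking_category = cell$smoking_category,
      cigarettes_per_day = cig, packs_per_day = cig / 20,
      ucd_ug_per_g = ucd, censored = FALSE)
  }
  cohort <- do.call(rbind, out)
  if (is.null(cohort)) {
    cohort <- data.frame(locality = character(), sex = character(),
                         age = numeric(), age_band = character(),
                         smoking_category = character(),
                         cigarettes_per_day = integer(),
                         packs_per_day = numeric(),
                         ucd_ug_per_g = numeric(), censored = logical())
  }
  if (!is.null(lod_ug_per_g)) {
    below <- cohort$ucd_ug_per_g < lod_ug_per_g
    cohort$ucd_ug_per_g[below] <- lod_ug_per_g / sqrt(2)
    cohort$censored[below] <- TRUE
  }
  cohort <- cbind(id = seq_len(nrow(cohort)), cohort)
  rownames(cohort) <- NULL
  attr(cohort, "seed") <- seed
  cohort
}

#' Write a cohort to CSV with a seed sidecar
#'
#' Writes the cohort table as UTF-8 CSV and records the generating seed and
#' record count in a YAML sidecar (`<file>.meta.yaml`), so the file can be
#' regenerated byte-identically.
#'
#' @param cohort A cohort data frame from [generate_cohort()].
#' @param file Output CSV path.
#' @return The CSV path, invisibly.
#' @export
write_cohort <- function(cohort, file) {
  utils::write.csv(cohort, file, row.names = FALSE, fileEncoding = "UTF-8")
  meta <- list(seed = as.integer(attr(cohort, "seed")),
               n_records = nrow(cohort))
  yaml::write_yaml(meta, paste0(file, ".meta.yaml"))
  invisible(file)
}
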