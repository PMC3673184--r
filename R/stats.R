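# Biomonitoring statistics for urinary cadmium cohorts.

#' Substitute values below the detection limit
#'
#' Concentrations strictly below the limit of detection are replaced by
#' LOD divided by the square root of 2 (the standard substitution for
#' left-censored biomonitoring data); values at or above the LOD are
#' unchanged.
#'
#' @param x Concentrations, ug/L (non-negative).
#' @param lod Limit of detection, ug/L (default 0.05).
#' @return The substituted vector.
#' @examples
#' lod_substitute(c(0.02, 0.05, 0.40))  # 0.03536, 0.05, 0.40
#' @export
lod_substitute <- function(x, lod = 0.05) {
  if (any(x < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  ifelse(x < lod, lod / sqrt(2), x)
}

#' Geometric mean
#'
#' @param x Positive values, n >= 1.
#' @return `exp(mean(log(x)))`, in the units of `x`.
#' @examples
#' geometric_mean(c(1, 10, 100))  # 10
#' @export
geometric_mean <- function(x) {
  if (length(x) < 1) stop("need at least one value")
  if (any(!is.finite(x) | x <= 0)) stop("values must be positive")
  exp(mean(log(x)))
}

#' Lognormal parameters from geometric mean and arithmetic SD
#'
#' Inverts the (GM, SD) summary of a lognormal distribution into its
#' log-scale parameters: `mu = log(gm)` and `sigma^2 = log(w)` with
#' `w = (1 + sqrt(1 + 4 (sd/gm)^2)) / 2`, so that the distribution's
#' geometric mean equals `gm` and its arithmetic standard deviation equals
#' `sd`.  (Survey tables report geometric means with arithmetic SDs of the
#' untransformed values, which is why SD can exceed GM.)
#'
#' @param gm Geometric mean (> 0).
#' @param sd Arithmetic standard deviation (>= 0).  Vectorized.
#' @return List with components `mu` and `sigma`.
#' @examples
#' lognormal_from_gm_sd(0.40, 0.46)$sigma  # ~0.7495
#' @export
lognormal_from_gm_sd <- function(gm, sd) {
  if (any(gm <= 0)) stop("gm must be positive")
  if (any(sd < 0)) stop("sd must be non-negative")
  w <- (1 + sqrt(1 + 4 * (sd / gm)^2)) / 2
  list(mu = log(gm), sigma = sqrt(log(w)))
}

#' Percentage of values at or above a threshold
#'
#' @param x Values.
#' @param tau Threshold (> 0); the comparison is inclusive (`>=`).
#' @return Percentage in \[0, 100\].
#' @export
pct_over_threshold <- function(x, tau) {
  if (tau <= 0) stop("tau must be positive")
  100 * mean(x >= tau)
}

#' Compare urinary cadmium between groups
#'
#' Implements the survey's testing scheme.  Normality of each group is
#' assessed with Kolmogorov-Smirnov goodness-of-fit tests on the raw and
#' base-10 log-transformed values.  Two groups are compared with Student's
#' t-test when both pass raw-scale normality at 0.05 and with the
#' Mann-Whitney U test otherwise.  Three or more groups are compared by
#' one-way ANOVA on log10 values followed by Dunnett post-hoc comparisons
#' (multivariate-t adjustment) against the reference group.  Differences
#' are flagged at p <= 0.05.
#'
#' @param values Numeric measurements (positive; log10 is taken for the
#'   multi-group analysis).
#' @param group Group membership (factor or character), >= 2 groups with
#'   n >= 2 each.
#' @param reference Reference level for Dunnett comparisons (default the
#'   first level; use the never-smoker group).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `cd_group_test`: the per-group normality
#'   table, the omnibus method and p-value, pairwise comparisons (for >= 3
#'   groups) and significance flags.
#' @export
compare_groups <- function(values, group, reference = NULL, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  if (any(table(group) < 2)) stop("every group needs n >= 2")
  if (!is.null(reference)) group <- stats::relevel(group, ref = reference)

  ks_p <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)   # degenerate: zero variance
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }
  normality <- data.frame(
    group = levels(group),
    p_raw = vapply(levels(group), function(g) ks_p(values[group == g]),
                   numeric(1)),
    p_log10 = vapply(levels(group),
                     function(g) ks_p(log10(values[group == g])),
                     numeric(1)),
    row.names = NULL)

  comparisons <- NULL
  if (nlevels(group) == 2) {
    both_normal <- all(!is.na(normality$p_raw) & normality$p_raw > alpha)
    if (both_normal) {
      ht <- stats::t.test(values ~ group)
      method <- "t-test"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(values ~ group))
      method <- "Mann-Whitney U"
    }
    p_value <- ht$p.value
  } else {
    lg <- log10(values)
    dat <- data.frame(y = lg, g = group)
    fit <- stats::aov(y ~ g, data = dat)
    p_value <- summary(fit)[[1]][["Pr(>F)"]][1]
    method <- "one-way ANOVA (log10) + Dunnett"
    dn <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
    comparisons <- data.frame(
      comparison = names(dn$test$coefficients),
      estimate_log10 = unname(dn$test$coefficients),
      p_adjusted = unname(dn$test$pvalues),
      row.names = NULL)
    comparisons$significant <- comparisons$p_adjusted <= alpha
  }
  structure(list(method = method, p_value = p_value,
                 significant = p_value <= alpha,
                 normality = normality, comparisons = comparisons,
                 alpha = alpha),
            class = "cd_group_test")
}

#' @export
print.cd_group_test <- function(x, ...) {
  cat(sprintf("Group comparison: %s, p = %.4g (%ssignificant at %.2f)\n",
              x$method, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  if (!is.null(x$comparisons)) {
    cat("Dunnett comparisons vs reference:\n")
    print(x$comparisons, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Summarize a cohort into group statistics
#'
#' Computes, per grouping cell, the group size, geometric mean and
#' arithmetic SD of urinary cadmium and the percentages at or above 1 and
#' 5 ug/g creatinine.
#'
#' @param cohort Data frame with column `ucd_ug_per_g` and the grouping
#'   columns.
#' @param by Character vector of grouping columns (default locality, sex,
#'   age band and smoking category).
#' @param thresholds Exceedance thresholds, ug/g creatinine.
#' @return Data frame of group summaries.
#' @export
summarize_cohort <- function(cohort,
                             by = c("locality", "sex", "age_band",
                                    "smoking_category"),
                             thresholds = c(1, 5)) {
  stopifnot("ucd_ug_per_g" %in% names(cohort), all(by %in% names(cohort)))
  split_idx <- split(seq_len(nrow(cohort)), cohort[by], drop = TRUE)
  rows <- lapply(split_idx, function(idx) {
    x <- cohort$ucd_ug_per_g[idx]
    cell <- cohort[idx[1], by, drop = FALSE]
    stats <- data.frame(n = length(x), gm = geometric_mean(x),
                        sd = stats::sd(x))
    for (tau in thresholds) {
      stats[[sprintf("pct_ge_%g", tau)]] <- pct_over_threshold(x, tau)
    }
    cbind(cell, stats)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}

#' Smoker-to-never-smoker ratios of group geometric means
#'
#' For every (locality, sex, age band), the ratio of each smoking
#' category's geometric-mean urinary cadmium to the never-smoker geometric
#' mean, rounded to one decimal.
#'
#' @param summaries Group-summary data frame (columns `locality`, `sex`,
#'   `age_band`, `smoking_category`, `gm`).
#' @param reference Reference smoking category (default `"never"`).
#' @return Data frame with the reference GM and the rounded ratio per row.
#' @examples
#' ratio_report(data.frame(locality = "Bangkok", sex = "male",
#'                         age_band = "40-59",
#'                         smoking_category = c("never", "light_moderate"),
#'                         gm = c(0.49, 0.92)))  # ratio 1.9
#' @export
ratio_report <- function(summaries, reference = "never") {
  ref <- summaries[summaries$smoking_category == reference, ]
  if (!nrow(ref)) stop("missing reference category '", reference, "'")
  smk <- summaries[summaries$smoking_category != reference, ]
  key <- function(d) paste(d$locality, d$sex, d$age_band)
  ref_gm <- stats::setNames(ref$gm, key(ref))
  smk$gm_reference <- unname(ref_gm[key(smk)])
  if (any(is.na(smk$gm_reference))) {
    stop("missing reference cell for ",
         key(smk)[which(is.na(smk$gm_reference))[1]])
  }
  smk$ratio <- round(smk$gm / smk$gm_reference, 1)
  rownames(smk) <- NULL
  smk[, c("locality", "sex", "age_band", "smoking_category", "gm",
          "gm_reference", "ratio")]
}
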