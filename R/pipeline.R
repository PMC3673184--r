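# End-to-end pipeline: generate -> summarize -> anchor -> calibrate ->
# risk report, with deterministic, seed-stamped outputs.

#' Run the full exposure-reconstruction pipeline
#'
#' Generates a synthetic cohort from a specification, summarizes it into
#' the population and group tables, fits anchored reverse dosimetry to the
#' group geometric means, and writes the dietary-intake, smoking-rate and
#' risk-comparison tables plus a provenance log.  Outputs are deterministic
#' for a fixed seed; every file name is returned and the log records the
#' seed and a hash of the configuration.  A failure in any stage removes
#' the partial outputs of this run.
#'
#' @param output_dir Directory for the artifact bundle (created if needed).
#' @param seed Integer seed for cohort generation.
#' @param params_config Optional path to a YAML parameter file (default:
#'   packaged catalogue).
#' @param spec A `cd_cohort_spec` (default: the packaged Thai survey spec).
#' @param anchors Anchor intakes for [cd_reverse_fit()].
#' @param verbose Print stage progress to stderr.
#' @return Invisibly, a list with the output paths and the config hash.
#' @export
run_pipeline <- function(output_dir, seed = 1L, params_config = NULL,
                         spec = thai_survey_spec(),
                         anchors = thai_anchor_intakes(),
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[cdtk] ", sprintf(...))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = "cohort.csv",
             population_summary = "table1_population.csv",
             group_ucd = "table2_group_ucd.csv",
             diet = "table3_diet_estimates.csv",
             smoking = "table4_smoking_estimates.csv",
             risk = "risk_report.csv",
             risk_text = "risk_report.txt",
             log = "run_log.txt")
  paths <- vapply(paths, function(p) file.path(output_dir, p), character(1))
  created <- character(0)
  stage <- "configuration"
  tryCatch({
    params <- default_parameters(params_config)
    cfg_file <- tempfile()
    writeLines(c(readLines(params_config %||%
                             system.file("extdata", "params_default.yaml",
                                         package = "cdtk")),
                 sprintf("seed: %d", seed)), cfg_file)
    cfg_hash <- unname(tools::md5sum(cfg_file))
    unlink(cfg_file)

    stage <- "generate"
    say("generating cohort (seed %d)", seed)
    cohort <- generate_cohort(spec, seed = seed)
    write_cohort(cohort, paths[["cohort"]])
    created <- c(created, paths[["cohort"]],
                 paste0(paths[["cohort"]], ".meta.yaml"))

    stage <- "summarize"
    say("summarizing %d records", nrow(cohort))
    pop <- summarize_cohort(cohort, by = c("locality", "sex"))
    utils::write.csv(pop, paths[["population_summary"]], row.names = FALSE)
    groups <- summarize_cohort(cohort)
    utils::write.csv(groups, paths[["group_ucd"]], row.names = FALSE)
    created <- c(created, paths[["population_summary"]], paths[["group_ucd"]])

    stage <- "calibrate"
    say("anchored reverse-dosimetry fit")
    fit <- cd_reverse_fit(groups, anchors = anchors, params = params)
    utils::write.csv(fit$diet, paths[["diet"]], row.names = FALSE)
    utils::write.csv(fit$smoking, paths[["smoking"]], row.names = FALSE)
    created <- c(created, paths[["diet"]], paths[["smoking"]])

    stage <- "risk"
    say("risk comparison")
    risk <- exceedance_report(fit$diet)
    utils::write.csv(risk$table, paths[["risk"]], row.names = FALSE)
    writeLines(c("Risk comparison against tolerable intakes",
                 sprintf("config_hash: %s", cfg_hash),
                 risk$summary_lines), paths[["risk_text"]])
    created <- c(created, paths[["risk"]], paths[["risk_text"]])

    stage <- "log"
    writeLines(c(sprintf("seed: %d", seed),
                 sprintf("config_hash: %s", cfg_hash),
                 sprintf("cohort_records: %d", nrow(cohort)),
                 sprintf("calibrated_diet_groups: %d", nrow(fit$diet)),
                 sprintf("calibrated_smoking_groups: %d", nrow(fit$smoking)),
                 "parameter_provenance: packaged catalogue with per-group anchored gain scales"),
               paths[["log"]])
    created <- c(created, paths[["log"]])

    invisible(list(paths = as.list(paths), config_hash = cfg_hash,
                   fit = fit))
  }, error = function(e) {
    unlink(created)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
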