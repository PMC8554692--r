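# End-to-end pipeline: load or simulate a cohort, apply exclusion filters,
# classify every individual on the spectrum, stratify, tabulate and compare
# tumor patterns, and write diffable artifacts (timestamps are confined to
# the run log).

#' Pipeline run configuration
#'
#' Exactly one input source must be given: either both table paths, or a
#' simulation config.
#'
#' @param individuals_path,diagnoses_path Input CSV paths.
#' @param sim An [sim_config()] to simulate instead of reading tables.
#' @param exclude_r337h Drop p.R337H founder carriers before analysis.
#' @param exclude_clonal_hematopoiesis Drop flagged individuals.
#' @param criteria An [criteria_config()].
#' @param out_dir Output directory.
#' @param seed Seed recorded in the log and forwarded to simulation when
#'   `sim` carries no seed of its own.
#' @return A list of class `lfs_run_config`.
#' @export
run_config <- function(individuals_path = NULL, diagnoses_path = NULL,
                       sim = NULL, exclude_r337h = TRUE,
                       exclude_clonal_hematopoiesis = TRUE,
                       criteria = criteria_config(), out_dir = ".",
                       seed = NULL) {
  have_paths <- !is.null(individuals_path) || !is.null(diagnoses_path)
  if (have_paths == !is.null(sim)) {
    stop("provide exactly one of (individuals_path + diagnoses_path) or sim",
         call. = FALSE)
  }
  if (have_paths && (is.null(individuals_path) || is.null(diagnoses_path))) {
    stop("both individuals_path and diagnoses_path are required",
         call. = FALSE)
  }
  structure(list(individuals_path = individuals_path,
                 diagnoses_path = diagnoses_path, sim = sim,
                 exclude_r337h = exclude_r337h,
                 exclude_clonal_hematopoiesis = exclude_clonal_hematopoiesis,
                 criteria = criteria, out_dir = out_dir, seed = seed),
            class = "lfs_run_config")
}

#' Run the full pipeline
#'
#' Writes `assignments.csv`, `families.csv`, `strata.json`,
#' `tumor_patterns.csv`, `stats.json` and `run.log` into the output
#' directory; when simulating, the cohort tables and ground-truth labels
#' are written too. Outputs are deterministic for fixed inputs and seed.
#' On error, files written by the failed run are removed.
#'
#' @param rc An [run_config()].
#' @return Named character vector of written paths, invisibly.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "lfs_run_config"))
  if (!dir.exists(rc$out_dir)) {
    dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  written <- character()
  out <- function(f) file.path(rc$out_dir, f)
  on_fail <- function(e) {
    unlink(written[file.exists(written)])
    stop(e)
  }
  tryCatch({
    truth <- NULL
    if (!is.null(rc$sim)) {
      sim_cfg <- rc$sim
      if (!is.null(rc$seed)) sim_cfg$seed <- as.integer(rc$seed)
      sim <- generate_cohort(sim_cfg)
      cohort <- sim$cohort
      truth <- sim$truth
      paths <- write_cohort(cohort, rc$out_dir)
      utils::write.csv(truth, out("ground_truth.csv"), row.names = FALSE)
      written <- c(written, unname(paths), out("ground_truth.csv"))
    } else {
      cohort <- read_cohort(rc$individuals_path, rc$diagnoses_path)
    }
    filt <- apply_exclusions(cohort, rc$exclude_r337h,
                             rc$exclude_clonal_hematopoiesis)
    cohort <- filt$cohort
    classified <- classify_cohort(cohort, rc$criteria)
    write_assignments(classified$assignments, out("assignments.csv"))
    utils::write.csv(classified$families, out("families.csv"),
                     row.names = FALSE)
    written <- c(written, out("assignments.csv"), out("families.csv"))
    strata <- stratify_for_analysis(cohort, rc$criteria)
    jsonlite::write_json(as.list(strata$strata), out("strata.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, out("strata.json"))
    have_cases <- nrow(strata$met_cases) + nrow(strata$not_met_cases) > 0
    if (have_cases) {
      tbl <- tumor_pattern_table(strata)
      utils::write.csv(tbl, out("tumor_patterns.csv"), row.names = FALSE)
      written <- c(written, out("tumor_patterns.csv"))
    }
    ages <- summarize_ages(cohort, list(met = strata$met_ids,
                                        not_met = strata$not_met_ids))
    stats_record <- list(
      n_individuals = nrow(cohort$individuals),
      n_families = length(unique(cohort$individuals$family_id)),
      n_diagnoses = nrow(cohort$diagnoses),
      exclusions = as.list(filt$report),
      strata = as.list(strata$strata),
      category_counts = as.list(table(classified$assignments$category)),
      ages = ages)
    jsonlite::write_json(stats_record, out("stats.json"), auto_unbox = TRUE,
                         pretty = TRUE, dataframe = "rows")
    written <- c(written, out("stats.json"))
    log_lines <- c(
      paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      paste0("lfspectrum version: ",
             as.character(utils::packageVersion("lfspectrum"))),
      paste0("R version: ", R.version.string),
      paste0("seed: ", if (is.null(rc$seed)) "none" else rc$seed),
      paste0("input: ", if (is.null(rc$sim)) {
        paste(rc$individuals_path, rc$diagnoses_path, sep = ", ")
      } else "simulated"),
      paste0("exclude_r337h: ", rc$exclude_r337h),
      paste0("exclude_clonal_hematopoiesis: ",
             rc$exclude_clonal_hematopoiesis))
    writeLines(log_lines, out("run.log"))
    written <- c(written, out("run.log"))
    invisible(stats::setNames(written, basename(written)))
  }, error = on_fail)
}
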