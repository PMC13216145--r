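## Report assembly: one entry point running score -> classify -> compare ->
## regress (-> validate/cvi when label/panel files are supplied), emitting
## plain CSV reports plus a JSON run manifest. A command-line wrapper lives
## in inst/cli/postpipe.R.

#' Load a scoring configuration from JSON
#'
#' Recognised keys are the arguments of [scoring_config()]; absent keys keep
#' their defaults. An optional `seed` key provides the pipeline seed.
#'
#' @param path Path to a JSON config file, or `NULL` for all defaults.
#' @return A list with `scoring` (a [scoring_config()]) and `seed`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(list(scoring = scoring_config(), seed = 20260910L))
  raw <- jsonlite::fromJSON(path)
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 20260910L
  args <- raw[intersect(names(raw), names(formals(scoring_config)))]
  list(scoring = do.call(scoring_config, args), seed = seed)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

round_df <- function(df, cols, digits) {
  for (c_ in intersect(cols, names(df))) df[[c_]] <- round(df[[c_]], digits)
  df
}

#' Run the full analysis pipeline
#'
#' Reads a cohort, scores and classifies every patient, builds the
#' group-comparison and odds-ratio tables, and (when rater labels or an
#' expert panel are supplied) the cut-off validation and content-validity
#' reports. Outputs, all plain CSV/JSON under `out_dir`:
#' `scores.csv` (per-patient breakdown plus outcome), `outcomes.csv`
#' (transition counts), `table2_continuous.csv` / `table2_categorical.csv`,
#' `table3.csv`, optionally `validation.csv` and `cvi.csv`, and
#' `manifest.json` (command, config, input hashes, seed, package version,
#' timestamp). Outputs are a pure function of (inputs, config, seed);
#' percentages are printed to 1 decimal place and odds ratios to 3.
#'
#' @param cohort_path Path to a `cohort.csv`.
#' @param out_dir Output directory (created if missing).
#' @param config_path Optional JSON scoring config.
#' @param raters_path Optional rater-label CSV enabling cut-off validation.
#' @param panel_path Optional expert-panel CSV enabling the CVI report.
#' @param cutoffs Cut-offs swept in the validation report.
#' @return Invisibly, a named list of the files written.
#' @export
run_pipeline <- function(cohort_path, out_dir, config_path = NULL,
                         raters_path = NULL, panel_path = NULL,
                         cutoffs = c(8, 9, 10)) {
  cfg <- stage("config", load_config(config_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- stage("read", read_cohort(cohort_path))
  written <- list()
  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("postpipe")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    inputs = as.list(tools::md5sum(stats::na.omit(
      c(cohort_path, config_path, raters_path, panel_path)))),
    scoring_config = unclass(cfg$scoring))

  if (nrow(cohort) == 0) {
    message("no records in cohort; nothing to do")
    manifest$note <- "no records"
    path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(list(manifest = path)))
  }

  scores <- stage("score", score_cohort(cohort, cfg$scoring))
  outcomes <- stage("classify", classify_cohort(cohort, scores))

  out_scores <- cbind(scores, outcome = as.character(outcomes))
  written$scores <- file.path(out_dir, "scores.csv")
  utils::write.csv(out_scores, written$scores, row.names = FALSE, na = "")

  trans <- outcome_transitions(cohort, outcomes)
  written$outcomes <- file.path(out_dir, "outcomes.csv")
  utils::write.csv(trans, written$outcomes, row.names = FALSE)

  summ <- stage("compare", summarize_cohort(cohort, scores,
                                            mc_seed = cfg$seed))
  written$table2_continuous <- file.path(out_dir, "table2_continuous.csv")
  utils::write.csv(round_df(summ$continuous,
                            c("mean_neg", "sd_neg", "median_neg", "iqr_neg",
                              "mean_pos", "sd_pos", "median_pos", "iqr_pos"), 2),
                   written$table2_continuous, row.names = FALSE, na = "")
  written$table2_categorical <- file.path(out_dir, "table2_categorical.csv")
  utils::write.csv(round_df(summ$categorical,
                            c("percent", "percent_neg", "percent_pos"), 1),
                   written$table2_categorical, row.names = FALSE, na = "")

  fit <- stage("regress", {
    X <- build_design(cohort, model_spec("full"))
    fit_logistic(scores$is_post_pipeline, X)
  })
  written$table3 <- file.path(out_dir, "table3.csv")
  utils::write.csv(format_ortable(fit), written$table3, row.names = FALSE)
  manifest$regression_n_used <- attr(fit, "n_used")

  if (!is.null(raters_path)) {
    labels <- stage("validate", read_raters(raters_path))
    val <- stage("validate", validate_cutoffs(scores, labels, cutoffs))
    written$validation <- file.path(out_dir, "validation.csv")
    utils::write.csv(round_df(val, c("sensitivity", "specificity", "auc"), 3),
                     written$validation, row.names = FALSE)
  }
  if (!is.null(panel_path)) {
    cvi <- stage("cvi", cvi_report(read_panel(panel_path)))
    tab <- cvi$items
    tab$s_cvi_ave_relevance <- cvi$s_cvi_ave_relevance
    tab$s_cvi_ave_clarity <- cvi$s_cvi_ave_clarity
    tab$s_cvi_ave_overall <- cvi$s_cvi_ave_overall
    written$cvi <- file.path(out_dir, "cvi.csv")
    utils::write.csv(round_df(tab, c("i_cvi_relevance", "i_cvi_clarity",
                                     "mean_relevance", "mean_clarity",
                                     "s_cvi_ave_relevance", "s_cvi_ave_clarity",
                                     "s_cvi_ave_overall"), 3),
                     written$cvi, row.names = FALSE)
  }

  manifest$outputs <- names(written)
  written$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, written$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(written)
}
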