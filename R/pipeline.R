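# End-to-end pipeline: cohort -> (optional simulated staircase
# measurement) -> group assignment -> reading composite -> whole-sample
# and between-group hierarchical regressions -> cross-task correlations,
# with a reproducibility manifest. A single root seed deterministically
# spawns per-stage sub-seeds so stages can be re-run in isolation.

#' Pipeline configuration
#'
#' @param cohort A [cohort_spec()].
#' @param measure Simulate staircase measurement of every threshold
#'   (slower); otherwise the generated true thresholds are analysed.
#' @param modes Analyses to run: `"whole_sample"` (reading-composite
#'   predictor, all participants) and/or `"between_group"` (group
#'   predictor, assigned participants only).
#' @param standardize_composite Standardise the composite scores before
#'   regression (scores are otherwise in eigen-projection units).
#' @param seed Root seed; mandatory for simulated runs.
#' @param out_dir Optional output directory for delimited/JSON reports.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), measure = FALSE,
                            modes = c("whole_sample", "between_group"),
                            standardize_composite = FALSE,
                            seed = 1L, out_dir = NULL) {
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(seed)) stop("a seed is mandatory for simulated runs",
                          call. = FALSE)
  structure(
    list(cohort = cohort, measure = measure, modes = modes,
         standardize_composite = standardize_composite,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config")
}

reading_columns <- c("nart_raw", "towre_swe_std", "towre_pd_std")

#' Run the full analysis pipeline
#'
#' Executes every stage under seeds spawned from the root seed and returns
#' (and optionally writes) the cohort table, composite report, regression
#' reports for each task and mode, the cross-task correlation report and a
#' manifest sufficient to replay the run. Identical configuration and seed
#' give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result` with fields `cohort`,
#'   `composite`, `fits` (nested by mode then task), `correlations` and
#'   `manifest`.
#' @examples
#' res <- run_pipeline(pipeline_config(cohort_spec(n = 40), seed = 7))
#' names(res$fits$whole_sample)
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- spawn_seeds(config$seed, 2L)
  cohort <- tryCatch(generate_cohort(config$cohort, seed = seeds[1]),
                     error = function(e) pipeline_abort("cohort", e))
  if (config$measure) {
    cohort <- tryCatch(measure_cohort(cohort, seed = seeds[2]),
                       error = function(e) pipeline_abort("measure", e))
  }
  if ("between_group" %in% config$modes) {
    cohort <- tryCatch(assign_groups(cohort),
                       error = function(e) pipeline_abort("groups", e))
  }
  composite <- tryCatch(
    pca_composite(cohort[reading_columns],
                  standardize_scores = config$standardize_composite),
    error = function(e) pipeline_abort("composite", e))
  cohort$reading_composite <- composite$scores

  tasks <- sub("^thr_", "",
               grep("^thr_(?!.*_true$)", names(cohort), value = TRUE,
                    perl = TRUE))
  fits <- list()
  if ("whole_sample" %in% config$modes) {
    fits$whole_sample <- lapply(stats::setNames(tasks, tasks), function(t) {
      tryCatch(
        hierarchical_fit(cohort[[paste0("thr_", t)]],
                         controls = data.frame(gender = cohort$gender,
                                               spm = cohort$spm_raw),
                         predictor = cohort$reading_composite,
                         predictor_name = "reading_skill"),
        error = function(e) pipeline_abort("whole_sample_fit", e))
    })
  }
  if ("between_group" %in% config$modes) {
    sub <- cohort[cohort$group != "unassigned", ]
    sub$group <- droplevels(sub$group)
    fits$between_group <- lapply(stats::setNames(tasks, tasks),
                                 function(t) {
      tryCatch(
        hierarchical_fit(sub[[paste0("thr_", t)]],
                         controls = data.frame(gender = sub$gender,
                                               spm = sub$spm_raw),
                         predictor = sub$group,
                         predictor_name = "reading_group"),
        error = function(e) pipeline_abort("between_group_fit", e))
    })
  }
  correlations <- tryCatch(
    task_correlations(cohort[paste0("thr_", tasks)]),
    error = function(e) pipeline_abort("correlations", e))

  manifest <- list(
    package = "cohermetrics",
    version = as.character(utils::packageVersion("cohermetrics")),
    seed = config$seed, stage_seeds = as.integer(seeds),
    n = nrow(cohort), measure = config$measure, modes = config$modes,
    tasks = tasks,
    cohort_spec = summarise_cohort_spec(config$cohort))

  result <- structure(
    list(cohort = cohort, composite = composite, fits = fits,
         correlations = correlations, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline(result, config$out_dir)
  result
}

pipeline_abort <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed [E_", toupper(stage), "]: ",
       conditionMessage(e), call. = FALSE)
}

summarise_cohort_spec <- function(spec) {
  list(n = spec$n, female_fraction = spec$female_fraction,
       reading_correlations = spec$reading_correlations[
         upper.tri(spec$reading_correlations)],
       spm_mean = spec$spm_mean, spm_sd = spec$spm_sd,
       threshold_models = lapply(spec$threshold_models, as.list),
       truncation = spec$truncation)
}

fit_to_list <- function(fit) {
  list(n = fit$n, r2_step1 = fit$r2_step1, r2_full = fit$r2_full,
       delta_r2 = fit$delta_r2, f_change = fit$f_change,
       df1 = fit$df1, df2 = fit$df2, p_change = fit$p_change,
       f2_local = fit$f2_local, coefficients = fit$coefficients)
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(result$cohort, file.path(out_dir, "cohort.tsv"))
  jsonlite::write_json(
    list(loadings = as.list(result$composite$loadings),
         eigenvalues = result$composite$eigenvalues,
         variance_explained_pct =
           result$composite$variance_explained_pct),
    file.path(out_dir, "composite.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(result$fits, function(mode) lapply(mode, fit_to_list)),
    file.path(out_dir, "regressions.json"), auto_unbox = TRUE,
    digits = NA, dataframe = "rows")
  utils::write.table(
    data.frame(task = rownames(result$correlations$r_matrix),
               round(result$correlations$r_matrix, 6)),
    file.path(out_dir, "correlations.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> n =", x$manifest$n, "seed =", x$manifest$seed,
      "\n  modes:", paste(names(x$fits), collapse = ", "),
      "\n  tasks:", paste(x$manifest$tasks, collapse = ", "), "\n")
  invisible(x)
}
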