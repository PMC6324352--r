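#' @title End-to-end analysis pipeline
#' @description Orchestrates simulate (or read) -> score -> group -> fit ->
#'   calibrate -> report, writing every table as delimited text plus a JSON
#'   manifest with input digests, seeds, and filter counts, so a run is
#'   fully reproducible and auditable.
#' @name pipeline_cli
NULL

#' Standard clinical subgroups
#'
#' The three subgroup predicates used throughout: diabetes as measured by
#' the risk model (a diabetes condition category in the post-hierarchy
#' set), mental health and dementia as measured by the psychiatric grouper.
#'
#' @param hcc_profiles an `hcc_profiles` object.
#' @param psycms_profiles a `psycms_profiles` object for the same cohort.
#' @return named list of logical vectors aligned with the cohort.
#' @export
default_subgroups <- function(hcc_profiles, psycms_profiles) {
  pr <- hcc_profiles$profiles
  dm_ids <- unique(hcc_profiles$hccs$patient_id[
    hcc_profiles$hccs$cc %in% c("CC18", "CC19")])
  fl <- psycms_profiles$flags
  stopifnot(identical(pr$patient_id, fl$patient_id))
  list(diabetes = pr$patient_id %in% dm_ids,
       mental_health = fl$any_mh_sa,
       dementia = fl$dementia)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_rc("pipeline stage '%s' failed: %s", stage, conditionMessage(e),
            class = "riskcalib_pipeline_error")
  })
}

#' Run the full analysis pipeline
#'
#' With `simulate = TRUE` (default) the cohort, risk-model bundle and code
#' list are generated by [generate_cohort()]; otherwise they are read from
#' `input_dir` (the layout written by [write_synthetic()]). The pipeline
#' then scores the cohort, classifies psychiatric comorbidity, fits the base
#' and augmented cost models for each requested family, builds calibration
#' tables for the full cohort and the three standard subgroups, the
#' missed-diagnosis table, the descriptive summary, and the base-vs-
#' augmented improvement series, and writes everything under `out_dir` with
#' a machine-readable manifest.
#'
#' @param out_dir output directory.
#' @param n,seed,mispricing simulation settings (used when `simulate`).
#' @param simulate generate inputs (default) or read them from `input_dir`.
#' @param input_dir input directory when `simulate = FALSE`.
#' @param families model families to fit (first one drives calibration).
#' @param cost_year analysis year.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, n = 5000L, seed = 1L, mispricing = "MH_UNPRICED",
                         simulate = TRUE, input_dir = NULL,
                         families = c("ols_linear"), cost_year = 2012L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  if (simulate) {
    gen <- pipeline_stage("simulate", {
      generate_cohort(generator_config(n = n, seed = seed,
                                       mispricing = mispricing,
                                       cost_year = cost_year))
    })
    cohort <- gen$cohort; spec <- gen$spec; codelist <- gen$codelist
    say("simulate: n=%d seed=%d mispricing=%s", n, seed, mispricing)
  } else {
    gen <- NULL
    cohort <- pipeline_stage("read", {
      cl <- read_claims(file.path(input_dir, "claims", "diagnoses.csv"),
                        file.path(input_dir, "claims", "costs.csv"),
                        file.path(input_dir, "claims", "demographics.csv"))
      say("read: %d rows rejected", cl$report$n_rejected)
      assemble_cohort(cl, cost_year)
    })
    spec <- pipeline_stage("scoring", {
      load_model_spec(file.path(input_dir, "model_spec"))
    })
    codelist <- pipeline_stage("grouping", {
      load_psycms_codelist(file.path(input_dir, "psycms"))
    })
  }
  say("cohort: %d patients (excluded: medication_only=%d, no_va_use=%d)",
      nrow(cohort$patients), cohort$exclusions["medication_only"],
      cohort$exclusions["no_va_use"])

  hcc <- pipeline_stage("scoring", score_cohort(cohort, spec))
  say("scoring: mean score %.2f, %d unmapped diagnosis events",
      mean(hcc$profiles$score), hcc$n_unmapped)
  psy <- pipeline_stage("grouping", classify_cohort(cohort, codelist))

  scores <- hcc$profiles$score
  models <- list()
  for (fam in families) {
    models[[paste0(fam, "_base")]] <- pipeline_stage("fit",
      fit_cost_model(cohort, scores, family = fam))
    models[[paste0(fam, "_augmented")]] <- pipeline_stage("fit",
      fit_cost_model(cohort, scores, psycms_profiles = psy,
                     codelist = codelist, family = fam))
    say("fit %s: R^2 base %.4f augmented %.4f", fam,
        models[[paste0(fam, "_base")]]$r_squared,
        models[[paste0(fam, "_augmented")]]$r_squared)
  }
  model_files <- character()
  for (nm in names(models)) {
    f <- file.path(out_dir, paste0("model_", nm, ".json"))
    write_cost_model(models[[nm]], f)
    model_files <- c(model_files, f)
  }

  fam1 <- families[1]
  pred_base <- predict(models[[paste0(fam1, "_base")]], scores)
  pred_aug <- predict(models[[paste0(fam1, "_augmented")]], scores,
                      psycms_profiles = psy, codelist = codelist)
  subgroups <- default_subgroups(hcc, psy)
  cal_files <- character()
  cal <- pipeline_stage("calibrate", {
    tabs <- list(full_cohort = calibration_table(cohort, pred_base,
                                                 label = "full_cohort"))
    for (nm in names(subgroups)) {
      tabs[[nm]] <- tryCatch(
        calibration_table(cohort, pred_base, subgroups[[nm]], label = nm),
        riskcalib_decile_error = function(e) {
          say("calibrate: subgroup '%s' skipped (%s)", nm, conditionMessage(e))
          NULL
        })
    }
    Filter(Negate(is.null), tabs)
  })
  for (nm in names(cal)) {
    f <- file.path(out_dir, paste0("calibration_", nm, ".csv"))
    write_calibration(cal[[nm]], f)
    cal_files <- c(cal_files, f)
  }

  imp <- pipeline_stage("calibrate",
    improvement_series(cohort, pred_base, pred_aug,
                       subgroup = subgroups$mental_health))
  imp_file <- file.path(out_dir, "improvement_series.csv")
  utils::write.csv(imp$deciles, imp_file, row.names = FALSE, quote = FALSE)

  missed <- pipeline_stage("report", missed_mh_analysis(hcc, psy, codelist))
  missed_file <- file.path(out_dir, "missed_diagnoses.csv")
  write_missed_table(missed, missed_file)
  say("missed: %d patients with psychiatric diagnoses unseen by the risk model",
      missed$denominator)

  summary_tab <- pipeline_stage("report", {
    summarize_cohort(cohort,
                     flags = c(list(diabetes_v21 = subgroups$diabetes,
                                    any_mh_v21 = hcc$profiles$has_mh_hcc),
                               as.list(psy$flags[, -1, drop = FALSE])),
                     scores = scores)
  })
  summary_file <- file.path(out_dir, "cohort_summary.csv")
  utils::write.csv(summary_tab, summary_file, row.names = FALSE, quote = FALSE)

  log_file <- file.path(out_dir, "run.log")
  writeLines(log_lines, log_file)

  outputs <- c(model_files, cal_files, imp_file, missed_file, summary_file)
  manifest <- list(
    seed = seed, n = nrow(cohort$patients), mispricing = if (simulate) mispricing else NA,
    cost_year = cohort$cost_year, families = families,
    improvement_reduction = imp$reduction,
    package_version = as.character(utils::packageVersion("riskcalib")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
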