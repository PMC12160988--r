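# End-to-end orchestration: simulate images -> measure -> qc ->
# simulate cohort -> exclusions -> match -> fit -> report.

#' Configuration of a full pipeline run
#'
#' Every random operation reads a stage seed from the configuration, so a
#' saved configuration fully reproduces a run.
#'
#' @param out_dir Output directory of the run.
#' @param n_images Number of synthetic images.
#' @param degraded_frac Fraction of deliberately degraded images.
#' @param image_size Image side, px.
#' @param cohort A [cohort_params()]; the default enlarges the control arm so
#'   that 1:1 matching of the combined case arms has a pool to draw from.
#' @param exclusion_rules Passed to [apply_exclusions()] on the cohort.
#' @param measures Pallor measures to model.
#' @param image_seed,cohort_seed,match_seed Stage seeds (all required).
#' @param write_images Write PNGs and masks of the simulated images.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("pallorkit_run_"),
                       n_images = 24, degraded_frac = 0.15, image_size = 512,
                       cohort = cohort_params(n_control = 900),
                       exclusion_rules = list(),
                       measures = pallor_measures(),
                       image_seed = 101L, cohort_seed = 202L,
                       match_seed = 303L,
                       write_images = FALSE) {
  structure(list(out_dir = out_dir, n_images = n_images,
                 degraded_frac = degraded_frac, image_size = image_size,
                 cohort = cohort, exclusion_rules = exclusion_rules,
                 measures = measures, image_seed = image_seed,
                 cohort_seed = cohort_seed, match_seed = match_seed,
                 write_images = write_images),
            class = "run_config")
}

validate_run_config <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  for (s in c("image_seed", "cohort_seed", "match_seed"))
    if (is.null(config[[s]]) || is.na(config[[s]]))
      stop("run_config is missing required seed '", s, "'", call. = FALSE)
  if (!inherits(config$cohort, "cohort_params"))
    stop("config$cohort must be cohort_params", call. = FALSE)
  if (!all(config$measures %in% pallor_measures()))
    stop("unknown measure in config$measures", call. = FALSE)
  invisible(config)
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in order, writing intermediate CSVs and a
#' flowchart-style counts log (images generated and QC-rejected, cohort
#' participants generated, excluded, matched and modelled) to the run
#' directory. Any stage failure halts with the stage name.
#'
#' @param config A [run_config()]; validated before execution.
#' @return An object of class `pallor_run`: result tables, file paths and the
#'   provenance counts, invisibly printable.
#' @export
run_pipeline <- function(config = run_config()) {
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # 1. simulate images
  batch <- stage("simulate-images",
                 generate_batch(config$n_images, degraded_frac = config$degraded_frac,
                                image_size = config$image_size,
                                seed = config$image_seed))
  if (config$write_images) stage("write-images", write_batch(batch, out("images")))
  truth <- batch_truth(batch)
  utils::write.csv(truth, out("image_truth.csv"), row.names = FALSE)

  # 2. quality control, then 3. measurement of passing images
  qc <- stage("qc", qc_batch(batch))
  utils::write.csv(qc, out("qc.csv"), row.names = FALSE)
  passing <- batch[qc$pass]
  pallor <- stage("measure",
                  if (length(passing)) measure_batch(passing)
                  else stop("no image passed quality control"))
  utils::write.csv(pallor, out("pallor.csv"), row.names = FALSE)

  # 4. simulate cohort + exclusions
  cohort <- stage("simulate-cohort",
                  generate_cohort(config$cohort, seed = config$cohort_seed))
  ex <- stage("exclusions", apply_exclusions(cohort, config$exclusion_rules))
  cohort_kept <- ex$table
  utils::write.csv(cohort_kept, out("cohort.csv"), row.names = FALSE)
  if (nrow(ex$log)) utils::write.csv(ex$log, out("exclusions.csv"), row.names = FALSE)

  # 5. age/sex matching: combined case arms vs control pool, 1:1
  cases <- cohort_kept[cohort_kept$group != "control", , drop = FALSE]
  pool <- cohort_kept[cohort_kept$group == "control", , drop = FALSE]
  mt <- stage("match", match_controls(cases, pool, ratio = 1,
                                      seed = config$match_seed))
  analysis <- rbind(cases, pool[pool$id %in% mt$control_ids, , drop = FALSE])
  utils::write.csv(mt$pairs, out("matched_pairs.csv"), row.names = FALSE)

  # 6. adjusted models per measure: logistic per case arm, linear durations
  fits <- stage("fit", {
    rows_logit <- list(); rows_lin <- list()
    for (ms in config$measures) {
      for (arm in c("prevalent_pd", "incident_pd")) {
        d <- analysis[analysis$group %in% c(arm, "control"), , drop = FALSE]
        if (!any(d$group == arm)) next
        d$case <- d$group == arm
        m <- fit_logistic(d, "case", ms)
        rows_logit[[paste(arm, ms)]] <- cbind(arm = arm, model_row(m))
      }
      prev <- analysis[analysis$group == "prevalent_pd", , drop = FALSE]
      if (nrow(prev) > 15) {
        m <- fit_linear(prev, ms, "years_since_dx",
                        response = if (config$cohort$duration_model == "sd_per_year")
                          "pallor" else "duration")
        rows_lin[[paste("prevalent_pd", ms)]] <- cbind(arm = "prevalent_pd",
                                                       model_row(m))
      }
      inc <- analysis[analysis$group == "incident_pd", , drop = FALSE]
      if (nrow(inc) > 15) {
        m <- fit_linear(inc, ms, "years_to_dx",
                        response = if (config$cohort$duration_model == "sd_per_year")
                          "pallor" else "duration")
        rows_lin[[paste("incident_pd", ms)]] <- cbind(arm = "incident_pd",
                                                      model_row(m))
      }
    }
    list(logistic = do.call(rbind, rows_logit), linear = do.call(rbind, rows_lin))
  })
  utils::write.csv(fits$logistic, out("models_logistic.csv"), row.names = FALSE)
  utils::write.csv(fits$linear, out("models_linear.csv"), row.names = FALSE)

  # 7. flowchart-style provenance counts
  grp <- function(tab) as.list(table(factor(tab$group,
    levels = c("control", "prevalent_pd", "incident_pd"))))
  counts <- list(
    images = list(generated = length(batch),
                  degraded = sum(truth$degraded),
                  qc_rejected = sum(!qc$pass),
                  measured = sum(qc$pass)),
    cohort = list(generated = grp(cohort),
                  excluded = as.list(stats::setNames(ex$log$n_removed, ex$log$rule)),
                  after_exclusions = grp(cohort_kept),
                  matched_controls = length(mt$control_ids),
                  analyzed = grp(analysis),
                  unmatched_controls = sum(cohort_kept$group == "control") -
                    length(mt$control_ids)))
  jsonlite::write_json(counts, out("provenance.json"), auto_unbox = TRUE,
                       digits = NA)

  structure(list(config = config, qc = qc, pallor = pallor,
                 cohort = cohort_kept, match = mt, analysis = analysis,
                 models_logistic = fits$logistic, models_linear = fits$linear,
                 counts = counts, out_dir = config$out_dir),
            class = "pallor_run")
}

#' @export
print.pallor_run <- function(x, ...) {
  cat("pallorkit pipeline run:", x$out_dir, "\n")
  cat(sprintf("  images: %d generated, %d QC-rejected, %d measured\n",
              x$counts$images$generated, x$counts$images$qc_rejected,
              x$counts$images$measured))
  cat(sprintf("  cohort: %d analyzed (%d matched controls)\n",
              nrow(x$analysis), x$counts$cohort$matched_controls))
  cat(sprintf("  models: %d logistic, %d linear rows\n",
              NROW(x$models_logistic), NROW(x$models_linear)))
  invisible(x)
}
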