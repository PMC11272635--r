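#' End-to-end simulation pipeline
#'
#' Ties the stages together: sample a synthetic cohort, run the 12-condition
#' protocol at each pelvic tilt, build the incidence table, summarize it,
#' and fit/compare the mixed models. All outputs are CSV files in the run
#' directory, together with the configuration used (copied verbatim) and a
#' plain-text log of the settings in force.
#'
#' @name io_cli
NULL

#' Pipeline run configuration
#'
#' @param seed integer seed for cohort sampling.
#' @param n_patients cohort size.
#' @param tilts pelvic tilt grid in degrees (default -10, 0, +10).
#' @param resolution mesh edge length, mm.
#' @param out_dir output directory for [run_pipeline()].
#' @param write_meshes also write per-patient STL meshes and landmark JSON
#'   files (off by default; they are large).
#' @param fit_models fit the mixed models (requires a tilt grid with
#'   variance).
#' @param cohort optional [cohort_spec()] overriding the default cohort
#'   distributions (its seed/n are taken from `seed`/`n_patients`).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_patients = 20L, tilts = c(-10, 0, 10),
                       resolution = 1.5, out_dir = "hip_run",
                       write_meshes = FALSE, fit_models = TRUE,
                       cohort = NULL) {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              tilts = as.numeric(tilts), resolution = resolution,
              out_dir = out_dir, write_meshes = isTRUE(write_meshes),
              fit_models = isTRUE(fit_models),
              cohort = cohort)
  class(cfg) <- "run_config"
  cfg
}

#' Write/read a run configuration as plain-text JSON
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `run_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- if (!is.null(x$cohort)) unclass(x$cohort) else NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- NULL
  if (!is.null(x$cohort)) {
    co <- x$cohort
    co$means <- unlist(co$means); co$sds <- unlist(co$sds)
    co$aiis_prob <- unlist(co$aiis_prob)
    class(co) <- "cohort_spec"
  }
  run_config(seed = x$seed, n_patients = x$n_patients, tilts = x$tilts,
             resolution = x$resolution, out_dir = x$out_dir,
             write_meshes = x$write_meshes, fit_models = x$fit_models,
             cohort = co)
}

#' Run the full simulation pipeline
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the run directory path, invisibly. The directory contains
#'   `config.json`, `cohort.csv` (measured covariates), `records.csv`
#'   (per-condition impingement records), `incidence.csv` (the long-format
#'   contract), `summary_overall.csv` and subgroup summaries, and when
#'   model fitting is enabled `coefficients.csv` (the fitted fixed effects
#'   with CIs), `model_comparison.csv`, `tilt_profile.csv` (per-region mean
#'   incidence with 95% CI vs tilt, line-plot data) and `run_log.txt`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  write_config(config, file.path(config$out_dir, "config.json"))

  if (config$fit_models && length(unique(config$tilts)) < 2)
    stop("stage 'mixed_model' refused: the tilt grid ",
         "has no variance (need at least two distinct tilts)", call. = FALSE)

  spec <- config$cohort
  if (is.null(spec)) spec <- cohort_spec(n_patients = config$n_patients,
                                         seed = config$seed)
  else { spec$n_patients <- config$n_patients; spec$seed <- config$seed }

  say("stage synth: generating ", spec$n_patients, " hips")
  cohort <- tryCatch(sample_cohort(spec, resolution = config$resolution,
                                   quiet = quiet),
                     error = function(e)
                       stop("stage 'synth' failed: ", conditionMessage(e),
                            call. = FALSE))
  write.csv(cohort$covariates, file.path(config$out_dir, "cohort.csv"),
            row.names = FALSE)
  if (config$write_meshes) {
    mdir <- file.path(config$out_dir, "meshes")
    dir.create(mdir, showWarnings = FALSE)
    for (i in seq_along(cohort$models)) {
      m <- cohort$models[[i]]
      write_stl(m$pelvis, file.path(mdir, sprintf("patient%03d_pelvis.stl", i)))
      write_stl(m$femur, file.path(mdir, sprintf("patient%03d_femur.stl", i)))
      write_landmarks_json(m$pelvis,
                           file.path(mdir, sprintf("patient%03d_pelvis.json", i)))
      write_landmarks_json(m$femur,
                           file.path(mdir, sprintf("patient%03d_femur.json", i)))
    }
  }

  say("stage simulate: ", length(config$tilts), " tilt conditions x 12 postures")
  recs <- vector("list", length(cohort$models) * length(config$tilts))
  ri <- 0
  for (i in seq_along(cohort$models)) {
    for (tau in config$tilts) {
      ri <- ri + 1
      recs[[ri]] <- tryCatch(
        run_protocol(cohort$models[[i]], tau, patient_id = i),
        error = function(e)
          stop("stage 'simulate' failed for patient ", i, " at tilt ", tau,
               ": ", conditionMessage(e), call. = FALSE))
    }
    say("  patient ", i, "/", length(cohort$models))
  }
  records <- do.call(rbind, recs)
  write.csv(records, file.path(config$out_dir, "records.csv"), row.names = FALSE)

  say("stage incidence")
  inc <- cohort_incidence(records, cohort$covariates)
  write_incidence_csv(inc, file.path(config$out_dir, "incidence.csv"))
  summ <- summarize_cohort(inc)
  write.csv(summ$overall, file.path(config$out_dir, "summary_overall.csv"),
            row.names = FALSE)
  write.csv(summ$by_aiis, file.path(config$out_dir, "summary_by_aiis.csv"),
            row.names = FALSE)
  write.csv(summ$by_fv, file.path(config$out_dir, "summary_by_fv.csv"),
            row.names = FALSE)
  write.csv(summ$by_lcea, file.path(config$out_dir, "summary_by_lcea.csv"),
            row.names = FALSE)

  fit <- cmp <- NULL
  if (config$fit_models) {
    say("stage analyze: mixed models")
    fit <- tryCatch(fit_mixed(inc), error = function(e)
      stop("stage 'analyze' failed: ", conditionMessage(e), call. = FALSE))
    write.csv(fit$coefficients, file.path(config$out_dir, "coefficients.csv"),
              row.names = FALSE)
    cmp <- compare_models(inc)
    write.csv(cmp, file.path(config$out_dir, "model_comparison.csv"),
              row.names = FALSE)
    prof <- .tilt_profile(inc)
    write.csv(prof, file.path(config$out_dir, "tilt_profile.csv"),
              row.names = FALSE)
  }

  k <- gen_constants()
  log_lines <- c(
    paste("hipimpinge", as.character(utils::packageVersion("hipimpinge"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("seed", config$seed),
    paste("n_patients", config$n_patients),
    paste("tilts", paste(config$tilts, collapse = " ")),
    paste("resolution_mm", config$resolution),
    paste("clipped_draws", attr(cohort$covariates, "n_clipped")),
    "settings:",
    paste(" ", names(k), vapply(k, function(v) paste(v, collapse = "/"),
                                character(1))))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  say("done: ", config$out_dir)
  invisible(config$out_dir)
}

# Per-region mean incidence with normal-theory 95% CI at each tilt (the
# line-plot data for incidence-vs-tilt figures).
.tilt_profile <- function(inc) {
  ag <- aggregate(incidence_pct ~ tilt_deg + region, inc, function(v) {
    m <- mean(v); s <- if (length(v) > 1) sd(v) else NA_real_
    half <- if (is.na(s)) NA_real_ else qt(0.975, length(v) - 1) * s / sqrt(length(v))
    c(mean = m, lo = m - half, hi = m + half, n = length(v))
  })
  data.frame(tilt_deg = ag$tilt_deg, region = ag$region,
             mean = ag$incidence_pct[, "mean"],
             ci_low = ag$incidence_pct[, "lo"],
             ci_high = ag$incidence_pct[, "hi"],
             n = as.integer(ag$incidence_pct[, "n"]))
}
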