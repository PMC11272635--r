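#' Impingement incidence tables and cohort summaries
#'
#' Incidence is the percentage of the 12 protocol conditions in which bone
#' contact occurs before the activity-of-daily-living threshold:
#' `incidence = count / 12 * 100`, per acetabular region and in total. Since
#' each condition reports a single contact region (the largest patch),
#' regional counts sum exactly to the total count.
#'
#' @name incidence_stats
NULL

#' Compute per-region incidence from one 12-condition protocol run
#'
#' @param records data.frame from [run_protocol()] (exactly 12 rows, one per
#'   condition id 1..12).
#' @return data.frame with rows for regions `A`, `B`, `C` and `total`:
#'   `region`, `count`, `incidence_pct`, `n_conditions`.
#' @export
compute_incidence <- function(records) {
  ids <- sort(records$condition_id)
  if (length(ids) != 12 || !identical(as.integer(ids), 1:12))
    stop("need exactly 12 records with condition ids 1..12 (got ",
         paste(records$condition_id, collapse = ","), ")", call. = FALSE)
  cnt <- function(reg) sum(records$impinged & records$region %in% reg)
  counts <- c(A = cnt("A"), B = cnt("B"), C = cnt("C"),
              total = sum(records$impinged))
  data.frame(region = names(counts), count = as.integer(counts),
             incidence_pct = as.numeric(counts) / 12 * 100,
             n_conditions = 12L, stringsAsFactors = FALSE)
}

#' Build a long-format incidence table for a cohort run
#'
#' One row per (patient, tilt, region incl. total), with the measured
#' anatomical covariates attached. This table is the contract between the
#' simulation half and the statistics half of the pipeline.
#'
#' @param all_records row-bound [run_protocol()] records over patients and
#'   tilts.
#' @param covariates covariate table from [sample_cohort()].
#' @return data.frame with columns `patient_id`, `tilt_deg`, `region`,
#'   `incidence_pct`, `aiis_type`, `lcea`, `femoral_version`,
#'   `acetabular_version`.
#' @export
cohort_incidence <- function(all_records, covariates) {
  keys <- unique(all_records[, c("patient_id", "tilt_deg")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- all_records$patient_id == keys$patient_id[i] &
      all_records$tilt_deg == keys$tilt_deg[i]
    inc <- compute_incidence(all_records[sel, ])
    out[[i]] <- data.frame(patient_id = keys$patient_id[i],
                           tilt_deg = keys$tilt_deg[i],
                           region = inc$region,
                           incidence_pct = inc$incidence_pct,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  cv <- covariates[, c("patient_id", "aiis_type", "lcea",
                       "femoral_version", "acetabular_version")]
  merge(tab, cv, by = "patient_id", sort = TRUE)
}

.fv_class <- function(fv) cut(fv, c(-Inf, 5, 19, Inf),
                              labels = c("low", "normal", "high"), right = FALSE)
.lcea_class <- function(x) cut(x, c(-Inf, 25, 40, Inf),
                               labels = c("low", "normal", "high"), right = FALSE)

.mean_sd <- function(df) {
  ag <- aggregate(incidence_pct ~ tilt_deg + region, df, function(v)
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
      n = length(v)))
  data.frame(tilt_deg = ag$tilt_deg, region = ag$region,
             mean = ag$incidence_pct[, "mean"], sd = ag$incidence_pct[, "sd"],
             n = as.integer(ag$incidence_pct[, "n"]))
}

#' Summarize cohort incidence by tilt, region and anatomical subgroups
#'
#' Produces the per-tilt, per-region mean and sample SD table, plus subgroup
#' summaries by AIIS type, femoral-version class (low < 5, normal 5-19,
#' high > 19 degrees) and LCEA class (low < 25, normal 25-40, high > 40
#' degrees). Subgroups with no members are absent from the output; SD for
#' single-member subgroups is reported as NA.
#'
#' @param table a [cohort_incidence()] table.
#' @return list with data.frames `overall`, `by_aiis`, `by_fv`, `by_lcea`.
#' @export
summarize_cohort <- function(table) {
  if (!nrow(table)) stop("empty incidence table", call. = FALSE)
  tot <- table[table$region == "total", ]
  by_grp <- function(cls) {
    keep <- !is.na(cls)
    d <- tot[keep, ]
    d$group <- as.character(cls[keep])
    ag <- aggregate(incidence_pct ~ group + tilt_deg, d, function(v)
      c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
        n = length(v)))
    data.frame(group = ag$group, tilt_deg = ag$tilt_deg,
               mean = ag$incidence_pct[, "mean"],
               sd = ag$incidence_pct[, "sd"],
               n = as.integer(ag$incidence_pct[, "n"]))
  }
  list(overall = .mean_sd(table),
       by_aiis = by_grp(tot$aiis_type),
       by_fv = by_grp(.fv_class(tot$femoral_version)),
       by_lcea = by_grp(.lcea_class(tot$lcea)))
}

#' Read/write the long-format incidence CSV contract
#' @param table a [cohort_incidence()] table.
#' @param path CSV file path.
#' @return `write_incidence_csv` returns `path` invisibly;
#'   `read_incidence_csv` the table.
#' @export
write_incidence_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_incidence_csv
#' @export
read_incidence_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
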