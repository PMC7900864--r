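## CSV import/export for the three-table cohort interchange format.

#' Write a cohort to CSV tables
#'
#' Writes `encounters.csv` (`encounter_id`, `patient_id`, `age_years`,
#' `sex`, `race`, `arrival_datetime`, `location`, `comorbidity_count`),
#' `events.csv` (`encounter_id`, `t_minutes`, `kind`, `code`, `value`,
#' `unit`), `specimens.csv` (`encounter_id`, `t_minutes`, `tube_type`,
#' `remnant_volume_ul`, `clinical_testing_complete_minutes`) and
#' `truth_labels.csv`.
#'
#' @param cohort an [EHRCohort-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "EHRCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  enc <- cohort@encounters
  enc$arrival_datetime <- format(enc$arrival_datetime, "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC")
  paths <- file.path(dir, c("encounters.csv", "events.csv", "specimens.csv",
                            "truth_labels.csv"))
  utils::write.csv(enc, paths[1], row.names = FALSE)
  utils::write.csv(cohort@events, paths[2], row.names = FALSE)
  utils::write.csv(cohort@specimens, paths[3], row.names = FALSE)
  utils::write.csv(cohort@truth, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from CSV tables
#'
#' Inverse of [writeCohort()]. The attached configuration records only the
#' table sizes (generation parameters are not serialized).
#'
#' @param dir directory holding the CSV tables.
#' @return an [EHRCohort-class].
#' @export
readCohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  enc <- rd("encounters.csv")
  enc$arrival_datetime <- as.POSIXct(enc$arrival_datetime,
                                     format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  truth_path <- file.path(dir, "truth_labels.csv")
  truth <- if (file.exists(truth_path)) rd("truth_labels.csv")
           else data.frame(encounter_id = enc$encounter_id, true_sepsis = NA)
  new("EHRCohort", encounters = enc, events = rd("events.csv"),
      specimens = rd("specimens.csv"), truth = truth,
      config = generatorConfig(nEncounters = nrow(enc), seed = 0))
}
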