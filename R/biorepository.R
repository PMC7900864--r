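## Remnant-specimen eligibility, aliquot accounting and availability
## reporting for the virtually enabled biorepository.

#' Remnant-volume minima per tube type
#'
#' Blood minima: heparin strictly greater than 550 uL, EDTA at least 450 uL,
#' sodium fluoride at least 225 uL; urine at least 125 uL. The citrate
#' minimum is not stated by the screening protocol and defaults to the
#' EDTA-like 450 uL (configurable).
#'
#' @return data.frame with `tube_type`, `min_volume_ul`, `strict`.
#' @export
remnantVolumeRules <- function() {
  data.frame(
    tube_type = c("heparin", "edta", "sodium_fluoride", "citrate", "urine"),
    min_volume_ul = c(550, 450, 225, 450, 125),
    strict = c(TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Assess remnant-specimen eligibility
#'
#' A specimen enters the biorepository when (1) its tube type is known, (2)
#' it is collected from the clinical laboratory within 48 hours (2880
#' minutes) of acquisition, (3) collection happens after clinical testing is
#' complete, and (4) its remnant volume meets the tube-type minimum
#' (strict `>` for heparin, `>=` otherwise). Eligibility is volume- and
#' time-monotone: more volume or a shorter delay never flips an eligible
#' specimen to rejected.
#'
#' @param specimens data.frame with `encounter_id` (or `study_id`),
#'   `t_minutes`, `tube_type`, `remnant_volume_ul`,
#'   `clinical_testing_complete_minutes` and optionally
#'   `collected_from_lab_minutes` (defaults to the testing-complete time,
#'   i.e. staff pick the tube up as soon as testing finishes).
#' @param maxDelayMinutes collection window after acquisition (default 2880).
#' @param rules volume minima, see [remnantVolumeRules()].
#' @param aliquotVolumeUl aliquot size used for accounting (default 125).
#' @return list with `samples` (eligible rows, with `aliquot_count =
#'   floor(volume / aliquotVolumeUl)`) and `rejects` (rows with a `reason`
#'   in `unknown_tube`, `window_48h`, `before_testing_complete`,
#'   `insufficient_volume`).
#' @export
#' @examples
#' sp <- data.frame(encounter_id = "E1", t_minutes = 30, tube_type = "heparin",
#'                  remnant_volume_ul = c(550, 551),
#'                  clinical_testing_complete_minutes = 200)
#' assessRemnantEligibility(sp)$rejects$reason  # 550 fails the strict minimum
assessRemnantEligibility <- function(specimens, maxDelayMinutes = 2880,
                                     rules = remnantVolumeRules(),
                                     aliquotVolumeUl = 125) {
  checkColumns(specimens, c("t_minutes", "tube_type", "remnant_volume_ul",
                            "clinical_testing_complete_minutes"), "specimens")
  sp <- specimens
  if (!"collected_from_lab_minutes" %in% names(sp))
    sp$collected_from_lab_minutes <- sp$clinical_testing_complete_minutes

  reason <- rep(NA_character_, nrow(sp))
  known <- sp$tube_type %in% rules$tube_type
  reason[!known] <- "unknown_tube"

  delay <- sp$collected_from_lab_minutes - sp$t_minutes
  sel <- is.na(reason) & delay > maxDelayMinutes
  reason[sel] <- "window_48h"
  sel <- is.na(reason) &
    sp$collected_from_lab_minutes < sp$clinical_testing_complete_minutes
  reason[sel] <- "before_testing_complete"

  idx <- match(sp$tube_type, rules$tube_type)
  ok <- volumeOk(sp$remnant_volume_ul, rules$min_volume_ul[idx], rules$strict[idx])
  sel <- is.na(reason) & !ok
  reason[sel] <- "insufficient_volume"

  eligible <- is.na(reason)
  samples <- sp[eligible, , drop = FALSE]
  samples$aliquot_count <- floor(samples$remnant_volume_ul / aliquotVolumeUl)
  rejects <- sp[!eligible, , drop = FALSE]
  rejects$reason <- reason[!eligible]
  rownames(samples) <- rownames(rejects) <- NULL
  list(samples = samples, rejects = rejects)
}

#' Aliquot accounting over the enrolled cohort
#'
#' Per-patient specimen availability by tube type (a patient "has two or more
#' aliquots" of a tube type when at least two eligible specimens of that type
#' exist), the fraction of enrolled patients with two or more eligible
#' specimens of any type, urine availability, and the total aliquot counter.
#' Percentages are integer-rounded over the enrolled denominator.
#'
#' @param samples eligible samples from [assessRemnantEligibility()], carrying
#'   a patient key column (`study_id` or `encounter_id`).
#' @param enrolledIds character vector of enrolled patient keys: the report
#'   denominator.
#' @param idColumn name of the patient key column (default `"study_id"` if
#'   present, else `"encounter_id"`).
#' @return list with `per_patient` (wide table of eligible-specimen counts by
#'   tube type), `ge2_any` / `ge2_by_tube` / `urine_ge2` (named lists with
#'   `count`, `denominator`, `percent`), and `total_aliquots`.
#' @export
aliquotAccounting <- function(samples, enrolledIds,
                              idColumn = if ("study_id" %in% names(samples))
                                "study_id" else "encounter_id") {
  checkColumns(samples, c(idColumn, "tube_type", "aliquot_count"), "samples")
  if (!length(enrolledIds)) stop("enrolledIds must be non-empty")
  dt <- data.table::as.data.table(samples)
  data.table::setnames(dt, idColumn, "pid")
  dt <- dt[pid %in% enrolledIds]
  n <- length(enrolledIds)

  counts <- dt[, .(n_specimens = .N, n_aliquots = sum(aliquot_count)),
               by = .(pid, tube_type)]
  wide <- data.table::dcast(counts, pid ~ tube_type, value.var = "n_specimens",
                            fill = 0L)
  per_patient <- merge(data.table::data.table(pid = enrolledIds), wide,
                       by = "pid", all.x = TRUE)
  for (j in setdiff(names(per_patient), "pid"))
    data.table::set(per_patient, which(is.na(per_patient[[j]])), j, 0L)

  stat <- function(count) list(count = count, denominator = n,
                               percent = percentValue(count, n))
  any2 <- counts[, .(tot = sum(n_specimens)), by = pid][tot >= 2L, pid]
  blood <- setdiff(unique(dt$tube_type), "urine")
  ge2_by_tube <- lapply(stats::setNames(blood, blood), function(tt) {
    stat(length(counts[tube_type == tt & n_specimens >= 2L, unique(pid)]))
  })
  urine2 <- counts[tube_type == "urine" & n_specimens >= 2L, unique(pid)]

  list(per_patient = as.data.frame(per_patient),
       ge2_any = stat(length(any2)),
       ge2_by_tube = ge2_by_tube,
       urine_ge2 = stat(length(urine2)),
       total_aliquots = sum(dt$aliquot_count))
}

#' Biorepository report for an enrolled cohort
#'
#' Convenience wrapper chaining [assessRemnantEligibility()] and
#' [aliquotAccounting()] over the specimens of enrolled patients, keyed by
#' study identifier through the crosswalk.
#'
#' @param specimens full specimen table (`encounter_id` keyed).
#' @param crosswalk the [Crosswalk-class] of the enrolled cohort.
#' @param ... passed to [assessRemnantEligibility()].
#' @return the [aliquotAccounting()] list plus `rejects`.
#' @export
biorepositoryReport <- function(specimens, crosswalk, ...) {
  stopifnot(is(crosswalk, "Crosswalk"))
  m <- crosswalk@map
  sp <- specimens[specimens$encounter_id %in% m$encounter_id, , drop = FALSE]
  sp$study_id <- m$study_id[match(sp$encounter_id, m$encounter_id)]
  elig <- assessRemnantEligibility(sp, ...)
  rep <- aliquotAccounting(elig$samples, m$study_id, idColumn = "study_id")
  rep$rejects <- elig$rejects
  rep
}
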