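## Enrollment funnel: daily cap, ordered three-reason exclusion cascade,
## de-identification crosswalk and funnel reports with conservation checks.

#' Required tube types and volume minima for enrollment
#'
#' The minimum set of remnant blood tubes required for enrollment: at least
#' one heparin (volume strictly greater than 550 uL), one EDTA (>= 450 uL)
#' and one sodium-fluoride (>= 225 uL) specimen collected inside the
#' screening window. Urine never affects enrollment.
#'
#' @return data.frame with columns `tube_type`, `min_volume_ul`, `strict`
#'   (TRUE for a strict `>` comparison).
#' @export
requiredTubeRules <- function() {
  data.frame(
    tube_type = c("heparin", "edta", "sodium_fluoride"),
    min_volume_ul = c(550, 450, 225),
    strict = c(TRUE, FALSE, FALSE)
  )
}

#' Partition flags under the daily enrollment cap
#'
#' Per calendar day (local midnight of the simulated arrival datetime, UTC),
#' the first `capPerDay` flags by flag time are screened; the remainder are
#' capped. Ties on flag time break by ascending `encounter_id`.
#'
#' @param flags data.frame of flagged encounters with `encounter_id`,
#'   `flag_time_minutes` and `arrival_datetime` (POSIXct or parseable).
#' @param capPerDay non-negative daily cap (default 4).
#' @return the flags table with added columns `flag_day` (Date) and
#'   `screened` (logical); `!screened` rows are the cap casualties.
#' @export
#' @examples
#' fl <- data.frame(encounter_id = sprintf("E%d", 1:6),
#'                  flag_time_minutes = c(10, 50, 20, 40, 30, 60),
#'                  arrival_datetime = as.POSIXct("2020-01-01", tz = "UTC"))
#' table(applyDailyCap(fl, 4)$screened)
applyDailyCap <- function(flags, capPerDay = 4) {
  checkColumns(flags, c("encounter_id", "flag_time_minutes", "arrival_datetime"),
               "flags")
  stopifnot(capPerDay >= 0)
  if (!nrow(flags)) {
    flags$flag_day <- as.Date(character())
    flags$screened <- logical()
    return(flags)
  }
  arrival <- as.POSIXct(flags$arrival_datetime, tz = "UTC")
  flag_at <- arrival + flags$flag_time_minutes * 60
  flags$flag_day <- as.Date(flag_at, tz = "UTC")
  ord <- order(flags$flag_day, flags$flag_time_minutes, flags$encounter_id)
  rank_in_day <- stats::ave(seq_along(ord), flags$flag_day[ord],
                            FUN = seq_along)
  screened <- logical(nrow(flags))
  screened[ord] <- rank_in_day <= capPerDay
  flags$screened <- screened
  flags
}

## does one encounter's in-window specimen set satisfy the tube rules?
## returns "none" when no in-window specimen exists at all, otherwise the
## first failing reason in printed order, or "pass"
volumeOk <- function(vol, minimum, strict) {
  strict <- rep_len(strict, length(vol))
  minimum <- rep_len(minimum, length(vol))
  ifelse(strict, vol > minimum, vol >= minimum)
}

#' Classify screened flags into enrolled and excluded
#'
#' Applies the three printed exclusion rules in order: (1) specimens not
#' collected within the window, (2) insufficient remnant volume, (3) required
#' tube types absent. The first failing rule becomes the recorded reason;
#' passing all three yields enrollment. Rule (2) fires when some required
#' tube type has in-window specimens but none meeting its volume minimum;
#' rule (3) when a required tube type has no in-window specimen at all while
#' every tube type that is present meets its minimum.
#'
#' @param screenedFlags data.frame of screened flags (`encounter_id`, plus
#'   any columns to carry through, e.g. `patient_id`, `flag_day`).
#' @param specimens specimen table (`encounter_id`, `t_minutes`, `tube_type`,
#'   `remnant_volume_ul`). Orphan rows (no matching flag) are ignored with a
#'   warning.
#' @param windowMinutes specimen collection window (default 360).
#' @param tubeRules required tube types and minima, see [requiredTubeRules()].
#' @return `screenedFlags` with added `status` (`"enrolled"` or
#'   `"excluded"`) and `exclusion_reason` (`"none"`, `"specimen_window"`,
#'   `"insufficient_volume"` or `"tube_types_absent"`).
#' @export
classifyExclusions <- function(screenedFlags, specimens, windowMinutes = 360,
                               tubeRules = requiredTubeRules()) {
  checkColumns(screenedFlags, "encounter_id", "screenedFlags")
  checkColumns(specimens, c("encounter_id", "t_minutes", "tube_type",
                            "remnant_volume_ul"), "specimens")
  orphan <- setdiff(unique(specimens$encounter_id), screenedFlags$encounter_id)
  if (length(orphan))
    warning(sprintf("%d specimen row(s) without a matching screened flag; ignored",
                    sum(specimens$encounter_id %in% orphan)))
  sp <- data.table::as.data.table(specimens)
  sp <- sp[encounter_id %in% screenedFlags$encounter_id]
  anywin <- sp[t_minutes >= 0 & t_minutes < windowMinutes]

  ids <- screenedFlags$encounter_id
  has_window_specimen <- ids %in% unique(anywin$encounter_id)

  present <- matrix(FALSE, length(ids), nrow(tubeRules),
                    dimnames = list(ids, tubeRules$tube_type))
  meets <- present
  for (i in seq_len(nrow(tubeRules))) {
    tr <- tubeRules[i, ]
    d <- anywin[tube_type == tr$tube_type]
    present[, i] <- ids %in% unique(d$encounter_id)
    ok <- d[volumeOk(remnant_volume_ul, tr$min_volume_ul, tr$strict),
            unique(encounter_id)]
    meets[, i] <- ids %in% ok
  }
  insufficient <- rowSums(present & !meets) > 0
  absent <- rowSums(!present) > 0

  reason <- rep("none", length(ids))
  reason[!has_window_specimen] <- "specimen_window"
  sel <- reason == "none" & insufficient
  reason[sel] <- "insufficient_volume"
  sel <- reason == "none" & absent
  reason[sel] <- "tube_types_absent"

  out <- screenedFlags
  out$status <- ifelse(reason == "none", "enrolled", "excluded")
  out$exclusion_reason <- reason
  out
}

#' Assign study identifiers and de-identify enrollment records
#'
#' Enrolled records receive sequential zero-padded study identifiers
#' (default `VESPRE-0001` upward, in flag-time then encounter order). The
#' crosswalk linking study identifiers to patient and encounter identifiers
#' is returned separately from the de-identified export, which carries no
#' `patient_id` and no absolute datetimes.
#'
#' @param records output of [classifyExclusions()] (optionally with capped
#'   records appended), needing `encounter_id`, `status` and, for the
#'   crosswalk, `patient_id`.
#' @param prefix study-identifier prefix.
#' @param width zero-padding width (default 4, grows as needed).
#' @return list with elements `crosswalk` (a [Crosswalk-class]) and
#'   `deidentified` (records with `study_id`, stripped of identifiers).
#' @export
assignStudyIds <- function(records, prefix = "VESPRE", width = 4) {
  checkColumns(records, c("encounter_id", "status"), "records")
  enrolled <- records[records$status == "enrolled", , drop = FALSE]
  if (anyDuplicated(enrolled$encounter_id))
    stop("duplicate enrollment of encounter(s): ",
         paste(unique(enrolled$encounter_id[duplicated(enrolled$encounter_id)]),
               collapse = ", "))
  if ("flag_time_minutes" %in% names(enrolled)) {
    day <- if ("flag_day" %in% names(enrolled)) enrolled$flag_day
           else rep(0L, nrow(enrolled))
    enrolled <- enrolled[order(day, enrolled$flag_time_minutes,
                               enrolled$encounter_id), , drop = FALSE]
  }
  n <- nrow(enrolled)
  width <- max(width, nchar(as.character(max(n, 1L))))
  study_id <- if (n) sprintf("%s-%0*d", prefix, width, seq_len(n)) else character()
  xw <- data.frame(
    study_id = study_id,
    patient_id = if ("patient_id" %in% names(enrolled)) enrolled$patient_id
                 else rep(NA_character_, n),
    encounter_id = enrolled$encounter_id,
    stringsAsFactors = FALSE)
  crosswalk <- new("Crosswalk", map = xw,
                   created = as.POSIXct(Sys.time(), tz = "UTC"))
  deid <- records
  deid$study_id <- xw$study_id[match(deid$encounter_id, xw$encounter_id)]
  drop <- intersect(c("patient_id", "arrival_datetime"), names(deid))
  deid <- deid[, setdiff(names(deid), drop), drop = FALSE]
  ## encounter_id is retained internally only through the crosswalk
  deid$encounter_id <- NULL
  list(crosswalk = crosswalk, deidentified = deid)
}

#' Re-identify a de-identified export through the crosswalk
#'
#' @param deidentified the de-identified records (with `study_id`).
#' @param crosswalk the [Crosswalk-class] from [assignStudyIds()].
#' @return the records with `patient_id` and `encounter_id` restored.
#' @export
reidentify <- function(deidentified, crosswalk) {
  stopifnot(is(crosswalk, "Crosswalk"))
  m <- crosswalk@map
  idx <- match(deidentified$study_id, m$study_id)
  deidentified$patient_id <- m$patient_id[idx]
  deidentified$encounter_id <- m$encounter_id[idx]
  deidentified
}

#' Build the funnel report
#'
#' Aggregates enrollment records into funnel counts with conservation
#' identities enforced (flagged = screened + capped; screened = enrolled +
#' excluded; exclusion reasons sum to excluded) and derived percentages with
#' recorded denominators: percentages of at least 1% print to the nearest
#' integer, smaller ones to one decimal.
#'
#' @param records data.frame covering every flagged encounter, with `status`
#'   in `enrolled` / `excluded` / `eligible_not_screened_cap` and
#'   `exclusion_reason`.
#' @param context optional named numeric vector of context denominators
#'   (e.g. `total_ed_encounters`, `total_lab_specimens`,
#'   `remnant_samples_identified`) used for additional percentages.
#' @return a [FunnelReport-class].
#' @export
#' @examples
#' rec <- data.frame(status = c("enrolled", "excluded", "eligible_not_screened_cap"),
#'                   exclusion_reason = c("none", "specimen_window", "none"))
#' buildFunnelReport(rec)
buildFunnelReport <- function(records, context = numeric()) {
  checkColumns(records, c("status", "exclusion_reason"), "records")
  bad <- setdiff(unique(records$status),
                 c("enrolled", "excluded", "eligible_not_screened_cap"))
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  if (any(context < 0, na.rm = TRUE)) stop("negative context counts are not allowed")
  counts <- c(
    flagged = nrow(records),
    eligible_screened = sum(records$status != "eligible_not_screened_cap"),
    not_screened_cap = sum(records$status == "eligible_not_screened_cap"),
    enrolled = sum(records$status == "enrolled"),
    excluded = sum(records$status == "excluded"),
    excluded_specimen_window = sum(records$exclusion_reason == "specimen_window"),
    excluded_insufficient_volume = sum(records$exclusion_reason == "insufficient_volume"),
    excluded_tube_types_absent = sum(records$exclusion_reason == "tube_types_absent"))
  pct <- function(name, num, den) {
    data.frame(name = name, numerator = num, denominator = den,
               value = percentValue(num, den),
               formatted = formatPercent(num, den), stringsAsFactors = FALSE)
  }
  p <- list(
    pct("eligible_screened_of_flagged", counts[["eligible_screened"]], counts[["flagged"]]),
    pct("enrolled_of_eligible_screened", counts[["enrolled"]], counts[["eligible_screened"]]),
    pct("excluded_of_eligible_screened", counts[["excluded"]], counts[["eligible_screened"]]))
  if ("total_ed_encounters" %in% names(context))
    p <- c(p, list(pct("flagged_of_ed_encounters", counts[["flagged"]],
                       context[["total_ed_encounters"]])))
  if (all(c("remnant_samples_identified", "total_lab_specimens") %in% names(context)))
    p <- c(p, list(pct("remnant_of_lab_specimens",
                       context[["remnant_samples_identified"]],
                       context[["total_lab_specimens"]])))
  percentages <- do.call(rbind, p)
  new("FunnelReport", counts = counts, percentages = percentages,
      context = context)
}

#' Run the full enrollment funnel on a screened cohort
#'
#' Convenience wrapper: daily cap, exclusion cascade, study-id assignment and
#' funnel report in one call.
#'
#' @param screened output of [screenCohort()].
#' @param specimens specimen table of the same cohort.
#' @param capPerDay daily enrollment cap (default 4).
#' @param windowMinutes specimen collection window (default 360).
#' @param context see [buildFunnelReport()].
#' @return list with `records` (per-flag disposition), `crosswalk`,
#'   `deidentified` and `report` (a [FunnelReport-class]).
#' @export
enrollCohort <- function(screened, specimens, capPerDay = 4,
                         windowMinutes = 360, context = numeric()) {
  flags <- screened[screened$flagged, , drop = FALSE]
  capped <- applyDailyCap(flags, capPerDay)
  eligible <- capped[capped$screened, , drop = FALSE]
  scr <- classifyExclusions(
    eligible,
    specimens[specimens$encounter_id %in% eligible$encounter_id, , drop = FALSE],
    windowMinutes)
  notscr <- capped[!capped$screened, , drop = FALSE]
  if (nrow(notscr)) {
    notscr$status <- "eligible_not_screened_cap"
    notscr$exclusion_reason <- "none"
  } else {
    notscr$status <- character()
    notscr$exclusion_reason <- character()
  }
  records <- rbind(scr, notscr)
  ids <- assignStudyIds(records)
  list(records = records, crosswalk = ids$crosswalk,
       deidentified = ids$deidentified,
       report = buildFunnelReport(records, context))
}
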