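## Digital sepsis-3 screening alert: six flag criteria including the modified
## SOFA organ-dysfunction elements, plus a full-SOFA adjudication oracle.
##
## Window semantics are half-open [0, windowMinutes) minutes from ED arrival.
## Each element is evaluated on the worst value observed in the window (min
## for P/F, GCS, MAP, platelets; max for bilirubin, creatinine) and is false
## when no measurement of that kind exists. Thresholds are strict exactly as
## stated: P/F < 400, GCS < 15, MAP < 70 or vasopressors administered,
## bilirubin > 1.2, platelets < 150, creatinine > 1.2.

#' Default vasopressor medication codes recognized by the alert
#' @return character vector of medication codes.
#' @export
vasopressorCodes <- function() {
  c("norepinephrine", "epinephrine", "vasopressin", "phenylephrine",
    "dopamine", "dobutamine", "vasopressor")
}

#' Default antibiotic medication codes recognized by the alert
#' @return character vector of medication codes.
#' @export
antibioticCodes <- function() {
  c("vancomycin", "cefepime", "piperacillin_tazobactam", "ceftriaxone",
    "levofloxacin", "antibiotic")
}

#' The standard SOFA scoring grid
#'
#' Transcription of the conventional six-organ SOFA thresholds as a long
#' table (`organ`, `input`, `op`, `threshold`, `score`): an organ's sub-score
#' is the highest `score` whose condition (`input op threshold`) holds for
#' the worst-in-window value. Cardiovascular sub-scores 3-4 require
#' vasopressor dose rates the simulator does not model, so any vasopressor
#' administration scores 2; respiratory sub-scores 3-4 are likewise applied
#' on the P/F threshold alone, without the ventilatory-support condition.
#'
#' @return data.frame of grid rows shipped in `inst/extdata/sofa_grid.csv`.
#' @export
#' @examples
#' sofaGrid()
sofaGrid <- function() {
  utils::read.csv(system.file("extdata", "sofa_grid.csv", package = "vespre"),
                  stringsAsFactors = FALSE)
}

## ---- internals -------------------------------------------------------------

## coerce/validate the events table; numeric codes must carry numeric values
validateEvents <- function(events) {
  checkColumns(events, c("encounter_id", "t_minutes", "kind", "code", "value"),
               "events")
  if (!is.numeric(events$value)) {
    raw <- events$value
    coerced <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & raw != "" & is.na(coerced) &
      events$kind %in% c("vital", "lab") & events$code != "o2_device"
    if (any(bad))
      stop(sprintf("record-level validation error: non-numeric value for numeric code (first offender: encounter %s, code %s, value '%s')",
                   events$encounter_id[which(bad)[1]], events$code[which(bad)[1]],
                   raw[which(bad)[1]]), call. = FALSE)
    events$value <- coerced
  }
  if (is.integer(events$value)) events$value <- as.numeric(events$value)
  events$t_minutes <- as.numeric(events$t_minutes)
  events
}

firstTime <- function(t) if (length(t)) min(t) else NA_real_

## per-encounter worst values, evidence times and first-qualifying times for
## every quantity the alert and the full-SOFA oracle need
alertWorstTable <- function(events, windowMinutes = 360,
                            vasoCodes = vasopressorCodes(),
                            abxCodes = antibioticCodes()) {
  events <- validateEvents(events)
  dt <- data.table::as.data.table(events)
  win <- dt[t_minutes >= 0 & t_minutes < windowMinutes]
  ids <- unique(dt$encounter_id)
  out <- data.table::data.table(encounter_id = ids, key = "encounter_id")

  num <- win[kind %in% c("vital", "lab") & !is.na(value)]

  emptyAgg <- function() data.table::data.table(
    encounter_id = character(), worst = numeric(), worst_t = numeric(),
    q_t = numeric())
  aggWorst <- function(d, worst = c("min", "max"), qualFun) {
    worst <- match.arg(worst)
    if (!nrow(d)) return(emptyAgg())
    d[, {
      w <- if (worst == "min") which.min(value) else which.max(value)
      .(worst = value[w], worst_t = t_minutes[w],
        q_t = firstTime(t_minutes[qualFun(value)]))
    }, by = encounter_id]
  }
  mergeIn <- function(out, d, prefix) {
    d <- data.table::copy(d)
    data.table::setnames(d, c("worst", "worst_t", "q_t"),
                         paste0(prefix, c("", "_t", "_qt")))
    merge(out, d, by = "encounter_id", all.x = TRUE)
  }

  out <- mergeIn(out, aggWorst(num[code == "platelets"], "min", function(v) v < 150), "plt")
  out <- mergeIn(out, aggWorst(num[code == "gcs"], "min", function(v) v < 15), "gcs")
  out <- mergeIn(out, aggWorst(num[code == "bilirubin"], "max", function(v) v > 1.2), "bili")
  out <- mergeIn(out, aggWorst(num[code == "creatinine"], "max", function(v) v > 1.2), "creat")

  ## MAP: direct map measurements take precedence over (sbp + 2 dbp)/3 pairs
  map_direct <- aggWorst(num[code == "map"], "min", function(v) v < 70)
  pairs <- merge(num[code == "sbp", .(encounter_id, t_minutes, sbp = value)],
                 num[code == "dbp", .(encounter_id, t_minutes, dbp = value)],
                 by = c("encounter_id", "t_minutes"))
  if (nrow(pairs)) {
    pairs[, value := (sbp + 2 * dbp) / 3]
    map_derived <- aggWorst(pairs[, .(encounter_id, t_minutes, value)], "min",
                            function(v) v < 70)
  } else {
    map_derived <- emptyAgg()
  }
  map_derived <- map_derived[!encounter_id %in% map_direct$encounter_id]
  out <- mergeIn(out, rbind(map_direct, map_derived), "map")

  ## P/F: needs a measured PaO2 and an FiO2 in window; FiO2 0.21 imputed only
  ## from an oxygen-device event charted as room air. Worst-case convention:
  ## min PaO2 over max FiO2.
  fio2 <- num[code == "fio2"]
  fio2 <- if (nrow(fio2))
    fio2[, .(fio2 = max(value), fio2_t = firstTime(t_minutes)), by = encounter_id]
  else data.table::data.table(encounter_id = character(), fio2 = numeric(),
                              fio2_t = numeric())
  room <- win[code == "o2_device" & grepl("room air", unit, fixed = TRUE),
              .(room_t = firstTime(t_minutes)), by = encounter_id]
  pao2 <- num[code == "pao2"]
  if (nrow(pao2)) {
    pa <- merge(pao2, fio2, by = "encounter_id", all.x = TRUE)
    pa <- merge(pa, room, by = "encounter_id", all.x = TRUE)
    pa[, fio2_eff := data.table::fifelse(!is.na(fio2), fio2,
                                         data.table::fifelse(!is.na(room_t), 0.21, NA_real_))]
    pa[, info_t := data.table::fifelse(!is.na(fio2), fio2_t, room_t)]
    pa <- pa[!is.na(fio2_eff)]
    if (nrow(pa)) {
      pa[, pf := value / fio2_eff]
      pf_agg <- pa[, {
        w <- which.min(pf)
        .(worst = pf[w], worst_t = t_minutes[w],
          q_t = {
            qt <- t_minutes[pf < 400]
            if (length(qt)) max(min(qt), info_t[1L]) else NA_real_
          })
      }, by = encounter_id]
    } else pf_agg <- emptyAgg()
  } else pf_agg <- emptyAgg()
  out <- mergeIn(out, pf_agg, "pf")

  meds <- win[kind == "med_admin"]
  vaso <- meds[code %in% vasoCodes, .(vaso_t = firstTime(t_minutes)), by = encounter_id]
  abx <- meds[code %in% abxCodes, .(abx_t = firstTime(t_minutes)), by = encounter_id]
  cult <- win[kind == "culture_order", .(cult_t = firstTime(t_minutes)), by = encounter_id]
  labsFirst <- function(cd, nm) {
    d <- num[code == cd, stats::setNames(.(firstTime(t_minutes)), nm), by = encounter_id]
    d
  }
  for (d in list(vaso, abx, cult, labsFirst("hemoglobin", "hgb_t"),
                 labsFirst("lactate", "lact_t"), labsFirst("sodium", "sod_t")))
    out <- merge(out, d, by = "encounter_id", all.x = TRUE)
  out
}

## full-SOFA sub-scores from a worst-value table (vectorized over encounters)
sofaScoresFromWorst <- function(wt, grid = sofaGrid()) {
  inputs <- list(pf = wt$pf, platelets = wt$plt, bilirubin = wt$bili,
                 map = wt$map, gcs = wt$gcs, creatinine = wt$creat,
                 vasopressor = as.numeric(!is.na(wt$vaso_t)))
  n <- nrow(wt)
  organs <- unique(grid$organ)
  scores <- matrix(0, n, length(organs), dimnames = list(NULL, organs))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    v <- inputs[[g$input]]
    hit <- if (g$op == "lt") !is.na(v) & v < g$threshold else !is.na(v) & v >= g$threshold
    scores[, g$organ] <- pmax(scores[, g$organ], ifelse(hit, g$score, 0))
  }
  scores
}

## the six flag criteria, flag indicator and flag time, per encounter
alertCriteriaTable <- function(encounters, events, windowMinutes = 360,
                               enrollingLocation = "ED",
                               vasoCodes = vasopressorCodes(),
                               abxCodes = antibioticCodes(),
                               grid = sofaGrid()) {
  checkColumns(encounters, c("encounter_id", "age_years", "location"), "encounters")
  wt <- alertWorstTable(events, windowMinutes, vasoCodes, abxCodes)
  wt <- merge(data.table::as.data.table(encounters[, c("encounter_id", "age_years",
                                                       "location")]),
              wt, by = "encounter_id", all.x = TRUE)

  trig <- data.table::data.table(
    pf_ratio = !is.na(wt$pf) & wt$pf < 400,
    gcs = !is.na(wt$gcs) & wt$gcs < 15,
    map_or_pressor = (!is.na(wt$map) & wt$map < 70) | !is.na(wt$vaso_t),
    bilirubin = !is.na(wt$bili) & wt$bili > 1.2,
    platelets = !is.na(wt$plt) & wt$plt < 150,
    creatinine = !is.na(wt$creat) & wt$creat > 1.2)

  qt <- cbind(wt$pf_qt, wt$gcs_qt,
              pmin(wt$map_qt, wt$vaso_t, na.rm = TRUE),
              wt$bili_qt, wt$plt_qt, wt$creat_qt)
  qt[!as.matrix(trig)] <- NA_real_
  elem_first <- suppressWarnings(apply(qt, 1, min, na.rm = TRUE))
  elem_first[!is.finite(elem_first)] <- NA_real_

  crit <- data.frame(
    encounter_id = wt$encounter_id,
    ed_location = wt$location == enrollingLocation,
    age_ge_18 = !is.na(wt$age_years) & wt$age_years >= 18,
    cultures_in_window = !is.na(wt$cult_t),
    antibiotics_in_window = !is.na(wt$abx_t),
    sofa_element = rowSums(as.matrix(trig)) > 0,
    required_labs = !is.na(wt$hgb_t) & !is.na(wt$lact_t) & !is.na(wt$sod_t),
    n_elements_triggered = as.integer(rowSums(as.matrix(trig))),
    stringsAsFactors = FALSE)
  crit$flagged <- crit$ed_location & crit$age_ge_18 & crit$cultures_in_window &
    crit$antibiotics_in_window & crit$sofa_element & crit$required_labs
  flag_time <- pmax(wt$cult_t, wt$abx_t, elem_first, wt$hgb_t, wt$lact_t,
                    wt$sod_t, 0)
  crit$flag_time_minutes <- ifelse(crit$flagged, flag_time, NA_real_)
  crit$adjudicated_sofa <- as.integer(rowSums(sofaScoresFromWorst(wt, grid)))
  crit
}

singleEncounterEvents <- function(events) {
  ids <- unique(events$encounter_id)
  if (length(ids) > 1L)
    stop("events must belong to a single encounter; got ", length(ids))
  ids
}

## ---- exported operations ---------------------------------------------------

#' Evaluate the six modified SOFA elements for one encounter
#'
#' Each element is assessed on the worst value observed in
#' `[0, windowMinutes)` and is false when no measurement of that kind exists.
#' MAP is taken from direct `map` events when present, otherwise derived as
#' `(sbp + 2 dbp) / 3` from same-time pairs; the P/F ratio requires a
#' measured PaO2 plus either a measured FiO2 or a room-air oxygen-device
#' event (FiO2 imputed 0.21).
#'
#' @param events event table for one encounter (columns `encounter_id`,
#'   `t_minutes`, `kind`, `code`, `value`, `unit`).
#' @param windowMinutes screening window, half-open, default 360.
#' @param vasoCodes medication codes recognized as vasopressors.
#' @return a [SofaAssessment-class]; see [nElementsTriggered()] and
#'   [sofaElements()].
#' @export
#' @examples
#' ev <- data.frame(encounter_id = "E1", t_minutes = 30, kind = "lab",
#'                  code = "platelets", value = 149, unit = "10^3/uL")
#' nElementsTriggered(evaluateSofaElements(ev))
evaluateSofaElements <- function(events, windowMinutes = 360,
                                 vasoCodes = vasopressorCodes()) {
  stopifnot(windowMinutes > 0)
  id <- singleEncounterEvents(events)
  wt <- alertWorstTable(events, windowMinutes, vasoCodes)
  w <- wt[1L]
  vaso <- !is.na(w$vaso_t)
  elements <- data.frame(
    element = c("pf_ratio", "gcs", "map_or_pressor", "bilirubin", "platelets",
                "creatinine"),
    triggered = c(!is.na(w$pf) & w$pf < 400,
                  !is.na(w$gcs) & w$gcs < 15,
                  (!is.na(w$map) & w$map < 70) | vaso,
                  !is.na(w$bili) & w$bili > 1.2,
                  !is.na(w$plt) & w$plt < 150,
                  !is.na(w$creat) & w$creat > 1.2),
    evidence_value = c(w$pf, w$gcs,
                       if (!is.na(w$map)) w$map else NA_real_,
                       w$bili, w$plt, w$creat),
    evidence_time = c(w$pf_t, w$gcs_t,
                      if (!is.na(w$map) && w$map < 70) w$map_t else w$vaso_t,
                      w$bili_t, w$plt_t, w$creat_t),
    stringsAsFactors = FALSE)
  ## cardiovascular evidence: prefer the hypotensive MAP reading, else the
  ## vasopressor administration time
  new("SofaAssessment", encounterId = as.character(id), elements = elements,
      windowMinutes = windowMinutes)
}

#' Suspected infection: cultures plus antibiotics within the window
#'
#' @inheritParams evaluateSofaElements
#' @param abxCodes medication codes recognized as antibiotics.
#' @return `TRUE` iff at least one blood-culture order and at least one
#'   antibiotic administration both occur in `[0, windowMinutes)`. An empty
#'   stream is `FALSE`.
#' @export
detectSuspectedInfection <- function(events, windowMinutes = 360,
                                     abxCodes = antibioticCodes()) {
  if (!nrow(events)) return(FALSE)
  singleEncounterEvents(events)
  events <- validateEvents(events)
  win <- events[events$t_minutes >= 0 & events$t_minutes < windowMinutes, ]
  any(win$kind == "culture_order") &&
    any(win$kind == "med_admin" & win$code %in% abxCodes)
}

#' Required laboratory tubes: hemoglobin, lactate and sodium obtained
#'
#' The alert requires all three analytes to have at least one result inside
#' the window; the rule exists to guarantee the proper tube types were drawn.
#'
#' @inheritParams evaluateSofaElements
#' @return `TRUE` iff hemoglobin, lactate and sodium each have a result in
#'   window.
#' @export
checkRequiredLabs <- function(events, windowMinutes = 360) {
  if (!nrow(events)) return(FALSE)
  singleEncounterEvents(events)
  events <- validateEvents(events)
  win <- events[events$t_minutes >= 0 & events$t_minutes < windowMinutes &
                  !is.na(events$value), ]
  all(c("hemoglobin", "lactate", "sodium") %in% win$code)
}

#' Evaluate the digital alert for one encounter
#'
#' The flag is emitted iff all six criteria hold: (1) location in the
#' enrolling ED, (2) age 18 or older, (3) blood cultures in window, (4)
#' antibiotics in window, (5) at least one modified SOFA element, (6)
#' hemoglobin, lactate and sodium obtained. Criteria accumulate over the
#' window; the flag time is the earliest minute at which all are satisfied.
#'
#' @param encounter one-row data.frame with at least `encounter_id`,
#'   `age_years`, `location`.
#' @param events event table for the same encounter.
#' @param windowMinutes screening window (default 360).
#' @param enrollingLocation location value that satisfies criterion 1.
#' @return a one-row data.frame (`encounter_id`, `flag_time_minutes`, the six
#'   criterion booleans, `n_elements_triggered`, `adjudicated_sofa`) or
#'   `NULL` when no flag is raised.
#' @export
generateAlert <- function(encounter, events, windowMinutes = 360,
                          enrollingLocation = "ED") {
  checkColumns(encounter, c("encounter_id", "age_years", "location"), "encounter")
  if (nrow(encounter) != 1L) stop("encounter must be a single row")
  if (is.na(encounter$age_years)) stop("validation error: missing age")
  crit <- alertCriteriaTable(encounter, events, windowMinutes,
                             enrollingLocation = enrollingLocation)
  if (!isTRUE(crit$flagged[1L])) return(NULL)
  crit[1L, c("encounter_id", "flag_time_minutes", "ed_location", "age_ge_18",
             "cultures_in_window", "antibiotics_in_window", "sofa_element",
             "required_labs", "n_elements_triggered", "adjudicated_sofa")]
}

#' Full-SOFA adjudication oracle for one encounter
#'
#' Sums the six organ sub-scores (0-4 each) of the standard SOFA grid,
#' computed on worst-in-window values; organs with no data score 0. This is
#' the manual-adjudication stand-in used to check that flagged encounters
#' carry SOFA >= 2 under the sepsis-3 definition.
#'
#' @inheritParams evaluateSofaElements
#' @param grid scoring grid, see [sofaGrid()].
#' @return integer total score in 0-24.
#' @export
#' @examples
#' ev <- data.frame(encounter_id = "E1", t_minutes = 10, kind = "lab",
#'                  code = "platelets", value = 90, unit = "10^3/uL")
#' adjudicateFullSofa(ev)  # platelets < 100 scores 2
adjudicateFullSofa <- function(events, windowMinutes = 360, grid = sofaGrid()) {
  if (!nrow(events)) return(0L)
  singleEncounterEvents(events)
  wt <- alertWorstTable(events, windowMinutes)
  as.integer(rowSums(sofaScoresFromWorst(wt[1L], grid)))
}

#' Screen a whole cohort with the digital alert
#'
#' Vectorized evaluation of [generateAlert()] over every encounter of a
#' cohort, with the full-SOFA adjudication attached.
#'
#' @param cohort an [EHRCohort-class] (or pass `encounters` and `events`
#'   tables via `...` as `screenCohort(encounters = , events = )`).
#' @param windowMinutes screening window (default 360).
#' @param enrollingLocation location satisfying criterion 1.
#' @param encounters,events alternative tabular inputs when no cohort object
#'   is at hand.
#' @return data.frame with one row per encounter: the six criterion booleans,
#'   `flagged`, `flag_time_minutes` (NA unless flagged),
#'   `n_elements_triggered`, `adjudicated_sofa`, plus `arrival_datetime` for
#'   downstream calendar-day logic. Use `subset(x, flagged)` as the flags
#'   table of the enrollment funnel.
#' @export
screenCohort <- function(cohort = NULL, windowMinutes = 360,
                         enrollingLocation = "ED", encounters = NULL,
                         events = NULL) {
  if (!is.null(cohort)) {
    stopifnot(is(cohort, "EHRCohort"))
    encounters <- cohort@encounters
    events <- cohort@events
  }
  crit <- alertCriteriaTable(encounters, events, windowMinutes,
                             enrollingLocation = enrollingLocation)
  out <- merge(crit, encounters[, c("encounter_id", "patient_id", "arrival_datetime")],
               by = "encounter_id")
  out[order(out$encounter_id), ]
}
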