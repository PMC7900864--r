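## Synthetic emergency-department EHR generator: encounters, timestamped event
## streams, laboratory specimens and biomarker panels with known ground truth.

#' Default clinical variable marginals
#'
#' One row per clinical event code emitted by the generator. Septic encounters
#' draw from marginals matching the enrolled-cohort characteristics (mean/SD
#' for approximately normal variables, median/IQR-derived log-normals for
#' skewed ones); non-septic encounters draw from reference-range marginals.
#' The `miss` column holds the default missing-completely-at-random rate per
#' variable; together with age and comorbidity count (never missing) the
#' defaults leave 23 of 29 variables below 25% missingness.
#'
#' @return data.frame with columns `code`, `kind`, `dist`, `s_m`, `s_s`,
#'   `h_m`, `h_s`, `lo`, `hi`, `unit`, `miss`. For `dist = "normal"` the
#'   `*_m`/`*_s` pairs are mean/SD (truncated to `[lo, hi]`); for
#'   `"lognormal"` they are median and sdlog.
#' @export
#' @examples
#' head(clinicalMarginals())
clinicalMarginals <- function() {
  L <- function(q1, q3) sdlogFromIqr(q1, q3)
  df <- rbind(
    data.frame(code = "bands",       kind = "lab",   dist = "lognormal", s_m = 10,    s_s = L(4, 21),     h_m = 2,    h_s = 0.8,  lo = 0,   hi = 100, unit = "%",        miss = 0.45),
    data.frame(code = "crp",         kind = "lab",   dist = "normal",    s_m = 12.5,  s_s = 12.1,         h_m = 3,    h_s = 3,    lo = 0.1, hi = Inf, unit = "mg/L",     miss = 0.55),
    data.frame(code = "esr",         kind = "lab",   dist = "normal",    s_m = 46.0,  s_s = 52.3,         h_m = 15,   h_s = 10,   lo = 1,   hi = Inf, unit = "mm/h",     miss = 0.60),
    data.frame(code = "wbc",         kind = "lab",   dist = "normal",    s_m = 13.4,  s_s = 8.8,          h_m = 8,    h_s = 2.5,  lo = 0.5, hi = Inf, unit = "10^9/L",   miss = 0.08),
    data.frame(code = "rr",          kind = "vital", dist = "normal",    s_m = 23.6,  s_s = 6.5,          h_m = 16,   h_s = 3,    lo = 6,   hi = 60,  unit = "breaths/min", miss = 0.03),
    data.frame(code = "spo2",        kind = "vital", dist = "normal",    s_m = 92.9,  s_s = 5.3,          h_m = 97,   h_s = 2,    lo = 50,  hi = 100, unit = "%",        miss = 0.03),
    data.frame(code = "temp",        kind = "vital", dist = "normal",    s_m = 38.1,  s_s = 1.1,          h_m = 36.8, h_s = 0.4,  lo = 32,  hi = 43,  unit = "degC",     miss = 0.03),
    data.frame(code = "pao2",        kind = "lab",   dist = "normal",    s_m = 134.3, s_s = 74.1,         h_m = 90,   h_s = 12,   lo = 30,  hi = 600, unit = "mmHg",     miss = 0.65),
    data.frame(code = "hr",          kind = "vital", dist = "normal",    s_m = 104.8, s_s = 22.5,         h_m = 80,   h_s = 12,   lo = 20,  hi = 230, unit = "bpm",      miss = 0.02),
    data.frame(code = "sbp",         kind = "vital", dist = "normal",    s_m = 104.9, s_s = 24.3,         h_m = 125,  h_s = 15,   lo = 50,  hi = 260, unit = "mmHg",     miss = 0.02),
    data.frame(code = "dbp",         kind = "vital", dist = "normal",    s_m = 60,    s_s = 15,           h_m = 75,   h_s = 10,   lo = 25,  hi = 160, unit = "mmHg",     miss = 0.02),
    data.frame(code = "troponin",    kind = "lab",   dist = "lognormal", s_m = 0.1,   s_s = L(0.1, 0.2),  h_m = 0.02, h_s = 0.5,  lo = 0,   hi = Inf, unit = "ng/mL",    miss = 0.50),
    data.frame(code = "lactate",     kind = "lab",   dist = "lognormal", s_m = 1.4,   s_s = L(1.0, 2.2),  h_m = 1.0,  h_s = 0.3,  lo = 0,   hi = Inf, unit = "mmol/L",   miss = 0.12),
    data.frame(code = "bicarbonate", kind = "lab",   dist = "normal",    s_m = 22.9,  s_s = 4.7,          h_m = 24.5, h_s = 2.5,  lo = 5,   hi = 50,  unit = "mEq/L",    miss = 0.05),
    data.frame(code = "creatinine",  kind = "lab",   dist = "lognormal", s_m = 1.4,   s_s = L(1.0, 2.3),  h_m = 0.9,  h_s = 0.2,  lo = 0,   hi = Inf, unit = "mg/dL",    miss = 0.05),
    data.frame(code = "bun",         kind = "lab",   dist = "lognormal", s_m = 25,    s_s = L(16, 41),    h_m = 14,   h_s = 0.3,  lo = 0,   hi = Inf, unit = "mg/dL",    miss = 0.05),
    data.frame(code = "albumin",     kind = "lab",   dist = "normal",    s_m = 3.3,   s_s = 0.7,          h_m = 4.2,  h_s = 0.4,  lo = 1,   hi = 6,   unit = "g/dL",     miss = 0.30),
    data.frame(code = "alt",         kind = "lab",   dist = "lognormal", s_m = 21,    s_s = L(12, 42),    h_m = 20,   h_s = 0.5,  lo = 0,   hi = Inf, unit = "U/L",      miss = 0.15),
    data.frame(code = "ast",         kind = "lab",   dist = "lognormal", s_m = 29,    s_s = L(17, 52),    h_m = 24,   h_s = 0.4,  lo = 0,   hi = Inf, unit = "U/L",      miss = 0.15),
    data.frame(code = "bilirubin",   kind = "lab",   dist = "lognormal", s_m = 0.8,   s_s = L(0.5, 1.5),  h_m = 0.5,  h_s = 0.4,  lo = 0,   hi = Inf, unit = "mg/dL",    miss = 0.12),
    data.frame(code = "hemoglobin",  kind = "lab",   dist = "normal",    s_m = 10.9,  s_s = 2.3,          h_m = 14,   h_s = 1.5,  lo = 3,   hi = 22,  unit = "g/dL",     miss = 0.04),
    data.frame(code = "inr",         kind = "lab",   dist = "normal",    s_m = 1.5,   s_s = 0.9,          h_m = 1.0,  h_s = 0.08, lo = 0.8, hi = 12,  unit = "",         miss = 0.35),
    data.frame(code = "platelets",   kind = "lab",   dist = "lognormal", s_m = 208,   s_s = L(144, 278),  h_m = 250,  h_s = 0.25, lo = 0,   hi = Inf, unit = "10^3/uL",  miss = 0.04),
    data.frame(code = "chloride",    kind = "lab",   dist = "normal",    s_m = 101.6, s_s = 5.7,          h_m = 102,  h_s = 3,    lo = 70,  hi = 130, unit = "mEq/L",    miss = 0.04),
    data.frame(code = "glucose",     kind = "lab",   dist = "lognormal", s_m = 129,   s_s = L(104, 171),  h_m = 100,  h_s = 0.15, lo = 0,   hi = Inf, unit = "mg/dL",    miss = 0.04),
    data.frame(code = "sodium",      kind = "lab",   dist = "normal",    s_m = 135.3, s_s = 7.3,          h_m = 139,  h_s = 3,    lo = 100, hi = 175, unit = "mEq/L",    miss = 0.04),
    data.frame(code = "gcs",         kind = "vital", dist = "normal",    s_m = 11.8,  s_s = 4.3,          h_m = 15,   h_s = 0.5,  lo = 3,   hi = 15,  unit = "",         miss = 0.10)
  )
  rownames(df) <- NULL
  df
}

#' The seventeen biomarkers measured on remnant specimens
#'
#' @return character vector of canonical marker column names.
#' @export
sepsisMarkers <- function() {
  c("PAI_1", "AT_III", "IL_6", "IL_8", "IL_10", "E_selectin", "Ang_1",
    "Ang_2", "ICAM", "HO_1", "TIMP_2", "IGFBP7", "lactate", "bicarbonate",
    "uric_acid", "CRP", "PCT")
}

#' Default log-normal biomarker marginals
#'
#' Medians and log-scale dispersions for the seventeen remnant-plasma markers,
#' grouped (for display) into tissue damage, resistance/innate immunity and
#' tolerance panels. Cytokines get wide dispersions (sdlog around 1) so that
#' log2 fold changes of +/-4 against the cohort median are plausible.
#'
#' @return data.frame with columns `marker`, `median`, `sdlog`, `miss`,
#'   `unit`, `group`.
#' @export
biomarkerParams <- function() {
  df <- data.frame(
    marker = sepsisMarkers(),
    median = c(40, 80, 50, 30, 10, 60, 10, 5, 300, 20, 80, 100, 1.4, 23, 5, 12, 0.5),
    sdlog  = c(0.9, 0.3, 1.2, 1.1, 1.0, 0.6, 0.7, 0.9, 0.5, 0.8, 0.6, 0.8,
               0.55, 0.2, 0.35, 1.0, 1.3),
    miss   = 0.08,
    unit   = c("ng/mL", "%", "pg/mL", "pg/mL", "pg/mL", "ng/mL", "ng/mL",
               "ng/mL", "ng/mL", "ng/mL", "ng/mL", "ng/mL", "mmol/L",
               "mEq/L", "mg/dL", "mg/L", "ng/mL"),
    group  = c("damage", "damage", "resistance", "resistance", "resistance",
               "resistance", "tolerance", "tolerance", "resistance", "damage",
               "tolerance", "tolerance", "damage", "damage", "damage",
               "resistance", "resistance")
  )
  rownames(df) <- NULL
  df
}

#' Default remnant-volume distributions per tube type
#'
#' Truncated-normal location/scale (in microliters) per tube type. Defaults
#' put roughly a quarter of individual blood specimens below their tube-type
#' volume minimum, which makes about a quarter of otherwise-eligible
#' patients fail the volume rule on at least one required tube.
#'
#' @return data.frame with columns `tube_type`, `mean`, `sd`, `lambda`
#'   (expected specimens of that tube type per encounter; counts are
#'   Poisson).
#' @export
tubeVolumeParams <- function() {
  data.frame(
    tube_type = c("heparin", "edta", "sodium_fluoride", "citrate", "urine"),
    mean = c(650, 550, 300, 550, 1500),
    sd = c(150, 150, 110, 150, 700),
    lambda = c(1.7, 1.5, 1.8, 2.0, 1.0)
  )
}

#' Default event-process rates for the generator
#' @return named list of rates used by [generateCohort()].
#' @export
defaultEventRates <- function() {
  list(
    cultureProbNonSepsis = 0.15,
    antibioticProbNonSepsis = 0.25,
    vasopressorProbSepsis = 0.14,
    vasopressorProbNonSepsis = 0.01,
    supplementalO2ProbSepsis = 0.50,
    supplementalO2ProbNonSepsis = 0.15,
    lateWindowMinutes = 480,     # non-guaranteed cultures/antibiotics land in [0, this)
    specimenWindowMax = 390,     # specimen draw times land in [0, this)
    antibioticCodes = c("vancomycin", "cefepime", "piperacillin_tazobactam",
                        "ceftriaxone", "levofloxacin"),
    vasopressorCodes = c("norepinephrine", "epinephrine", "vasopressin",
                         "phenylephrine", "dopamine", "dobutamine")
  )
}

#' Construct a generator configuration
#'
#' All downstream stages are driven by seeded synthetic cohorts produced from
#' this configuration. With a fixed seed the generator is a pure function of
#' the configuration: calling it twice yields identical output.
#'
#' @param nEncounters number of emergency-department encounters to simulate.
#' @param sepsisPrevalence fraction of adult encounters carrying true sepsis.
#' @param ageMean,ageSd adult age distribution (years), truncated to
#'   `[18, 105]`.
#' @param maleFraction fraction of encounters recorded male.
#' @param raceProbs named probabilities for the race field (normalized).
#' @param comorbidityMean,comorbiditySd Elixhauser comorbidity count
#'   distribution (truncated at 0, rounded).
#' @param minorFraction fraction of encounters that are under-18 negative
#'   controls (never true sepsis).
#' @param edFraction fraction of encounters located in the enrolling ED.
#' @param missingness named per-variable missing-completely-at-random rates;
#'   defaults to the `miss` column of `marginals`. Unknown names are an
#'   error.
#' @param marginals clinical variable marginals, see [clinicalMarginals()].
#' @param markerParams biomarker marginals, see [biomarkerParams()].
#' @param tubeParams tube-type remnant-volume parameters, see
#'   [tubeVolumeParams()].
#' @param eventRates event-process rates, see [defaultEventRates()].
#' @param arrivalsPerDay mean ED arrivals per calendar day (spreads
#'   encounters over study days so the daily cap is exercisable).
#' @param studyStart simulated study start datetime (UTC).
#' @param seed RNG seed; fixed seed implies byte-identical output.
#' @return a validated [GeneratorConfig-class] object.
#' @export
#' @examples
#' cfg <- generatorConfig(nEncounters = 100, seed = 7)
#' cfg
generatorConfig <- function(nEncounters = 1000L,
                            sepsisPrevalence = 0.08,
                            ageMean = 59, ageSd = 17,
                            maleFraction = 0.56,
                            raceProbs = c(White = 0.825, Black = 0.156, Other = 0.019),
                            comorbidityMean = 4.0, comorbiditySd = 2.3,
                            minorFraction = 0.02,
                            edFraction = 0.97,
                            missingness = NULL,
                            marginals = clinicalMarginals(),
                            markerParams = biomarkerParams(),
                            tubeParams = tubeVolumeParams(),
                            eventRates = defaultEventRates(),
                            arrivalsPerDay = 70,
                            studyStart = as.POSIXct("2017-10-17 00:00:00", tz = "UTC"),
                            seed = 1L) {
  if (length(nEncounters) != 1L || is.na(nEncounters) || nEncounters < 0)
    stop("configuration error in field 'nEncounters': must be a single count >= 0")
  defaults <- stats::setNames(marginals$miss, marginals$code)
  if (is.null(missingness)) {
    missingness <- defaults
  } else {
    unknown <- setdiff(names(missingness), marginals$code)
    if (length(unknown))
      stop(sprintf("configuration error in field 'missingness': unknown variable(s) %s",
                   paste(unknown, collapse = ", ")))
    defaults[names(missingness)] <- missingness
    missingness <- defaults
  }
  rp <- raceProbs / sum(raceProbs)
  for (fld in c("sepsisPrevalence", "maleFraction", "minorFraction", "edFraction")) {
    v <- get(fld)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("configuration error in field '%s': fraction must lie in [0,1]", fld))
  }
  new("GeneratorConfig",
      nEncounters = as.integer(nEncounters),
      sepsisPrevalence = sepsisPrevalence,
      ageMean = ageMean, ageSd = ageSd,
      maleFraction = maleFraction, raceProbs = rp,
      comorbidityMean = comorbidityMean, comorbiditySd = comorbiditySd,
      minorFraction = minorFraction, edFraction = edFraction,
      missingness = missingness, marginals = marginals,
      markerParams = markerParams, tubeParams = tubeParams,
      eventRates = eventRates, arrivalsPerDay = arrivalsPerDay,
      studyStart = studyStart, seed = as.numeric(seed))
}

## draw one clinical variable for a mix of septic / non-septic encounters
drawMarginal <- function(row, septic) {
  n <- length(septic)
  val <- numeric(n)
  if (row$dist == "normal") {
    val[septic] <- rtruncnorm(sum(septic), row$s_m, row$s_s, row$lo, row$hi)
    val[!septic] <- rtruncnorm(sum(!septic), row$h_m, row$h_s, row$lo, row$hi)
  } else {
    val[septic] <- rlnormMedian(sum(septic), row$s_m, row$s_s)
    val[!septic] <- rlnormMedian(sum(!septic), row$h_m, row$h_s)
    val <- pmin(pmax(val, max(row$lo, 1e-6)), row$hi)
  }
  if (row$code == "gcs") val <- round(val)
  val
}

#' Generate a synthetic ED cohort
#'
#' Produces encounters, a timestamped clinical event stream, laboratory
#' specimens and per-encounter truth labels. Every true-sepsis encounter is
#' guaranteed at least one blood-culture order, one antibiotic administration
#' and one qualifying organ-dysfunction value within the 6-hour screening
#' window; criterion-level truth is derived by evaluating the digital-alert
#' logic on the emitted events, so labels are consistent with the stream by
#' construction.
#'
#' @param config a [GeneratorConfig-class] from [generatorConfig()].
#' @return an [EHRCohort-class] with slots `encounters`, `events`,
#'   `specimens` and `truth` (columns `encounter_id`, `true_sepsis`, the six
#'   per-criterion booleans prefixed `crit_`).
#' @seealso [screenCohort()] to run the digital alert on the result.
#' @export
#' @examples
#' coh <- generateCohort(generatorConfig(nEncounters = 50, seed = 42))
#' coh
generateCohort <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  withSeed(config@seed, {
    n <- config@nEncounters
    enc_id <- sprintf("E%06d", seq_len(n))
    if (n == 0L) {
      empty_events <- data.frame(encounter_id = character(), t_minutes = numeric(),
                                 kind = character(), code = character(),
                                 value = numeric(), unit = character())
      return(new("EHRCohort",
                 encounters = data.frame(encounter_id = character(),
                                         patient_id = character(),
                                         age_years = numeric(), sex = character(),
                                         race = character(),
                                         arrival_datetime = as.POSIXct(character(), tz = "UTC"),
                                         location = character()),
                 events = empty_events,
                 specimens = data.frame(encounter_id = character(), t_minutes = numeric(),
                                        tube_type = character(),
                                        remnant_volume_ul = numeric(),
                                        clinical_testing_complete_minutes = numeric()),
                 truth = data.frame(encounter_id = character(), true_sepsis = logical()),
                 config = config))
    }

    minor <- stats::runif(n) < config@minorFraction
    age <- numeric(n)
    age[!minor] <- rtruncnorm(sum(!minor), config@ageMean, config@ageSd, 18, 105)
    age[minor] <- stats::runif(sum(minor), 1, 17.99)
    age <- round(age, 1)
    sex <- ifelse(stats::runif(n) < config@maleFraction, "male", "female")
    race <- sample(names(config@raceProbs), n, replace = TRUE, prob = config@raceProbs)
    location <- ifelse(stats::runif(n) < config@edFraction, "ED", "ward")
    comorbid <- pmax(0, round(stats::rnorm(n, config@comorbidityMean, config@comorbiditySd)))

    study_days <- max(1L, ceiling(n / config@arrivalsPerDay))
    day <- sample.int(study_days, n, replace = TRUE) - 1L
    secs <- floor(stats::runif(n, 0, 86400))
    arrival <- config@studyStart + day * 86400 + secs

    septic <- !minor & (stats::runif(n) < config@sepsisPrevalence)

    rates <- config@eventRates
    miss <- config@missingness
    marg <- config@marginals
    ev <- vector("list", 0L)
    addEv <- function(id, t, kind, code, value, unit) {
      if (!length(id)) return(invisible(NULL))
      ev[[length(ev) + 1L]] <<- data.table::data.table(
        encounter_id = id, t_minutes = as.numeric(t), kind = kind,
        code = code, value = as.numeric(value), unit = unit)
      invisible(NULL)
    }
    rwin <- function(k, upper = 360) floor(stats::runif(k, 0, upper))

    ## blood pressure drawn jointly so systolic/diastolic share timestamps
    bp_present <- stats::runif(n) < (1 - miss[["sbp"]])
    bi <- which(bp_present)
    bt <- rwin(length(bi))
    sbp_row <- marg[marg$code == "sbp", ]
    dbp_row <- marg[marg$code == "dbp", ]
    addEv(enc_id[bi], bt, "vital", "sbp", drawMarginal(sbp_row, septic[bi]), sbp_row$unit)
    addEv(enc_id[bi], bt, "vital", "dbp", drawMarginal(dbp_row, septic[bi]), dbp_row$unit)

    pao2_idx <- integer(0)
    pao2_t <- numeric(0)
    for (i in seq_len(nrow(marg))) {
      row <- marg[i, ]
      if (row$code %in% c("sbp", "dbp")) next
      present <- stats::runif(n) < (1 - miss[[row$code]])
      idx <- which(present)
      if (!length(idx)) next
      tt <- rwin(length(idx))
      addEv(enc_id[idx], tt, row$kind, row$code, drawMarginal(row, septic[idx]), row$unit)
      if (row$code == "pao2") { pao2_idx <- idx; pao2_t <- tt }
    }

    ## oxygen context for encounters with an arterial gas: either a measured
    ## FiO2 (supplemental oxygen) or a room-air device event (FiO2 imputable)
    if (length(pao2_idx)) {
      p_suppl <- ifelse(septic[pao2_idx], rates$supplementalO2ProbSepsis,
                        rates$supplementalO2ProbNonSepsis)
      suppl <- stats::runif(length(pao2_idx)) < p_suppl
      if (any(suppl))
        addEv(enc_id[pao2_idx[suppl]], pao2_t[suppl], "vital", "fio2",
              sample(c(0.28, 0.32, 0.4, 0.5, 0.6, 0.8, 1.0), sum(suppl), replace = TRUE),
              "fraction")
      if (any(!suppl))
        addEv(enc_id[pao2_idx[!suppl]], pao2_t[!suppl], "vital", "o2_device",
              NA_real_, "room air")
    }

    ## suspected-infection events
    sep_i <- which(septic)
    addEv(enc_id[sep_i], rwin(length(sep_i)), "culture_order", "blood_culture",
          NA_real_, "")
    addEv(enc_id[sep_i], rwin(length(sep_i)), "med_admin",
          sample(rates$antibioticCodes, length(sep_i), replace = TRUE), NA_real_, "dose")
    ns_i <- which(!septic)
    cult <- ns_i[stats::runif(length(ns_i)) < rates$cultureProbNonSepsis]
    addEv(enc_id[cult], rwin(length(cult), rates$lateWindowMinutes),
          "culture_order", "blood_culture", NA_real_, "")
    abx <- ns_i[stats::runif(length(ns_i)) < rates$antibioticProbNonSepsis]
    addEv(enc_id[abx], rwin(length(abx), rates$lateWindowMinutes), "med_admin",
          sample(rates$antibioticCodes, length(abx), replace = TRUE), NA_real_, "dose")

    ## vasopressors
    p_vaso <- ifelse(septic, rates$vasopressorProbSepsis, rates$vasopressorProbNonSepsis)
    vaso <- which(stats::runif(n) < p_vaso & !minor)
    addEv(enc_id[vaso], rwin(length(vaso)), "med_admin",
          sample(rates$vasopressorCodes, length(vaso), replace = TRUE), NA_real_, "dose")

    ## guarantee one qualifying modified-SOFA element per true-sepsis encounter
    if (length(sep_i)) {
      elem <- sample(c("platelets", "creatinine", "bilirubin", "gcs", "map", "pf"),
                     length(sep_i), replace = TRUE,
                     prob = c(0.30, 0.25, 0.10, 0.15, 0.15, 0.05))
      et <- rwin(length(sep_i))
      g <- function(which) sep_i[elem == which]
      gt <- function(which) et[elem == which]
      addEv(enc_id[g("platelets")], gt("platelets"), "lab", "platelets",
            stats::runif(length(g("platelets")), 40, 149), "10^3/uL")
      addEv(enc_id[g("creatinine")], gt("creatinine"), "lab", "creatinine",
            stats::runif(length(g("creatinine")), 1.3, 4.5), "mg/dL")
      addEv(enc_id[g("bilirubin")], gt("bilirubin"), "lab", "bilirubin",
            stats::runif(length(g("bilirubin")), 1.3, 6), "mg/dL")
      addEv(enc_id[g("gcs")], gt("gcs"), "vital", "gcs",
            sample(6:14, length(g("gcs")), replace = TRUE), "")
      mi <- g("map"); mt <- gt("map")
      addEv(enc_id[mi], mt, "vital", "sbp", stats::runif(length(mi), 68, 88), "mmHg")
      addEv(enc_id[mi], mt, "vital", "dbp", stats::runif(length(mi), 38, 52), "mmHg")
      pi <- g("pf"); pt <- gt("pf")
      addEv(enc_id[pi], pt, "lab", "pao2", stats::runif(length(pi), 55, 80), "mmHg")
      addEv(enc_id[pi], pt, "vital", "fio2",
            sample(c(0.32, 0.4, 0.5), length(pi), replace = TRUE), "fraction")
    }

    ## specimens: Poisson counts per tube type per encounter
    tp <- config@tubeParams
    sp <- vector("list", nrow(tp))
    for (i in seq_len(nrow(tp))) {
      cnt <- stats::rpois(n, tp$lambda[i])
      owner <- rep.int(seq_len(n), cnt)
      if (!length(owner)) next
      st <- floor(stats::runif(length(owner), 0, rates$specimenWindowMax))
      vol <- round(rtruncnorm(length(owner), tp$mean[i], tp$sd[i], 10, Inf), 1)
      sp[[i]] <- data.table::data.table(
        encounter_id = enc_id[owner], t_minutes = as.numeric(st),
        tube_type = tp$tube_type[i], remnant_volume_ul = vol,
        clinical_testing_complete_minutes = st + floor(stats::runif(length(owner), 60, 360)))
    }
    specimens <- as.data.frame(data.table::rbindlist(sp))
    specimens <- specimens[order(specimens$encounter_id, specimens$tube_type,
                                 specimens$t_minutes), ]
    rownames(specimens) <- NULL
    if (nrow(specimens))
      addEv(specimens$encounter_id, specimens$t_minutes, "specimen_collect",
            specimens$tube_type, specimens$remnant_volume_ul, "uL")

    events <- as.data.frame(data.table::rbindlist(ev))
    events <- events[order(events$encounter_id, events$t_minutes, events$code), ]
    rownames(events) <- NULL

    encounters <- data.frame(
      encounter_id = enc_id,
      patient_id = sprintf("P%06d", seq_len(n)),
      age_years = age, sex = sex, race = race,
      arrival_datetime = arrival, location = location,
      comorbidity_count = comorbid,
      stringsAsFactors = FALSE)

    ## truth: latent disease label plus criterion-level booleans obtained by
    ## running the digital-alert logic on the emitted stream
    crit <- alertCriteriaTable(encounters, events, windowMinutes = 360)
    crit <- crit[match(enc_id, crit$encounter_id), ]
    truth <- data.frame(
      encounter_id = enc_id,
      true_sepsis = septic,
      crit_ed_location = crit$ed_location,
      crit_age_ge_18 = crit$age_ge_18,
      crit_cultures_in_window = crit$cultures_in_window,
      crit_antibiotics_in_window = crit$antibiotics_in_window,
      crit_sofa_element = crit$sofa_element,
      crit_required_labs = crit$required_labs,
      stringsAsFactors = FALSE)

    new("EHRCohort", encounters = encounters, events = events,
        specimens = specimens, truth = truth, config = config)
  })
}

#' Generate a biomarker panel for enrolled patients
#'
#' Draws strictly positive marker concentrations from the configured
#' log-normal marginals, one column per enrolled patient, one row per marker
#' (SummarizedExperiment orientation: features x samples). Cells are set
#' missing completely at random at each marker's configured rate, emulating
#' markers not measured on a given remnant sample.
#'
#' @param config a [GeneratorConfig-class]; `markerParams(config)` rows must
#'   use the canonical marker names of [sepsisMarkers()].
#' @param enrolledIds non-empty character vector of patient/study identifiers.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"concentration"` (markers x patients), marker parameters in `rowData`
#'   and identifiers in `colData`.
#' @export
#' @examples
#' cfg <- generatorConfig(nEncounters = 10, seed = 3)
#' panel <- generateBiomarkerPanel(cfg, sprintf("VESPRE-%04d", 1:8))
#' dim(panel)
generateBiomarkerPanel <- function(config, enrolledIds) {
  stopifnot(is(config, "GeneratorConfig"))
  if (!length(enrolledIds)) stop("enrolledIds must be non-empty")
  mp <- config@markerParams
  unknown <- setdiff(mp$marker, sepsisMarkers())
  if (length(unknown))
    stop(sprintf("unknown marker name(s) in config: %s", paste(unknown, collapse = ", ")))
  withSeed(config@seed + 1, {
    np <- length(enrolledIds)
    mat <- matrix(NA_real_, nrow = nrow(mp), ncol = np,
                  dimnames = list(mp$marker, enrolledIds))
    for (i in seq_len(nrow(mp))) {
      v <- rlnormMedian(np, mp$median[i], mp$sdlog[i])
      v[stats::runif(np) < mp$miss[i]] <- NA_real_
      mat[i, ] <- v
    }
    SummarizedExperiment::SummarizedExperiment(
      assays = list(concentration = mat),
      rowData = S4Vectors::DataFrame(mp, row.names = mp$marker),
      colData = S4Vectors::DataFrame(study_id = enrolledIds, row.names = enrolledIds))
  })
}

#' Patients-by-markers table from a biomarker panel
#'
#' @param panel the SummarizedExperiment from [generateBiomarkerPanel()].
#' @return data.frame, one row per patient, one column per marker.
#' @export
panelTable <- function(panel) {
  stopifnot(is(panel, "SummarizedExperiment"))
  as.data.frame(t(SummarizedExperiment::assay(panel, "concentration")))
}

#' Synthetic cohort with a known orthogonal block-factor structure
#'
#' Generates `n` observations of `p` standardized variables loading on `k`
#' orthogonal latent factors over disjoint, near-equal variable blocks:
#' `x_j = loading * F_b(j) + sqrt(1 - loading^2) * e_j`, so each variable has
#' unit variance and unique variance `1 - loading^2`. Used to exercise the
#' eigenvalue factor screen with a known answer.
#'
#' @param n observations (default 549).
#' @param k number of latent factors.
#' @param p number of observed variables (default 23).
#' @param loading primary loading of each variable on its block factor.
#' @param seed RNG seed.
#' @return data.frame of `n` rows and `p` columns `V1..Vp`.
#' @export
#' @examples
#' x <- generateFactorCohort(n = 200, k = 3, p = 12, seed = 1)
#' nRetained(kaiserFactorScreen(x))
generateFactorCohort <- function(n = 549, k = 5, p = 23, loading = 0.7, seed = 1L) {
  stopifnot(k >= 1, p >= k, loading > 0, loading < 1)
  withSeed(seed, {
    block <- sort(rep_len(seq_len(k), p))
    f <- matrix(stats::rnorm(n * k), n, k)
    e <- matrix(stats::rnorm(n * p), n, p)
    x <- loading * f[, block, drop = FALSE] + sqrt(1 - loading^2) * e
    colnames(x) <- paste0("V", seq_len(p))
    as.data.frame(x)
  })
}

#' Worst-in-window clinical table for analytics
#'
#' Pivots the event stream into one row per encounter with, per clinical
#' code, the single value observed in the first `windowMinutes` minutes
#' (worst value under the screening conventions for alert variables, the
#' earliest value otherwise), plus age and comorbidity count. This is the
#' table handed to [summarizeCohort()], [filterByMissingness()] and
#' [kaiserFactorScreen()].
#'
#' @param cohort an [EHRCohort-class].
#' @param windowMinutes evaluation window (default 360).
#' @return data.frame, one row per encounter.
#' @export
clinicalTable <- function(cohort, windowMinutes = 360) {
  stopifnot(is(cohort, "EHRCohort"))
  events <- data.table::as.data.table(cohort@events)
  ev <- events[kind %in% c("vital", "lab") & !is.na(value) &
                 t_minutes >= 0 & t_minutes < windowMinutes]
  worst_min <- c("platelets", "gcs", "sbp", "dbp", "pao2", "spo2",
                 "hemoglobin", "bicarbonate", "albumin", "sodium")
  worst_max <- c("bilirubin", "creatinine", "lactate", "inr", "wbc", "bun",
                 "alt", "ast", "crp", "esr", "troponin", "bands", "hr", "rr",
                 "temp", "glucose", "fio2", "chloride")
  ev[, pick := data.table::fifelse(code %in% worst_min, value,
                                   data.table::fifelse(code %in% worst_max, -value, t_minutes))]
  agg <- ev[order(pick), .SD[1L], by = .(encounter_id, code)]
  wide <- data.table::dcast(agg, encounter_id ~ code, value.var = "value")
  out <- merge(
    data.table::as.data.table(cohort@encounters[, c("encounter_id", "age_years",
                                                    "comorbidity_count")]),
    wide, by = "encounter_id", all.x = TRUE)
  as.data.frame(out)
}
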