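## Central S4 containers. Constructors live with their module files;
## this file holds representations, validity and accessors.

#' @rdname generatorConfig
#' @exportClass GeneratorConfig
setClass("GeneratorConfig", representation(
  nEncounters = "integer",
  sepsisPrevalence = "numeric",
  ageMean = "numeric",
  ageSd = "numeric",
  maleFraction = "numeric",
  raceProbs = "numeric",
  comorbidityMean = "numeric",
  comorbiditySd = "numeric",
  minorFraction = "numeric",
  edFraction = "numeric",
  missingness = "numeric",
  marginals = "data.frame",
  markerParams = "data.frame",
  tubeParams = "data.frame",
  eventRates = "list",
  arrivalsPerDay = "numeric",
  studyStart = "POSIXct",
  seed = "numeric"
))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  frac <- c(sepsisPrevalence = object@sepsisPrevalence,
            maleFraction = object@maleFraction,
            minorFraction = object@minorFraction,
            edFraction = object@edFraction)
  bad <- names(frac)[is.na(frac) | frac < 0 | frac > 1]
  if (length(bad)) msg <- c(msg, sprintf("fraction field(s) outside [0,1]: %s",
                                         paste(bad, collapse = ", ")))
  if (length(object@nEncounters) != 1L || is.na(object@nEncounters) ||
      object@nEncounters < 0L)
    msg <- c(msg, "nEncounters must be a single non-negative integer")
  if (any(object@missingness < 0 | object@missingness > 1))
    msg <- c(msg, "missingness rates must lie in [0,1]")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single number")
  if (any(object@tubeParams$sd < 0)) msg <- c(msg, "tube volume sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname generateCohort
#' @exportClass EHRCohort
setClass("EHRCohort", representation(
  encounters = "data.frame",
  events = "data.frame",
  specimens = "data.frame",
  truth = "data.frame",
  config = "GeneratorConfig"
))

setValidity("EHRCohort", function(object) {
  msg <- character()
  if (!all(c("encounter_id", "patient_id", "age_years", "sex", "race",
             "arrival_datetime", "location") %in% names(object@encounters)))
    msg <- c(msg, "encounters table lacks required columns")
  if (!all(c("encounter_id", "t_minutes", "kind", "code", "value", "unit") %in%
           names(object@events)))
    msg <- c(msg, "events table lacks required columns")
  if (nrow(object@events) && any(object@events$t_minutes < 0, na.rm = TRUE))
    msg <- c(msg, "event times must be minutes from arrival >= 0")
  if (nrow(object@truth) &&
      !identical(sort(object@truth$encounter_id),
                 sort(object@encounters$encounter_id)))
    msg <- c(msg, "exactly one truth label per encounter is required")
  if (length(msg)) msg else TRUE
})

#' @rdname evaluateSofaElements
#' @exportClass SofaAssessment
setClass("SofaAssessment", representation(
  encounterId = "character",
  elements = "data.frame",   # element, triggered, evidence_value, evidence_time
  windowMinutes = "numeric"
))

setValidity("SofaAssessment", function(object) {
  el <- object@elements
  msg <- character()
  if (!all(c("element", "triggered", "evidence_value", "evidence_time") %in% names(el)))
    msg <- c(msg, "elements table lacks required columns")
  if (nrow(el) != 6L) msg <- c(msg, "exactly six modified SOFA elements expected")
  tt <- el$evidence_time[el$triggered & !is.na(el$evidence_time)]
  if (length(tt) && any(tt < 0 | tt >= object@windowMinutes))
    msg <- c(msg, "evidence times must fall inside the screening window")
  if (length(msg)) msg else TRUE
})

#' @rdname buildFunnelReport
#' @exportClass FunnelReport
setClass("FunnelReport", representation(
  counts = "numeric",        # named: flagged, eligible_screened, ...
  percentages = "data.frame",# name, numerator, denominator, value, formatted
  context = "numeric"        # optional named context denominators
))

setValidity("FunnelReport", function(object) {
  cn <- object@counts
  need <- c("flagged", "eligible_screened", "not_screened_cap", "enrolled",
            "excluded", "excluded_specimen_window", "excluded_insufficient_volume",
            "excluded_tube_types_absent")
  msg <- character()
  if (!all(need %in% names(cn))) {
    msg <- c(msg, "counts must carry the full funnel")
  } else {
    if (any(cn < 0)) msg <- c(msg, "negative counts are not allowed")
    if (cn[["flagged"]] != cn[["eligible_screened"]] + cn[["not_screened_cap"]])
      msg <- c(msg, "conservation violated: flagged != eligible_screened + not_screened_cap")
    if (cn[["eligible_screened"]] != cn[["enrolled"]] + cn[["excluded"]])
      msg <- c(msg, "conservation violated: eligible_screened != enrolled + excluded")
    if (cn[["excluded"]] != cn[["excluded_specimen_window"]] +
        cn[["excluded_insufficient_volume"]] + cn[["excluded_tube_types_absent"]])
      msg <- c(msg, "conservation violated: exclusion reasons do not sum to excluded")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname assignStudyIds
#' @exportClass Crosswalk
setClass("Crosswalk", representation(
  map = "data.frame",        # study_id, patient_id, encounter_id
  created = "POSIXct"
))

setValidity("Crosswalk", function(object) {
  m <- object@map
  msg <- character()
  if (!all(c("study_id", "patient_id", "encounter_id") %in% names(m)))
    msg <- c(msg, "crosswalk needs study_id, patient_id, encounter_id")
  if (anyDuplicated(m$study_id)) msg <- c(msg, "study_id must be unique")
  if (anyDuplicated(m$encounter_id)) msg <- c(msg, "encounter_id must be unique")
  if (length(msg)) msg else TRUE
})

#' @rdname costDesign
#' @exportClass CostDesign
setClass("CostDesign", representation(
  name = "character",
  nPatients = "integer",
  items = "data.frame"       # label, category, cents (integer)
))

setValidity("CostDesign", function(object) {
  msg <- character()
  it <- object@items
  if (!all(c("label", "category", "cents") %in% names(it)))
    msg <- c(msg, "items need label, category, cents")
  else {
    if (any(it$cents < 0)) msg <- c(msg, "negative cost amounts are not allowed")
    if (!all(it$category %in% costCategories()))
      msg <- c(msg, sprintf("categories must be one of: %s",
                            paste(costCategories(), collapse = ", ")))
  }
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname compareDesigns
#' @exportClass CostReport
setClass("CostReport", representation(
  summary = "data.frame",    # design, n_patients, total, per_patient, ratio_to_cheapest
  byCategory = "data.frame"  # design, category, total
))

#' @rdname logfoldMatrix
#' @exportClass LogFoldMatrix
setClass("LogFoldMatrix", representation(
  logfold = "matrix",        # patients x markers, NA where unmeasured
  clip = "numeric",
  markerMedians = "numeric"
))

setValidity("LogFoldMatrix", function(object) {
  msg <- character()
  meds <- apply(object@logfold, 2, medianLow)
  meds <- meds[!is.na(meds)]
  if (length(meds) && any(abs(meds) > 1e-12))
    msg <- c(msg, "each marker column must have (type-1) median log-fold 0")
  if (length(object@clip) != 1L || object@clip <= 0)
    msg <- c(msg, "clip must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname kaiserFactorScreen
#' @exportClass FactorScreenResult
setClass("FactorScreenResult", representation(
  eigenvalues = "numeric",   # descending
  nRetained = "integer",
  loadings = "matrix",
  nVariables = "integer"
))

setValidity("FactorScreenResult", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (is.unsorted(rev(ev), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be in descending order")
  if (abs(sum(ev) - object@nVariables) > 1e-6)
    msg <- c(msg, "eigenvalues must sum to the number of variables")
  if (object@nRetained != sum(ev > 1))
    msg <- c(msg, "nRetained inconsistent with eigenvalues > 1")
  if (length(msg)) msg else TRUE
})

#' @rdname opticsReachability
#' @exportClass ReachabilityProfile
setClass("ReachabilityProfile", representation(
  order = "integer",         # visit order (indices into the input)
  reachability = "numeric",  # per visit position; NA where undefined
  coreDistances = "numeric", # per input point; NA where undefined
  minPts = "integer",
  eps = "numeric",
  standardized = "logical"
))

setValidity("ReachabilityProfile", function(object) {
  msg <- character()
  n <- length(object@order)
  if (!identical(sort(object@order), seq_len(n)))
    msg <- c(msg, "visit order must be a permutation of the input points")
  if (length(object@reachability) != n)
    msg <- c(msg, "one reachability value per visit position required")
  if (n && !is.na(object@reachability[1L]))
    msg <- c(msg, "the first visit position has undefined reachability")
  if (length(msg)) msg else TRUE
})

#' @rdname summarizeCohort
#' @exportClass CohortSummary
setClass("CohortSummary", representation(
  table = "data.frame"       # variable, type, n, stat1..stat3, formatted
))

## ---- accessors -------------------------------------------------------------

#' Accessors for EHRCohort objects
#'
#' @param x an [EHRCohort-class] object.
#' @return `encounters()`, `clinicalEvents()`, `specimensTable()` and
#'   `truthLabels()` return the corresponding data.frame;
#'   `generatorConfigOf()` the [GeneratorConfig-class] the cohort was built
#'   from.
#' @name cohort-accessors
#' @aliases encounters clinicalEvents specimensTable truthLabels generatorConfigOf
#' @examples
#' coh <- generateCohort(generatorConfig(nEncounters = 20, seed = 1))
#' head(encounters(coh))
#' nrow(truthLabels(coh))
NULL

#' @rdname cohort-accessors
#' @export
encounters <- function(x) { stopifnot(is(x, "EHRCohort")); x@encounters }

#' @rdname cohort-accessors
#' @export
clinicalEvents <- function(x) { stopifnot(is(x, "EHRCohort")); x@events }

#' @rdname cohort-accessors
#' @export
specimensTable <- function(x) { stopifnot(is(x, "EHRCohort")); x@specimens }

#' @rdname cohort-accessors
#' @export
truthLabels <- function(x) { stopifnot(is(x, "EHRCohort")); x@truth }

#' @rdname cohort-accessors
#' @export
generatorConfigOf <- function(x) { stopifnot(is(x, "EHRCohort")); x@config }

#' @rdname evaluateSofaElements
#' @param x a `SofaAssessment`.
#' @export
nElementsTriggered <- function(x) {
  stopifnot(is(x, "SofaAssessment"))
  sum(x@elements$triggered)
}

#' @rdname evaluateSofaElements
#' @export
sofaElements <- function(x) { stopifnot(is(x, "SofaAssessment")); x@elements }

#' @rdname buildFunnelReport
#' @param x a `FunnelReport`.
#' @export
funnelCounts <- function(x) { stopifnot(is(x, "FunnelReport")); x@counts }

#' @rdname buildFunnelReport
#' @export
funnelPercentages <- function(x) { stopifnot(is(x, "FunnelReport")); x@percentages }

#' @rdname assignStudyIds
#' @param x a `Crosswalk`.
#' @export
crosswalkTable <- function(x) { stopifnot(is(x, "Crosswalk")); x@map }

#' @rdname kaiserFactorScreen
#' @param x a `FactorScreenResult`.
#' @export
eigenvalues <- function(x) { stopifnot(is(x, "FactorScreenResult")); x@eigenvalues }

#' @rdname kaiserFactorScreen
#' @export
nRetained <- function(x) { stopifnot(is(x, "FactorScreenResult")); x@nRetained }

#' @rdname kaiserFactorScreen
#' @export
factorLoadings <- function(x) { stopifnot(is(x, "FactorScreenResult")); x@loadings }

#' @rdname opticsReachability
#' @param x a `ReachabilityProfile`.
#' @export
visitOrder <- function(x) { stopifnot(is(x, "ReachabilityProfile")); x@order }

#' @rdname opticsReachability
#' @export
reachability <- function(x) { stopifnot(is(x, "ReachabilityProfile")); x@reachability }

#' @rdname opticsReachability
#' @export
coreDistances <- function(x) { stopifnot(is(x, "ReachabilityProfile")); x@coreDistances }

#' @rdname logfoldMatrix
#' @param x a `LogFoldMatrix`.
#' @export
logfoldValues <- function(x) { stopifnot(is(x, "LogFoldMatrix")); x@logfold }

#' @rdname logfoldMatrix
#' @export
displayValues <- function(x) {
  stopifnot(is(x, "LogFoldMatrix"))
  pmin(pmax(x@logfold, -x@clip), x@clip)
}

#' @rdname summarizeCohort
#' @param x a `CohortSummary`.
#' @export
summaryTable <- function(x) { stopifnot(is(x, "CohortSummary")); x@table }

## ---- show methods ----------------------------------------------------------

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig\n")
  cat(sprintf("  encounters: %d (sepsis prevalence %.2f, minors %.2f)\n",
              object@nEncounters, object@sepsisPrevalence, object@minorFraction))
  cat(sprintf("  age: %.1f (SD %.1f) y; male fraction %.2f\n",
              object@ageMean, object@ageSd, object@maleFraction))
  cat(sprintf("  clinical variables: %d; markers: %d; tube types: %d\n",
              nrow(object@marginals), nrow(object@markerParams),
              nrow(object@tubeParams)))
  cat(sprintf("  seed: %s\n", format(object@seed)))
})

setMethod("show", "EHRCohort", function(object) {
  cat(sprintf("EHRCohort: %d encounters, %d events, %d specimens\n",
              nrow(object@encounters), nrow(object@events), nrow(object@specimens)))
  if (nrow(object@truth))
    cat(sprintf("  true sepsis: %d (%.1f%%)\n", sum(object@truth$true_sepsis),
                100 * mean(object@truth$true_sepsis)))
})

setMethod("show", "SofaAssessment", function(object) {
  cat(sprintf("SofaAssessment for %s (window %g min): %d/6 elements triggered\n",
              object@encounterId, object@windowMinutes, nElementsTriggered(object)))
  print(object@elements, row.names = FALSE)
})

setMethod("show", "FunnelReport", function(object) {
  cat("FunnelReport\n")
  cn <- object@counts
  cat(sprintf("  flagged: %d\n", cn[["flagged"]]))
  cat(sprintf("    eligible & screened: %d | not screened (cap): %d\n",
              cn[["eligible_screened"]], cn[["not_screened_cap"]]))
  cat(sprintf("    enrolled: %d | excluded: %d (window %d, volume %d, tubes %d)\n",
              cn[["enrolled"]], cn[["excluded"]],
              cn[["excluded_specimen_window"]],
              cn[["excluded_insufficient_volume"]],
              cn[["excluded_tube_types_absent"]]))
  if (nrow(object@percentages)) {
    cat("  percentages:\n")
    p <- object@percentages
    for (i in seq_len(nrow(p)))
      cat(sprintf("    %s: %s%% (%d/%d)\n", p$name[i], p$formatted[i],
                  p$numerator[i], p$denominator[i]))
  }
})

setMethod("show", "Crosswalk", function(object) {
  cat(sprintf("Crosswalk: %d enrolled patients (created %s)\n",
              nrow(object@map), format(object@created)))
})

setMethod("show", "CostDesign", function(object) {
  cat(sprintf("CostDesign '%s': %d line items, n = %d patients\n",
              object@name, nrow(object@items), object@nPatients))
  cat(sprintf("  total $%.2f ($%.2f per patient)\n",
              totalCost(object), perPatientCost(object)))
})

setMethod("show", "CostReport", function(object) {
  cat("CostReport\n")
  print(object@summary, row.names = FALSE)
})

setMethod("show", "LogFoldMatrix", function(object) {
  cat(sprintf("LogFoldMatrix: %d patients x %d markers (display clip +/-%g)\n",
              nrow(object@logfold), ncol(object@logfold), object@clip))
  rng <- range(object@logfold, na.rm = TRUE)
  cat(sprintf("  stored log2 fold range: [%.2f, %.2f]; %d missing cells\n",
              rng[1], rng[2], sum(is.na(object@logfold))))
})

setMethod("show", "FactorScreenResult", function(object) {
  cat(sprintf("FactorScreenResult: %d of %d eigenvalues > 1\n",
              object@nRetained, object@nVariables))
  cat("  top eigenvalues:", paste(sprintf("%.2f", head(object@eigenvalues, 6)),
                                  collapse = ", "), "\n")
})

setMethod("show", "ReachabilityProfile", function(object) {
  cat(sprintf("ReachabilityProfile: %d points, minPts = %d, eps = %s%s\n",
              length(object@order), object@minPts,
              if (is.infinite(object@eps)) "Inf" else format(object@eps),
              if (object@standardized) " (standardized)" else ""))
  cat(sprintf("  finite reachability values: %d\n",
              sum(is.finite(object@reachability))))
})

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary\n")
  print(object@table[, c("variable", "type", "n", "formatted")], row.names = FALSE)
})
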