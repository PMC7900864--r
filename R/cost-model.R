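## Cent-exact line-item cost accounting for alternative study designs.
## Currency is held as integer cents throughout; per-patient values are
## rounded half-up to whole cents.

#' Cost categories
#' @return the three recognized line-item categories.
#' @export
costCategories <- function() c("project_management", "laboratory", "data_management")

dollarsToCents <- function(amount) {
  cents <- round(amount * 100)
  if (any(abs(amount * 100 - cents) > 1e-6))
    stop("amounts must be dollars and whole cents")
  as.integer(cents)
}

#' Construct a study cost design
#'
#' @param name design name (unique within a comparison).
#' @param nPatients number of enrolled patients (>= 1).
#' @param items data.frame with `label`, `category` (one of
#'   [costCategories()]) and `amount` in dollars-and-cents (non-negative).
#' @return a [CostDesign-class].
#' @export
#' @examples
#' d <- costDesign("demo", 100, data.frame(
#'   label = c("alert", "lab"), category = c("project_management", "laboratory"),
#'   amount = c(1000, 250.50)))
#' totalCost(d)
costDesign <- function(name, nPatients, items) {
  checkColumns(items, c("label", "category", "amount"), "items")
  if (!nrow(items)) stop("a cost design needs at least one line item")
  if (any(items$amount < 0)) stop("negative cost amounts are not allowed")
  obj <- new("CostDesign", name = as.character(name),
             nPatients = as.integer(nPatients),
             items = data.frame(label = items$label, category = items$category,
                                cents = dollarsToCents(items$amount),
                                stringsAsFactors = FALSE))
  validObject(obj)
  obj
}

#' Total and per-patient cost of a design
#'
#' `totalCost()` is the exact cent-level sum of line items, returned in
#' dollars. `perPatientCost()` divides the cent total by the patient count
#' and rounds half-up to whole cents.
#'
#' @param design a [CostDesign-class].
#' @param category optional single category to restrict to.
#' @return numeric dollars.
#' @export
totalCost <- function(design, category = NULL) {
  stopifnot(is(design, "CostDesign"))
  it <- design@items
  if (!is.null(category)) it <- it[it$category == category, , drop = FALSE]
  sum(it$cents) / 100
}

#' @rdname totalCost
#' @export
perPatientCost <- function(design, category = NULL) {
  stopifnot(is(design, "CostDesign"))
  if (design@nPatients < 1L) stop("nPatients must be >= 1")
  it <- design@items
  if (!is.null(category)) it <- it[it$category == category, , drop = FALSE]
  roundHalfUp(sum(it$cents) / design@nPatients) / 100
}

#' Compare study cost designs
#'
#' Builds a comparison report: per-design totals, per-patient values,
#' per-category stratification (categories sum exactly to the design total in
#' cent arithmetic) and the ratio of each design's per-patient cost to the
#' cheapest design's.
#'
#' @param designs list of two or more [CostDesign-class] objects with unique
#'   names.
#' @return a [CostReport-class]; see `costSummary()` and
#'   `costByCategory()`.
#' @export
#' @examples
#' compareDesigns(vespreCostDesigns())
compareDesigns <- function(designs) {
  stopifnot(length(designs) >= 2L)
  nm <- vapply(designs, function(d) d@name, character(1))
  if (anyDuplicated(nm)) stop("duplicate design names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  summary <- do.call(rbind, lapply(designs, function(d) {
    data.frame(design = d@name, n_patients = d@nPatients,
               total = totalCost(d), per_patient = perPatientCost(d),
               stringsAsFactors = FALSE)
  }))
  cheapest <- min(summary$per_patient)
  summary$ratio_to_cheapest <- summary$per_patient / cheapest
  byCategory <- do.call(rbind, lapply(designs, function(d) {
    data.frame(design = d@name, category = costCategories(),
               total = vapply(costCategories(), function(cc) totalCost(d, cc),
                              numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- rownames(byCategory) <- NULL
  new("CostReport", summary = summary, byCategory = byCategory)
}

#' @rdname compareDesigns
#' @param report a [CostReport-class].
#' @export
costSummary <- function(report) { stopifnot(is(report, "CostReport")); report@summary }

#' @rdname compareDesigns
#' @export
costByCategory <- function(report) { stopifnot(is(report, "CostReport")); report@byCategory }

#' Read cost designs from a YAML file
#'
#' Expects a top-level `designs:` list, each entry with `name`,
#' `n_patients` and `items` (`label`, `category`, `amount`).
#'
#' @param path YAML file path.
#' @return list of [CostDesign-class] objects.
#' @export
readCostDesigns <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$designs)) stop("YAML must carry a top-level 'designs' list")
  lapply(y$designs, function(d) {
    items <- do.call(rbind, lapply(d$items, function(it)
      data.frame(label = it$label, category = it$category, amount = it$amount,
                 stringsAsFactors = FALSE)))
    costDesign(d$name, d$n_patients, items)
  })
}

#' The shipped three-design cost fixtures
#'
#' The screening-study design itself, the earlier prehospital
#' coordinator-led cohort, and the hypothetical coordinator-led cohort
#' covering the same activities, as line items.
#'
#' @return list of three [CostDesign-class] objects.
#' @export
vespreCostDesigns <- function() {
  readCostDesigns(system.file("extdata", "cost_designs.yaml", package = "vespre"))
}
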