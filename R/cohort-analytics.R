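## Proof-of-concept cohort analytics: Table-1 style summaries, missingness
## filter, log2 fold-change biomarker matrices and the eigenvalue factor
## screen.

#' Summarize cohort variables
#'
#' Continuous variables are reported as mean (SD) or median \[IQR\] per the
#' configuration; binary outcomes as count (integer percent). Descriptors are
#' computed on non-missing values.
#'
#' @param table data.frame, one row per patient.
#' @param variableConfig data.frame with `variable` and `type` in
#'   `mean_sd` / `median_iqr` / `binary`. Variables absent from `table` are
#'   an error.
#' @return a [CohortSummary-class]; `summaryTable()` returns the underlying
#'   data.frame with `stat1`-`stat3` (mean/sd, median/q1/q3 or
#'   count/percent) and a `formatted` column.
#' @export
#' @examples
#' tb <- data.frame(age = c(50, 60, 70), died = c(0, 0, 1))
#' cfg <- data.frame(variable = c("age", "died"), type = c("mean_sd", "binary"))
#' summaryTable(summarizeCohort(tb, cfg))
summarizeCohort <- function(table, variableConfig) {
  checkColumns(variableConfig, c("variable", "type"), "variableConfig")
  absent <- setdiff(variableConfig$variable, names(table))
  if (length(absent))
    stop("variable(s) in config absent from table: ", paste(absent, collapse = ", "))
  rows <- lapply(seq_len(nrow(variableConfig)), function(i) {
    v <- variableConfig$variable[i]
    type <- variableConfig$type[i]
    x <- table[[v]]
    xx <- x[!is.na(x)]
    n <- length(xx)
    if (type == "mean_sd") {
      m <- mean(xx); s <- stats::sd(xx)
      data.frame(variable = v, type = type, n = n, stat1 = m, stat2 = s,
                 stat3 = NA_real_,
                 formatted = sprintf("%.1f (%.1f)", m, s))
    } else if (type == "median_iqr") {
      q <- stats::quantile(xx, c(0.25, 0.5, 0.75), names = FALSE)
      if (q[1] > q[3]) stop("IQR bounds out of order for ", v)
      data.frame(variable = v, type = type, n = n, stat1 = q[2], stat2 = q[1],
                 stat3 = q[3],
                 formatted = sprintf("%.1f [%.1f-%.1f]", q[2], q[1], q[3]))
    } else if (type == "binary") {
      cnt <- sum(xx != 0)
      pct <- percentValue(cnt, n)
      data.frame(variable = v, type = type, n = n, stat1 = cnt, stat2 = pct,
                 stat3 = NA_real_,
                 formatted = sprintf("%d (%s%%)", cnt, formatPercent(cnt, n)))
    } else stop("unknown summary type: ", type)
  })
  new("CohortSummary", table = do.call(rbind, rows))
}

#' Filter variables by missingness
#'
#' Retains variables whose missing fraction is strictly below the threshold
#' (a variable at exactly the threshold is dropped).
#'
#' @param table data.frame of candidate variables.
#' @param threshold missing-fraction cutoff in (0, 1]; default 0.25.
#' @return character vector of retained variable names.
#' @export
#' @examples
#' tb <- data.frame(a = c(1, NA, 3, 4), b = 1:4)
#' filterByMissingness(tb, 0.25)  # drops a (25% missing, strict rule)
filterByMissingness <- function(table, threshold = 0.25) {
  stopifnot(threshold > 0, threshold <= 1)
  frac <- vapply(table, function(x) mean(is.na(x)), numeric(1))
  names(frac)[frac < threshold]
}

#' Log2 fold-change matrix against the cohort median
#'
#' Each entry is `log2(value / marker median)`, the marker median being the
#' lower-order-statistic (type 1) median over non-missing patients so that
#' the median patient maps to 0 exactly. Missing cells stay missing (white
#' cells in the heat map); values are stored unclipped, with the display clip
#' (default +/-4) applied by `displayValues()`.
#'
#' @param biomarkers a patients-by-markers data.frame/matrix of strictly
#'   positive concentrations, or the SummarizedExperiment from
#'   [generateBiomarkerPanel()].
#' @param clip display clip bound (default 4).
#' @return a [LogFoldMatrix-class]; see [logfoldValues()] and
#'   [displayValues()].
#' @export
#' @examples
#' m <- matrix(c(1, 2, 4, 8, 16, 32), ncol = 2,
#'             dimnames = list(NULL, c("A", "B")))
#' logfoldValues(logfoldMatrix(m))
logfoldMatrix <- function(biomarkers, clip = 4) {
  if (is(biomarkers, "SummarizedExperiment"))
    biomarkers <- t(SummarizedExperiment::assay(biomarkers, 1L))
  mat <- as.matrix(biomarkers)
  if (!is.numeric(mat)) stop("biomarker values must be numeric")
  bad <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    rn <- if (is.null(rownames(mat))) bad[1, 1] else rownames(mat)[bad[1, 1]]
    cn <- if (is.null(colnames(mat))) bad[1, 2] else colnames(mat)[bad[1, 2]]
    stop(sprintf("non-positive biomarker value at patient %s, marker %s", rn, cn))
  }
  med <- apply(mat, 2, medianLow)
  lf <- log2(sweep(mat, 2, unname(med), "/"))
  dimnames(lf) <- dimnames(mat)
  new("LogFoldMatrix", logfold = lf, clip = clip, markerMedians = med)
}

#' Eigenvalue (Kaiser) factor screen
#'
#' Eigen-decomposition of the correlation matrix; the number of retained
#' factors is the count of eigenvalues strictly greater than 1. When a raw
#' table is supplied the correlation matrix is computed on pairwise-complete
#' observations (the analytic choice matching a missingness-filtered, not
#' imputed, cohort). Unrotated loadings are the eigenvectors scaled by the
#' square roots of their eigenvalues.
#'
#' @param x a numeric data.frame/matrix (observations x variables) or a
#'   correlation matrix (square, symmetric, unit diagonal).
#' @return a [FactorScreenResult-class]; see [eigenvalues()], [nRetained()],
#'   [factorLoadings()].
#' @export
#' @examples
#' r <- diag(4); nRetained(kaiserFactorScreen(r))  # all eigenvalues 1: none
kaiserFactorScreen <- function(x) {
  mat <- as.matrix(x)
  if (!is.numeric(mat)) stop("input must be numeric")
  isCor <- nrow(mat) == ncol(mat) &&
    all(abs(diag(mat) - 1) < 1e-8) &&
    isTRUE(all.equal(mat, t(mat), tolerance = 1e-8)) &&
    all(abs(mat) <= 1 + 1e-8)
  if (isCor) {
    R <- mat
  } else {
    if (ncol(mat) < 2L) stop("at least two variables are required")
    sds <- apply(mat, 2, stats::sd, na.rm = TRUE)
    const <- colnames(mat)[!is.na(sds) & sds == 0]
    if (is.null(colnames(mat))) const <- which(!is.na(sds) & sds == 0)
    if (length(const))
      stop("constant column(s) with undefined correlation: ",
           paste(const, collapse = ", "))
    R <- stats::cor(mat, use = "pairwise.complete.obs")
    if (any(is.na(R)))
      stop("correlation undefined for some variable pairs (no overlapping observations)")
  }
  e <- eigen(R, symmetric = TRUE)
  lam <- e$values
  load <- e$vectors %*% diag(sqrt(pmax(lam, 0)), nrow = length(lam))
  dimnames(load) <- list(colnames(R), paste0("F", seq_along(lam)))
  new("FactorScreenResult", eigenvalues = lam, nRetained = sum(lam > 1),
      loadings = load, nVariables = ncol(R))
}
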