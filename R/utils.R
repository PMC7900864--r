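## Internal helpers shared across modules.

#' Run an expression with a fixed RNG state, restoring the caller's state
#' @noRd
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Truncated normal draws by inverse-CDF (exact, vectorized)
#' @noRd
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) stop("sd must be non-negative")
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  out <- numeric(n)
  deg <- sd == 0   # degenerate: point mass clamped to the bounds
  out[deg] <- pmin(pmax(mean[deg], lower[deg]), upper[deg])
  k <- which(!deg)
  if (length(k)) {
    pl <- stats::pnorm(lower[k], mean[k], sd[k])
    pu <- stats::pnorm(upper[k], mean[k], sd[k])
    out[k] <- stats::qnorm(stats::runif(length(k), pl, pu), mean[k], sd[k])
  }
  out
}

#' Log-normal draws parameterized by median and sdlog
#' @noRd
rlnormMedian <- function(n, median, sdlog) {
  if (any(median <= 0)) stop("log-normal median must be positive")
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

#' sdlog implied by a printed median and IQR of a log-normal variable
#' @noRd
sdlogFromIqr <- function(q1, q3) (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))

#' Round half away from zero (commercial rounding), vectorized
#' @noRd
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Lower-order-statistic (type 1) median: always an observed value
#' @noRd
medianLow <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  stats::quantile(x, probs = 0.5, type = 1, names = FALSE)
}

#' Format a percentage the way the funnel reports print them:
#' >= 1% to the nearest integer, < 1% to one decimal place.
#' @noRd
formatPercent <- function(numerator, denominator) {
  if (is.na(denominator) || denominator == 0) return(NA_character_)
  pct <- 100 * numerator / denominator
  if (pct >= 1) sprintf("%d", as.integer(roundHalfUp(pct))) else sprintf("%.1f", roundHalfUp(pct, 1))
}

#' Numeric percentage on the same rounding convention as formatPercent
#' @noRd
percentValue <- function(numerator, denominator) {
  if (is.na(denominator) || denominator == 0) return(NA_real_)
  pct <- 100 * numerator / denominator
  if (pct >= 1) roundHalfUp(pct) else roundHalfUp(pct, 1)
}

#' Stop unless all named columns are present
#' @noRd
checkColumns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}
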