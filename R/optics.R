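## OPTICS reachability analysis and the smooth-vs-jagged clustering
## diagnostic.
##
## Canonical OPTICS semantics: the core distance of a point is the distance
## to its minPts-th nearest neighbor, the point itself counting as the first
## (undefined when that distance exceeds eps); the reachability of o from p
## is max(coreDist(p), dist(p, o)). Points are processed through a
## min-priority structure over tentative reachability, seeded at the
## unprocessed point of smallest index; ties break by smallest index.

#' OPTICS reachability profile
#'
#' Orders the points by density connectivity and records each point's
#' reachability distance at the moment it is visited. Valleys in the
#' reachability plot indicate natural clusters; a flat profile indicates
#' none. Coordinates are z-score standardized by default before Euclidean
#' distances are taken (constant columns are left centered only).
#'
#' @param points numeric matrix/data.frame, one row per point.
#' @param minPts neighborhood size defining the core distance (>= 2,
#'   default 5).
#' @param eps maximum neighborhood radius (default `Inf`).
#' @param standardize z-score columns before computing distances
#'   (default TRUE).
#' @return a [ReachabilityProfile-class]; see [visitOrder()],
#'   [reachability()] (NA at the first position of every new component) and
#'   [coreDistances()].
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(40), ncol = 2), matrix(rnorm(40, 6), ncol = 2))
#' prof <- opticsReachability(pts, minPts = 4)
#' prof
opticsReachability <- function(points, minPts = 5, eps = Inf,
                               standardize = TRUE) {
  mat <- as.matrix(points)
  if (!is.numeric(mat)) stop("points must be numeric")
  n <- nrow(mat)
  if (minPts < 2) stop("minPts must be at least 2")
  if (n < minPts) stop("need at least minPts points")
  if (standardize) {
    ctr <- colMeans(mat)
    scl <- apply(mat, 2, stats::sd)
    scl[scl == 0] <- 1
    mat <- sweep(sweep(mat, 2, ctr), 2, scl, "/")
  }
  D <- as.matrix(stats::dist(mat))

  ## core distance: minPts-th smallest entry of the point's distance row
  ## (the zero self-distance counts as the first neighbor)
  core <- unname(apply(D, 1, function(d) sort(d, partial = minPts)[minPts]))
  core[core > eps] <- NA_real_

  processed <- logical(n)
  tentative <- rep(Inf, n)          # current best reachability per point
  order_out <- integer(n)
  reach_out <- numeric(n)
  for (pos in seq_len(n)) {
    cand <- which(!processed)
    p <- cand[which.min(tentative[cand])]  # which.min breaks ties by index
    order_out[pos] <- p
    reach_out[pos] <- tentative[p]
    processed[p] <- TRUE
    if (!is.na(core[p])) {
      nb <- which(!processed & D[p, ] <= eps)
      if (length(nb)) {
        newr <- pmax(core[p], D[p, nb])
        upd <- newr < tentative[nb]
        tentative[nb[upd]] <- newr[upd]
      }
    }
  }
  reach_out[!is.finite(reach_out)] <- NA_real_
  new("ReachabilityProfile", order = order_out, reachability = reach_out,
      coreDistances = core, minPts = as.integer(minPts), eps = as.numeric(eps),
      standardized = isTRUE(standardize))
}

#' Smoothness score and clustering-family recommendation
#'
#' Scores how jagged a reachability profile is: the mean absolute successive
#' difference of the finite reachability values, normalized by their
#' interquartile range. A jagged profile (clear natural cluster structure)
#' recommends hierarchical clustering; a smooth one recommends partitioning
#' methods. A perfectly constant profile scores 0.
#'
#' @param profile a [ReachabilityProfile-class] with at least three finite
#'   reachability values.
#' @param threshold recommendation cutoff (default 0.5, a documented
#'   heuristic): scores at or above it recommend `"hierarchical"`, below it
#'   `"partitioning"`.
#' @return list with `score` and `recommendation`.
#' @export
#' @examples
#' pts <- matrix(runif(100), ncol = 2)
#' smoothnessScore(opticsReachability(pts, minPts = 4))
smoothnessScore <- function(profile, threshold = 0.5) {
  stopifnot(is(profile, "ReachabilityProfile"))
  r <- profile@reachability
  r <- r[!is.na(r)]
  if (length(r) < 3L)
    stop("profile must carry at least three finite reachability values")
  msd <- mean(abs(diff(r)))
  iqr <- stats::IQR(r)
  score <- if (msd == 0) 0 else msd / iqr
  list(score = score,
       recommendation = if (score >= threshold) "hierarchical" else "partitioning")
}

#' Plot a reachability profile
#'
#' Reachability distance against visit order; undefined positions are drawn
#' at the top.
#'
#' @param profile a [ReachabilityProfile-class].
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plotReachability <- function(profile, ...) {
  stopifnot(is(profile, "ReachabilityProfile"))
  r <- profile@reachability
  top <- max(r, na.rm = TRUE) * 1.1
  r[is.na(r)] <- top
  graphics::barplot(r, border = NA, space = 0, xlab = "visit order",
                    ylab = "reachability distance", ...)
}

#' Plot a log-fold biomarker heat map
#'
#' Clipped log2 fold changes, green (low) through white (missing/zero) to
#' red (high).
#'
#' @param x a [LogFoldMatrix-class].
#' @param ... passed to [graphics::image()].
#' @return invisibly `NULL`.
#' @export
plotLogFold <- function(x, ...) {
  stopifnot(is(x, "LogFoldMatrix"))
  m <- displayValues(x)
  pal <- grDevices::colorRampPalette(c("darkgreen", "white", "red"))(101)
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  zlim = c(-x@clip, x@clip), col = pal,
                  xlab = "patient", ylab = "marker", ...)
  invisible(NULL)
}
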