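## Shared fixtures: event builders and independent reference implementations
## used as oracles.

ev <- function(code, t, value = NA_real_, kind = "lab", unit = "", id = "E1") {
  data.frame(encounter_id = id, t_minutes = t, kind = kind, code = code,
             value = value, unit = unit, stringsAsFactors = FALSE)
}

vital <- function(code, t, value, id = "E1") ev(code, t, value, kind = "vital", id = id)
lab <- function(code, t, value, id = "E1") ev(code, t, value, kind = "lab", id = id)
med <- function(code, t, id = "E1") ev(code, t, NA_real_, kind = "med_admin", id = id)
culture <- function(t, id = "E1") ev("blood_culture", t, NA_real_,
                                     kind = "culture_order", id = id)
requiredLabs <- function(t = 10, id = "E1") rbind(
  lab("hemoglobin", t, 12, id), lab("lactate", t, 1.2, id), lab("sodium", t, 138, id))

oneEncounter <- function(..., id = "E1", age = 50, location = "ED") {
  list(encounter = data.frame(encounter_id = id, age_years = age,
                              location = location, stringsAsFactors = FALSE),
       events = do.call(rbind, list(...)))
}

## independent full-SOFA reference: plain transcription of the six-organ
## grid as nested conditionals (vasopressor floors the cardiovascular score
## at 2; respiratory thresholds applied without the support condition)
sofaOracle <- function(pf = NA, plt = NA, bili = NA, map = NA, vaso = FALSE,
                       gcs = NA, creat = NA) {
  resp <- if (is.na(pf)) 0 else if (pf < 100) 4 else if (pf < 200) 3 else
    if (pf < 300) 2 else if (pf < 400) 1 else 0
  coag <- if (is.na(plt)) 0 else if (plt < 20) 4 else if (plt < 50) 3 else
    if (plt < 100) 2 else if (plt < 150) 1 else 0
  liver <- if (is.na(bili)) 0 else if (bili >= 12) 4 else if (bili >= 6) 3 else
    if (bili >= 2) 2 else if (bili >= 1.2) 1 else 0
  cardio <- if (vaso) 2 else if (!is.na(map) && map < 70) 1 else 0
  cns <- if (is.na(gcs)) 0 else if (gcs < 6) 4 else if (gcs < 10) 3 else
    if (gcs < 13) 2 else if (gcs < 15) 1 else 0
  renal <- if (is.na(creat)) 0 else if (creat >= 5) 4 else if (creat >= 3.5) 3 else
    if (creat >= 2) 2 else if (creat >= 1.2) 1 else 0
  resp + coag + liver + cardio + cns + renal
}

## exhaustive O(n^2) OPTICS reference, written directly from the
## definitions: core distance = distance to the minPts-th nearest neighbor
## (self counted first), reachability(o <- p) = max(core(p), d(p, o)),
## next point = unprocessed minimum tentative reachability, ties and fresh
## starts at the smallest index
opticsOracle <- function(X, minPts, eps = Inf) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  core <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- sort(D[i, ])
    if (d[minPts] <= eps) core[i] <- d[minPts]
  }
  remaining <- seq_len(n)
  best <- rep(Inf, n)
  ord <- integer(0)
  reach <- numeric(0)
  while (length(remaining)) {
    pick <- remaining[order(best[remaining], remaining)][1]
    ord <- c(ord, pick)
    reach <- c(reach, best[pick])
    remaining <- setdiff(remaining, pick)
    if (!is.na(core[pick])) {
      for (o in remaining) {
        if (D[pick, o] <= eps) {
          r <- max(core[pick], D[pick, o])
          if (r < best[o]) best[o] <- r
        }
      }
    }
  }
  reach[!is.finite(reach)] <- NA_real_
  list(order = ord, reachability = reach)
}
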