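test_that("cohort summaries follow the mean/median/binary conventions", {
  tb <- data.frame(flat = rep(7, 10), spread = c(1, 2, 3, 4, 5, NA, NA, NA, NA, NA),
                   died = c(rep(0, 9), 1))
  cfg <- data.frame(variable = c("flat", "spread", "died"),
                    type = c("mean_sd", "median_iqr", "binary"))
  s <- summaryTable(summarizeCohort(tb, cfg))
  expect_equal(s$stat2[s$variable == "flat"], 0)           # constant column: SD 0
  expect_equal(unlist(s[s$variable == "spread", c("stat1", "stat2", "stat3")],
                      use.names = FALSE), c(3, 2, 4))      # median 3, IQR [2,4]
  expect_identical(s$n[s$variable == "spread"], 5L)        # non-missing only
  expect_identical(s$formatted[s$variable == "died"], "1 (10%)")
  # binary outcomes use the integer-percent convention: 49 of 549 is 9%
  mort <- data.frame(died = c(rep(1, 49), rep(0, 500)))
  m <- summaryTable(summarizeCohort(mort, data.frame(variable = "died",
                                                     type = "binary")))
  expect_identical(m$formatted, "49 (9%)")
  expect_error(summarizeCohort(tb, data.frame(variable = "ghost", type = "mean_sd")),
               "ghost")
})

test_that("missingness filter is strict at the threshold", {
  set.seed(2)
  n <- 100
  tb <- as.data.frame(matrix(rnorm(n * 29), n, 29))
  # push exactly 6 variables to 30% missing, leave 23 at 10%
  for (j in 1:23) tb[sample(n, 10), j] <- NA
  for (j in 24:29) tb[sample(n, 30), j] <- NA
  kept <- filterByMissingness(tb, 0.25)
  expect_identical(sort(kept), sort(paste0("V", 1:23)))
  # all-complete tables keep everything
  expect_identical(filterByMissingness(data.frame(a = 1:4, b = 5:8)), c("a", "b"))
  # a variable at exactly 25% missing is excluded (strict rule)
  tb2 <- data.frame(a = c(NA, 1, 2, 3), b = 1:4)
  expect_identical(filterByMissingness(tb2, 0.25), "b")
})

test_that("log-fold matrix maps the marker median to zero and clips display", {
  # every value at its column median: all-zero matrix
  m0 <- matrix(5, 7, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_true(all(logfoldValues(logfoldMatrix(m0)) == 0))
  # 16x the median is +4; 64x stores 6 but displays 4 under the default clip
  m <- matrix(rep(c(1, 1, 1, 1, 16, 64), 2), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  lf <- logfoldMatrix(m)
  expect_equal(unname(logfoldValues(lf)[5, 1]), 4)
  expect_equal(unname(logfoldValues(lf)[6, 1]), 6)
  expect_equal(unname(displayValues(lf)[6, 1]), 4)
  expect_equal(unname(displayValues(lf)[5, 1]), 4)
  # missing cells stay missing
  mna <- matrix(c(1, 2, NA, 8), 4, 1, dimnames = list(NULL, "A"))
  expect_identical(sum(is.na(logfoldValues(logfoldMatrix(mna)))), 1L)
  # non-positive values error with the offending cell named
  bad <- matrix(c(1, -2), 2, 1, dimnames = list(c("p1", "p2"), "A"))
  expect_error(logfoldMatrix(bad), "p2.*A")
})

test_that("log-fold column medians are exactly zero for any n", {
  set.seed(5)
  for (n in c(5, 6, 11, 20)) {
    m <- matrix(rlnorm(n * 4, sdlog = 1), n, 4,
                dimnames = list(NULL, paste0("M", 1:4)))
    m[sample(length(m), 3)] <- NA
    lf <- logfoldValues(logfoldMatrix(m))
    meds <- apply(lf, 2, function(x) quantile(x[!is.na(x)], 0.5, type = 1))
    expect_true(all(abs(meds) < 1e-12))
  }
  # works on the panel container directly
  panel <- generateBiomarkerPanel(generatorConfig(seed = 6), sprintf("S%02d", 1:40))
  lf <- logfoldMatrix(panel)
  expect_identical(dim(logfoldValues(lf)), c(40L, 17L))
})

test_that("eigenvalue screen retains factors by the strict > 1 rule", {
  # identity correlation: all eigenvalues exactly 1, none retained
  expect_identical(nRetained(kaiserFactorScreen(diag(6))), 0L)
  # perfect rank-1 correlation on 23 variables: one factor, top eigenvalue 23
  ones <- matrix(1, 23, 23)
  fs <- kaiserFactorScreen(ones)
  expect_identical(nRetained(fs), 1L)
  expect_equal(eigenvalues(fs)[1], 23)
  # loadings are eigenvectors scaled by sqrt(eigenvalue)
  expect_equal(abs(factorLoadings(fs)[, 1]), rep(1, 23), tolerance = 1e-8)
})

test_that("eigenvalues conserve total variance and handle missing data", {
  set.seed(31)
  for (p in c(4, 9, 23)) {
    x <- matrix(rnorm(300 * p), 300, p)
    x[sample(length(x), 60)] <- NA   # pairwise-complete correlations
    fs <- kaiserFactorScreen(as.data.frame(x))
    expect_lt(abs(sum(eigenvalues(fs)) - p), 1e-8)
    expect_identical(nRetained(fs), sum(eigenvalues(fs) > 1))
  }
  expect_error(kaiserFactorScreen(data.frame(a = rep(1, 10), b = rnorm(10))),
               "constant")
  expect_error(kaiserFactorScreen(data.frame(a = rnorm(5))), "two variables")
})

test_that("a five-block synthetic cohort yields five retained factors", {
  x <- generateFactorCohort(n = 549, k = 5, p = 23, loading = 0.7, seed = 2027)
  expect_identical(nRetained(kaiserFactorScreen(x)), 5L)
})

test_that("optics matches the forced two-point solution", {
  pts <- rbind(c(0, 0), c(3, 4))   # distance 5
  prof <- opticsReachability(pts, minPts = 2, eps = Inf, standardize = FALSE)
  expect_identical(visitOrder(prof), c(1L, 2L))
  expect_identical(reachability(prof), c(NA_real_, 5))
  expect_equal(coreDistances(prof), c(5, 5))
  expect_error(opticsReachability(pts, minPts = 1), "minPts")
  expect_error(opticsReachability(pts[1, , drop = FALSE], minPts = 2), "minPts")
})

test_that("the first visit position always has undefined reachability", {
  set.seed(77)
  for (i in 1:5) {
    pts <- matrix(rnorm(30), ncol = 2)
    prof <- opticsReachability(pts, minPts = 3)
    expect_true(is.na(reachability(prof)[1]))
    expect_identical(sort(visitOrder(prof)), 1:15)
  }
})

test_that("optics agrees with the exhaustive reference on random instances", {
  set.seed(90125)
  for (i in 1:15) {
    n <- sample(6:25, 1)
    d <- sample(1:4, 1)
    minPts <- sample(2:min(5, n), 1)
    eps <- sample(c(Inf, runif(1, 0.5, 3)), 1)
    pts <- matrix(rnorm(n * d), n, d)
    prof <- opticsReachability(pts, minPts = minPts, eps = eps,
                               standardize = FALSE)
    ref <- opticsOracle(pts, minPts = minPts, eps = eps)
    expect_identical(visitOrder(prof), as.integer(ref$order),
                     info = sprintf("case %d (n=%d, minPts=%d)", i, n, minPts))
    expect_equal(reachability(prof), ref$reachability, tolerance = 1e-12,
                 info = sprintf("case %d", i))
  }
})

test_that("smoothness score separates jagged from smooth profiles", {
  flat <- new("ReachabilityProfile", order = 1:6,
              reachability = c(NA, rep(2, 5)), coreDistances = rep(1, 6),
              minPts = 2L, eps = Inf, standardized = FALSE)
  s <- smoothnessScore(flat)
  expect_equal(s$score, 0)
  expect_identical(s$recommendation, "partitioning")
  # strictly alternating low/high reachability scores higher than constant
  jag <- new("ReachabilityProfile", order = 1:8,
             reachability = c(NA, rep(c(1, 5), length.out = 7)),
             coreDistances = rep(1, 8), minPts = 2L, eps = Inf,
             standardized = FALSE)
  sj <- smoothnessScore(jag)
  expect_gt(sj$score, s$score)
  expect_identical(sj$recommendation, "hierarchical")
  # fewer than three finite values is an error
  thin <- new("ReachabilityProfile", order = 1:3,
              reachability = c(NA, NA, 1), coreDistances = rep(1, 3),
              minPts = 2L, eps = Inf, standardized = FALSE)
  expect_error(smoothnessScore(thin), "three finite")
})

test_that("well-separated clusters score jaggeder than a uniform blob", {
  set.seed(814)
  n <- 120
  centers <- matrix(c(0, 0, 8, 0, 0, 8), ncol = 2, byrow = TRUE)
  clustered <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(n / 3, centers[k, 1], 0.4), rnorm(n / 3, centers[k, 2], 0.4))))
  uniform <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  sc <- smoothnessScore(opticsReachability(clustered, minPts = 5))
  su <- smoothnessScore(opticsReachability(uniform, minPts = 5))
  expect_gt(sc$score, su$score)
})
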