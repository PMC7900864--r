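mkFlags <- function(times, day = "2020-01-01", ids = NULL) {
  n <- length(times)
  data.frame(encounter_id = if (is.null(ids)) sprintf("E%03d", seq_len(n)) else ids,
             flag_time_minutes = times,
             arrival_datetime = as.POSIXct(day, tz = "UTC"),
             stringsAsFactors = FALSE)
}

spRow <- function(id, tube, vol, t = 30) {
  data.frame(encounter_id = id, t_minutes = t, tube_type = tube,
             remnant_volume_ul = vol, stringsAsFactors = FALSE)
}

goodTubes <- function(id, t = 30) rbind(
  spRow(id, "heparin", 700, t), spRow(id, "edta", 600, t),
  spRow(id, "sodium_fluoride", 300, t))

test_that("daily cap screens the first flags per calendar day", {
  # 6 flags on one day, cap 4
  r <- applyDailyCap(mkFlags(c(10, 50, 20, 40, 30, 60)), 4)
  expect_identical(sum(r$screened), 4L)
  expect_setequal(r$encounter_id[r$screened], c("E001", "E003", "E005", "E004"))
  # 3 flags under a cap of 4 are all screened
  expect_true(all(applyDailyCap(mkFlags(c(5, 10, 15)), 4)$screened))
  # the cap resets at local midnight: two days x 4 flags all pass
  two <- rbind(mkFlags(1:4, "2020-01-01"),
               mkFlags(1:4, "2020-01-02", ids = sprintf("F%03d", 1:4)))
  expect_true(all(applyDailyCap(two, 4)$screened))
  # a flag late in the day can roll past midnight into the next calendar day
  late <- mkFlags(c(10, 20, 30, 40, 24 * 60 + 10), "2020-01-01")
  r2 <- applyDailyCap(late, 4)
  expect_true(r2$screened[5])
  expect_identical(as.character(r2$flag_day[5]), "2020-01-02")
})

test_that("cap ties break by ascending encounter id and cap is idempotent", {
  tied <- mkFlags(rep(15, 5), ids = c("E9", "E2", "E7", "E1", "E5"))
  r <- applyDailyCap(tied, 4)
  expect_false(r$screened[r$encounter_id == "E9"])
  r2 <- applyDailyCap(r[r$screened, ], 4)
  expect_true(all(r2$screened))
  expect_identical(sort(r2$encounter_id), sort(r$encounter_id[r$screened]))
  # cap 0 screens nobody; empty input is fine
  expect_false(any(applyDailyCap(tied, 0)$screened))
  expect_identical(nrow(applyDailyCap(tied[0, ], 4)), 0L)
})

test_that("exclusion cascade applies the three rules in printed order", {
  flags <- data.frame(encounter_id = c("W", "V", "T", "OK"))
  sp <- rbind(
    spRow("W", "heparin", 700, t = 400),       # nothing inside the window
    spRow("V", "heparin", 500),                # present but under the minimum
    goodTubes("OK"),
    spRow("T", "heparin", 700), spRow("T", "edta", 600))  # sodium fluoride absent
  r <- classifyExclusions(flags, sp)
  r <- r[match(c("W", "V", "T", "OK"), r$encounter_id), ]
  expect_identical(r$exclusion_reason,
                   c("specimen_window", "insufficient_volume",
                     "tube_types_absent", "none"))
  expect_identical(r$status, c("excluded", "excluded", "excluded", "enrolled"))
})

test_that("volume minima at the boundary follow printed strictness", {
  flags <- data.frame(encounter_id = c("A", "B"))
  # heparin exactly 550 fails its strict rule; 551/450/225 enroll
  spA <- rbind(spRow("A", "heparin", 550), spRow("A", "edta", 450),
               spRow("A", "sodium_fluoride", 225))
  spB <- rbind(spRow("B", "heparin", 551), spRow("B", "edta", 450),
               spRow("B", "sodium_fluoride", 225))
  r <- classifyExclusions(flags, rbind(spA, spB))
  expect_identical(r$exclusion_reason[r$encounter_id == "A"], "insufficient_volume")
  expect_identical(r$status[r$encounter_id == "B"], "enrolled")
  # urine is never required for enrollment
  flags2 <- data.frame(encounter_id = "C")
  r2 <- classifyExclusions(flags2, rbind(goodTubes("C"), spRow("C", "urine", 10)))
  expect_identical(r2$status, "enrolled")
})

test_that("exclusion reasons are invariant to specimen row order", {
  set.seed(7)
  flags <- data.frame(encounter_id = sprintf("E%02d", 1:30))
  sp <- do.call(rbind, lapply(flags$encounter_id, function(id) {
    k <- sample(0:4, 1)
    if (!k) return(NULL)
    data.frame(encounter_id = id,
               t_minutes = sample(0:500, k, replace = TRUE),
               tube_type = sample(c("heparin", "edta", "sodium_fluoride",
                                    "citrate", "urine"), k, replace = TRUE),
               remnant_volume_ul = round(runif(k, 100, 900)))
  }))
  base <- classifyExclusions(flags, sp)
  for (i in 1:5) {
    perm <- sp[sample(nrow(sp)), ]
    r <- classifyExclusions(flags, perm)
    expect_identical(r[order(r$encounter_id), c("status", "exclusion_reason")],
                     base[order(base$encounter_id), c("status", "exclusion_reason")])
  }
})

test_that("orphan specimen rows raise a warning and are ignored", {
  flags <- data.frame(encounter_id = "A")
  sp <- rbind(goodTubes("A"), goodTubes("GHOST"))
  expect_warning(r <- classifyExclusions(flags, sp), "without a matching")
  expect_identical(nrow(r), 1L)
  expect_identical(r$status, "enrolled")
})

test_that("study ids are sequential, zero padded and round trip exactly", {
  rec <- data.frame(encounter_id = c("E3", "E1", "E2", "E9"),
                    patient_id = c("P3", "P1", "P2", "P9"),
                    status = c("enrolled", "enrolled", "enrolled", "excluded"),
                    exclusion_reason = c("none", "none", "none", "specimen_window"),
                    flag_time_minutes = c(30, 10, 20, 5),
                    arrival_datetime = as.POSIXct("2020-01-01", tz = "UTC"),
                    stringsAsFactors = FALSE)
  out <- assignStudyIds(rec)
  xw <- crosswalkTable(out$crosswalk)
  expect_identical(xw$study_id, sprintf("VESPRE-%04d", 1:3))
  expect_identical(xw$encounter_id, c("E1", "E2", "E3"))  # flag-time order
  # the de-identified export carries no direct identifiers
  expect_false(any(c("patient_id", "encounter_id", "arrival_datetime") %in%
                     names(out$deidentified)))
  # crosswalk re-identification recovers the originals exactly
  back <- reidentify(out$deidentified, out$crosswalk)
  enr <- back[back$status == "enrolled", ]
  expect_setequal(enr$patient_id, c("P1", "P2", "P3"))
  expect_setequal(enr$encounter_id, c("E1", "E2", "E3"))
})

test_that("empty enrollment and duplicate enrollment behave", {
  none <- data.frame(encounter_id = "E1", patient_id = "P1", status = "excluded",
                     exclusion_reason = "specimen_window")
  out <- assignStudyIds(none)
  expect_identical(nrow(crosswalkTable(out$crosswalk)), 0L)
  dup <- data.frame(encounter_id = c("E1", "E1"), patient_id = "P1",
                    status = "enrolled", exclusion_reason = "none")
  expect_error(assignStudyIds(dup), "duplicate")
})

test_that("funnel report enforces conservation and prints percentages", {
  # counts shaped like the published funnel: 3428 flagged, 2199 screened,
  # 1229 capped, 1027 enrolled
  rec <- data.frame(
    status = c(rep("enrolled", 1027), rep("excluded", 1172),
               rep("eligible_not_screened_cap", 1229)),
    exclusion_reason = c(rep("none", 1027),
                         rep(c("specimen_window", "insufficient_volume",
                               "tube_types_absent"), length.out = 1172),
                         rep("none", 1229)))
  rep <- buildFunnelReport(rec, context = c(remnant_samples_identified = 12963,
                                            total_lab_specimens = 3054644))
  cn <- funnelCounts(rep)
  expect_identical(cn[["flagged"]], 3428L)
  expect_identical(cn[["flagged"]],
                   cn[["eligible_screened"]] + cn[["not_screened_cap"]])
  expect_identical(cn[["eligible_screened"]], cn[["enrolled"]] + cn[["excluded"]])
  p <- funnelPercentages(rep)
  expect_identical(p$formatted[p$name == "eligible_screened_of_flagged"], "64")
  expect_identical(p$formatted[p$name == "remnant_of_lab_specimens"], "0.4")
})

test_that("degenerate and invalid funnel inputs are handled", {
  empty <- data.frame(status = character(), exclusion_reason = character())
  rep <- buildFunnelReport(empty)
  expect_true(all(funnelCounts(rep) == 0))
  expect_true(all(is.na(funnelPercentages(rep)$formatted)))
  expect_error(buildFunnelReport(data.frame(status = "enrolled",
                                            exclusion_reason = "none"),
                                 context = c(total_ed_encounters = -1)),
               "negative")
  expect_error(buildFunnelReport(data.frame(status = "wat",
                                            exclusion_reason = "none")),
               "unknown status")
})

test_that("the funnel wrapper conserves every level on generated cohorts", {
  for (seed in c(1, 202)) {
    coh <- generateCohort(generatorConfig(nEncounters = 1200, seed = seed))
    s <- screenCohort(coh)
    res <- enrollCohort(s, specimensTable(coh))
    cn <- funnelCounts(res$report)
    expect_identical(cn[["flagged"]], sum(s$flagged))
    expect_identical(cn[["flagged"]],
                     cn[["eligible_screened"]] + cn[["not_screened_cap"]])
    expect_identical(cn[["eligible_screened"]],
                     cn[["enrolled"]] + cn[["excluded"]])
    expect_identical(cn[["excluded"]],
                     cn[["excluded_specimen_window"]] +
                       cn[["excluded_insufficient_volume"]] +
                       cn[["excluded_tube_types_absent"]])
    expect_identical(nrow(crosswalkTable(res$crosswalk)), as.integer(cn[["enrolled"]]))
  }
})
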