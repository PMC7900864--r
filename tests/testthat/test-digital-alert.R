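test_that("modified SOFA elements use strict thresholds", {
  # one unit below the platelet cutoff triggers exactly one element
  a <- evaluateSofaElements(lab("platelets", 30, 149))
  expect_identical(nElementsTriggered(a), 1L)
  el <- sofaElements(a)
  expect_true(el$triggered[el$element == "platelets"])
  expect_identical(el$evidence_value[el$element == "platelets"], 149)

  # every boundary value fails its strict inequality
  boundary <- rbind(
    lab("platelets", 10, 150), vital("gcs", 10, 15), lab("bilirubin", 10, 1.2),
    lab("creatinine", 10, 1.2), vital("sbp", 10, 90), vital("dbp", 10, 60),
    lab("pao2", 10, 160), vital("fio2", 10, 0.4))
  expect_identical(nElementsTriggered(evaluateSofaElements(boundary)), 0L)
  # (90 + 2*60)/3 = 70 exactly; 160/0.4 = 400 exactly
})

test_that("elements are false without data and use worst-in-window values", {
  expect_identical(nElementsTriggered(evaluateSofaElements(lab("sodium", 5, 140))), 0L)
  # worst (minimum) platelet value in window decides, later recovery ignored
  a <- evaluateSofaElements(rbind(lab("platelets", 10, 200),
                                  lab("platelets", 100, 120),
                                  lab("platelets", 300, 180)))
  el <- sofaElements(a)
  expect_identical(el$evidence_value[el$element == "platelets"], 120)
  expect_identical(el$evidence_time[el$element == "platelets"], 100)
  # events at or beyond the window boundary are invisible (half-open window)
  b <- evaluateSofaElements(lab("platelets", 360, 80))
  expect_identical(nElementsTriggered(b), 0L)
})

test_that("cardiovascular element honors vasopressors and derived MAP", {
  # normal MAP throughout but a vasopressor administration triggers
  a <- evaluateSofaElements(rbind(vital("sbp", 10, 120), vital("dbp", 10, 80),
                                  med("norepinephrine", 50)))
  el <- sofaElements(a)
  expect_true(el$triggered[el$element == "map_or_pressor"])
  # derived MAP (sbp + 2 dbp)/3 from same-time pairs
  b <- evaluateSofaElements(rbind(vital("sbp", 20, 80), vital("dbp", 20, 50)))
  expect_true(sofaElements(b)$triggered[2 + 1])  # map_or_pressor row
  # direct map measurements take precedence over derived pairs
  d <- evaluateSofaElements(rbind(vital("sbp", 20, 80), vital("dbp", 20, 50),
                                  vital("map", 30, 85)))
  el <- sofaElements(d)
  expect_false(el$triggered[el$element == "map_or_pressor"])
  expect_identical(el$evidence_value[el$element == "map_or_pressor"], 85)
})

test_that("P/F ratio needs an FiO2, with room air imputed from device events", {
  # PaO2 alone: no FiO2 information, element stays false
  expect_identical(nElementsTriggered(evaluateSofaElements(lab("pao2", 10, 80))), 0L)
  # room-air device event imputes FiO2 0.21: 80/0.21 = 381 < 400
  a <- evaluateSofaElements(rbind(lab("pao2", 10, 80),
                                  ev("o2_device", 10, NA, kind = "vital",
                                     unit = "room air")))
  expect_true(sofaElements(a)$triggered[1])
  # measured FiO2: 80/0.5 = 160
  b <- evaluateSofaElements(rbind(lab("pao2", 10, 80), vital("fio2", 10, 0.5)))
  el <- sofaElements(b)
  expect_true(el$triggered[el$element == "pf_ratio"])
  expect_identical(el$evidence_value[el$element == "pf_ratio"], 160)
})

test_that("suspected infection needs both cultures and antibiotics in window", {
  expect_true(detectSuspectedInfection(rbind(culture(120), med("antibiotic", 300))))
  expect_false(detectSuspectedInfection(rbind(culture(420), med("antibiotic", 60))))
  expect_false(detectSuspectedInfection(med("antibiotic", 60)))
  expect_false(detectSuspectedInfection(culture(60)))
  expect_false(detectSuspectedInfection(culture(60)[0, ]))
  # vasopressors are not antibiotics
  expect_false(detectSuspectedInfection(rbind(culture(60), med("norepinephrine", 70))))
})

test_that("required labs rule needs hemoglobin, lactate and sodium", {
  expect_true(checkRequiredLabs(requiredLabs()))
  expect_false(checkRequiredLabs(rbind(lab("hemoglobin", 10, 12),
                                       lab("lactate", 10, 1.5))))
  expect_false(checkRequiredLabs(requiredLabs()[0, ]))
  expect_false(checkRequiredLabs(rbind(lab("hemoglobin", 370, 12),
                                       lab("lactate", 10, 1.5),
                                       lab("sodium", 10, 140))))
})

test_that("the alert fires only when all six criteria hold", {
  full <- rbind(culture(120), med("antibiotic", 150), lab("platelets", 60, 100),
                requiredLabs(200))
  one <- oneEncounter(full, age = 40)
  flag <- generateAlert(one$encounter, one$events)
  expect_s3_class(flag, "data.frame")
  expect_true(all(unlist(flag[c("ed_location", "age_ge_18", "cultures_in_window",
                                "antibiotics_in_window", "sofa_element",
                                "required_labs")])))
  # flag time: earliest minute all criteria are simultaneously satisfied
  expect_identical(flag$flag_time_minutes, 200)

  # age 17 fails criterion 2
  minor <- oneEncounter(full, age = 17)
  expect_null(generateAlert(minor$encounter, minor$events))
  # location outside the enrolling ED fails criterion 1
  ward <- oneEncounter(full, location = "ward")
  expect_null(generateAlert(ward$encounter, ward$events))
  # a missing sodium result fails the required-labs criterion
  nosod <- oneEncounter(culture(120), med("antibiotic", 150),
                        lab("platelets", 60, 100), lab("hemoglobin", 10, 12),
                        lab("lactate", 10, 1.5))
  expect_null(generateAlert(nosod$encounter, nosod$events))
  # missing age is a validation error
  noage <- oneEncounter(full, age = NA)
  expect_error(generateAlert(noage$encounter, noage$events), "age")
})

test_that("non-numeric values for numeric codes are a validation error", {
  bad <- data.frame(encounter_id = "E1", t_minutes = 10, kind = "lab",
                    code = "platelets", value = "not-a-number", unit = "")
  expect_error(evaluateSofaElements(bad), "validation")
  # coercible strings pass
  okv <- data.frame(encounter_id = "E1", t_minutes = 10, kind = "lab",
                    code = "platelets", value = "120", unit = "")
  expect_identical(nElementsTriggered(evaluateSofaElements(okv)), 1L)
})

test_that("full-SOFA adjudication matches the published grid", {
  # all values in the normal range score zero
  normal <- rbind(lab("platelets", 10, 250), lab("bilirubin", 10, 0.8),
                  lab("creatinine", 10, 0.9), vital("gcs", 10, 15),
                  vital("sbp", 10, 120), vital("dbp", 10, 80))
  expect_identical(adjudicateFullSofa(normal), 0L)
  # platelets 90 as the only abnormality scores 2 (< 100)
  expect_identical(adjudicateFullSofa(lab("platelets", 10, 90)), 2L)
  # GCS 14 and creatinine 1.5 score one point each
  expect_identical(adjudicateFullSofa(rbind(vital("gcs", 10, 14),
                                            lab("creatinine", 10, 1.5))), 2L)
  # organs with no data score 0; empty stream scores 0
  expect_identical(adjudicateFullSofa(lab("sodium", 10, 140)), 0L)
  expect_identical(adjudicateFullSofa(lab("sodium", 10, 140)[0, ]), 0L)
})

test_that("adjudication agrees with an independent grid transcription", {
  set.seed(404)
  for (i in 1:60) {
    vals <- list(
      plt = sample(c(NA, round(runif(1, 5, 400))), 1),
      bili = sample(c(NA, round(runif(1, 0.1, 15), 1)), 1),
      creat = sample(c(NA, round(runif(1, 0.3, 7), 1)), 1),
      gcs = sample(c(NA, sample(3:15, 1)), 1),
      map = sample(c(NA, round(runif(1, 40, 120))), 1),
      pf = sample(c(NA, round(runif(1, 40, 520))), 1),
      vaso = sample(c(TRUE, FALSE), 1))
    evts <- list()
    if (!is.na(vals$plt)) evts <- c(evts, list(lab("platelets", 10, vals$plt)))
    if (!is.na(vals$bili)) evts <- c(evts, list(lab("bilirubin", 11, vals$bili)))
    if (!is.na(vals$creat)) evts <- c(evts, list(lab("creatinine", 12, vals$creat)))
    if (!is.na(vals$gcs)) evts <- c(evts, list(vital("gcs", 13, vals$gcs)))
    if (!is.na(vals$map)) evts <- c(evts, list(vital("map", 14, vals$map)))
    if (!is.na(vals$pf)) evts <- c(evts, list(lab("pao2", 15, vals$pf),
                                              vital("fio2", 15, 1)))
    if (vals$vaso) evts <- c(evts, list(med("vasopressin", 16)))
    if (!length(evts)) next
    events <- do.call(rbind, evts)
    expect_identical(
      adjudicateFullSofa(events),
      as.integer(sofaOracle(pf = vals$pf, plt = vals$plt, bili = vals$bili,
                            map = vals$map, vaso = vals$vaso, gcs = vals$gcs,
                            creat = vals$creat)),
      info = paste("case", i))
  }
})

test_that("every triggered element implies its organ sub-score >= 1", {
  coh <- generateCohort(generatorConfig(nEncounters = 500, seed = 55))
  s <- screenCohort(coh)
  expect_true(all(s$adjudicated_sofa >= s$n_elements_triggered))
  expect_true(all(s$adjudicated_sofa[s$sofa_element] >= 1))
})

test_that("adding qualifying organ-dysfunction evidence never removes a flag", {
  coh <- generateCohort(generatorConfig(nEncounters = 400, seed = 66))
  s <- screenCohort(coh)
  flagged <- s$encounter_id[s$flagged]
  expect_gt(length(flagged), 3)
  extra <- do.call(rbind, lapply(head(flagged, 10), function(id)
    lab("platelets", 5, 40, id = id)))
  s2 <- screenCohort(encounters = encounters(coh),
                     events = rbind(clinicalEvents(coh), extra))
  expect_true(all(s2$flagged[match(flagged, s2$encounter_id)]))
  # and the alert output is a pure function of the event stream
  s3 <- screenCohort(coh)
  expect_identical(s[order(s$encounter_id), ], s3[order(s3$encounter_id), ])
})
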