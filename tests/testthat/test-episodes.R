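test_that("specialty classification: lookup, defaults, warning on unknowns", {
  cls <- classify_specialty(c("MICU", "CLC", "WARD"))
  expect_equal(cls$acute, c(TRUE, FALSE, TRUE))
  expect_equal(cls$icu, c(TRUE, FALSE, FALSE))
  expect_warning(u <- classify_specialty("XYZQ", default_acute = FALSE),
                 "unregistered")
  expect_false(u$acute); expect_false(u$icu)
  # case/whitespace-insensitive lookup
  expect_true(suppressWarnings(classify_specialty(" micu ")$icu))
})

test_that("worked-example trajectory reconstructs the published nesting", {
  ex <- generate_worked_example()
  st <- ex$specialty_transfers
  expect_equal(nrow(st), 4L)
  expect_equal(length(unique(st$facility_id)), 2L)
  # transfer happens on one calendar day: first stay ends the day the second begins
  expect_equal(as.Date(st$discharge[1]), as.Date(st$admit[2]))
  # CLC is non-acute under the default config
  expect_false(classify_specialty("CLC")$acute)

  sshs <- build_single_site_hospitalizations(st)
  expect_equal(nrow(sshs), 2L)
  expect_setequal(sshs$facility_id, c("F-BATTLE-CREEK", "F-ANN-ARBOR"))
  bedded <- build_bedded_stays(st)
  expect_equal(nrow(bedded), 4L)
  expect_equal(nrow(link_acute_hospitalizations(sshs)), 1L)
  expect_equal(nrow(build_episodes_of_care(bedded)), 1L)

  days <- expand_patient_facility_days(sshs)
  day1 <- min(days$date)
  expect_equal(nrow(days[date == day1 + 2]), 2L)          # transfer day: 2 rows
  d7 <- days[date == day1 + 6]
  expect_equal(nrow(d7), 1L)                               # same-facility move: 1 row
  expect_true(d7$icu_day)                                  # part-day ICU flags the day
})

test_that("single stays and empty/no-acute inputs behave at the boundaries", {
  one <- data.table(patient_id = "P1", facility_id = "F1",
                    specialty_code = "WARD",
                    admit = as.POSIXct("2014-02-01 08:00:00", tz = "UTC"),
                    discharge = as.POSIXct("2014-02-01 15:00:00", tz = "UTC"))
  expect_equal(nrow(build_bedded_stays(one)), 1L)
  sshs <- build_single_site_hospitalizations(one)
  expect_equal(nrow(sshs), 1L)
  # same-day admit/discharge: closed interval -> exactly 1 row
  expect_equal(nrow(expand_patient_facility_days(sshs)), 1L)
  # an isolated bedded stay is its own episode
  expect_equal(nrow(build_episodes_of_care(build_bedded_stays(one))), 1L)

  clc <- copy(one)[, specialty_code := "CLC"]
  expect_equal(nrow(build_single_site_hospitalizations(clc)), 0L)
})

test_that("acute run interrupted by a non-acute stay splits into two SSHs", {
  st <- data.table(
    patient_id = "P1", facility_id = "F1",
    specialty_code = c("WARD", "CLC", "WARD"),
    admit = as.POSIXct(c("2014-02-01 08:00", "2014-02-05 10:00",
                         "2014-02-12 09:00"), tz = "UTC"),
    discharge = as.POSIXct(c("2014-02-05 09:00", "2014-02-12 08:00",
                             "2014-02-15 11:00"), tz = "UTC"))
  sshs <- build_single_site_hospitalizations(st)
  expect_equal(nrow(sshs), 2L)
  # but the bedded stays chain into one episode of care
  expect_equal(nrow(build_episodes_of_care(build_bedded_stays(st))), 1L)
})

test_that("two SSHs far apart stay separate acute hospitalizations", {
  st <- data.table(
    patient_id = "P1", facility_id = c("F1", "F2"),
    specialty_code = "WARD",
    admit = as.POSIXct(c("2014-02-01 08:00", "2014-03-10 08:00"), tz = "UTC"),
    discharge = as.POSIXct(c("2014-02-05 09:00", "2014-03-14 09:00"), tz = "UTC"))
  sshs <- build_single_site_hospitalizations(st)
  expect_equal(nrow(link_acute_hospitalizations(sshs)), 2L)
})

test_that("grouping equals the brute-force closure oracle on random instances", {
  map <- load_specialty_map()
  for (seed in 1:25) {
    st <- random_stays(sample(5:50, 1L), seed = seed)
    sshs <- build_single_site_hospitalizations(st, map)
    mem <- attr(sshs, "member_stays")
    ora <- closure_components(mem$admit_date, mem$discharge_date,
                              paste(mem$patient_id, mem$facility_id))
    expect_true(same_partition(mem$ssh_id, ora),
                info = sprintf("SSH grouping, seed %d", seed))
    hosp <- link_acute_hospitalizations(sshs)
    lab <- rep(hosp$hosp_id, lengths(hosp$unit_ids))[
      match(sshs$ssh_id, unlist(hosp$unit_ids))]
    ora2 <- closure_components(sshs$admit_date, sshs$discharge_date,
                               sshs$patient_id)
    expect_true(same_partition(lab, ora2),
                info = sprintf("hospitalization chaining, seed %d", seed))
  }
})

test_that("every stay lands in exactly one group (partition invariant)", {
  st <- random_stays(60, seed = 42)
  sshs <- build_single_site_hospitalizations(st)
  mem <- attr(sshs, "member_stays")
  cls <- suppressWarnings(classify_specialty(st$specialty_code))
  expect_equal(nrow(mem), sum(cls$acute))
  expect_equal(anyDuplicated(mem$stay_id), 0L)
  bedded <- build_bedded_stays(st)
  expect_equal(nrow(attr(bedded, "member_stays")), nrow(st))
})

test_that("row-count conservation: day rows equal inclusive SSH spans", {
  st <- random_stays(80, seed = 7)
  sshs <- build_single_site_hospitalizations(st)
  days <- expand_patient_facility_days(sshs)
  spans <- sshs[, sum(as.integer(discharge_date - admit_date) + 1L)]
  expect_equal(nrow(days), spans)
  expect_equal(anyDuplicated(days[, .(patient_id, facility_id, date)]), 0L)
})

test_that("adding an unrelated patient never changes another patient's output", {
  a <- random_stays(20, n_patients = 1L, seed = 11)
  b <- random_stays(20, n_patients = 1L, seed = 12)[, patient_id := "P99"]
  solo <- build_single_site_hospitalizations(a)
  both <- build_single_site_hospitalizations(rbindlist(list(a, b)))
  keep <- c("patient_id", "facility_id", "admit_date", "discharge_date", "n_stays")
  expect_equal(both[patient_id == "P01", ..keep], solo[, ..keep],
               ignore_attr = TRUE)
})

test_that("overlapping stays at one facility are truncated, not duplicated", {
  st <- data.table(
    patient_id = "P1", facility_id = "F1", specialty_code = c("MICU", "WARD"),
    admit = as.POSIXct(c("2014-02-01 08:00", "2014-02-03 10:00"), tz = "UTC"),
    discharge = as.POSIXct(c("2014-02-05 09:00", "2014-02-08 11:00"), tz = "UTC"))
  sshs <- build_single_site_hospitalizations(st)
  days <- expand_patient_facility_days(sshs)
  expect_equal(anyDuplicated(days[, .(patient_id, facility_id, date)]), 0L)
  expect_equal(nrow(days), 8L)  # Feb 1-8 inclusive
})

test_that("missing discharge censors the SSH with a warning", {
  st <- data.table(patient_id = "P1", facility_id = "F1",
                   specialty_code = "WARD",
                   admit = as.POSIXct("2014-02-01 08:00", tz = "UTC"),
                   discharge = as.POSIXct(NA, tz = "UTC"))
  expect_warning(sshs <- build_single_site_hospitalizations(st), "censored")
  expect_true(sshs$censored)
  out <- compute_outcomes(sshs)
  expect_true(is.na(out$los_days))
  expect_true(is.na(out$readmit_30d))
})

test_that("outcome definitions: nesting, 30-day anchor, live-discharge denominator", {
  st <- data.table(
    patient_id = c("P1", "P2", "P3", "P3"), facility_id = "F1",
    specialty_code = "WARD",
    admit = as.POSIXct(c("2014-02-01 08:00", "2014-02-01 08:00",
                         "2014-02-01 08:00", "2014-02-20 08:00"), tz = "UTC"),
    discharge = as.POSIXct(c("2014-02-05 09:00", "2014-02-06 09:00",
                             "2014-02-04 09:00", "2014-02-25 09:00"), tz = "UTC"))
  sshs <- build_single_site_hospitalizations(st)
  deaths <- data.table(patient_id = c("P1", "P2"),
                       death_date = as.Date(c("2014-02-05", "2014-02-21")))
  out <- compute_outcomes(sshs, deaths)
  p1 <- out[patient_id == "P1"]
  # death on the discharge date: in-hospital, hence also 30-day
  expect_true(p1$in_hospital_mortality); expect_true(p1$mortality_30d)
  # in-hospital death is excluded from the readmission denominator
  expect_true(is.na(p1$readmit_30d))
  p2 <- out[patient_id == "P2"]
  # death 20 days after admission, after discharge: 30-day yes, in-hospital no
  expect_false(p2$in_hospital_mortality); expect_true(p2$mortality_30d)
  p3 <- out[patient_id == "P3"][order(admit_date)]
  expect_true(p3$readmit_30d[1])   # readmitted 16 days post-discharge
  expect_false(p3$readmit_30d[2])

  # death before admission is a hard input error
  expect_error(
    compute_outcomes(sshs, data.table(patient_id = "P1",
                                      death_date = as.Date("2014-01-01"))),
    class = "pd_input_error")
})
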