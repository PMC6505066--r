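cfg <- load_lab_config()

test_that("dual-path matching: LOINC, name with blank LOINC, topography veto", {
  labs <- rbindlist(list(
    lab_rec(name = "CREAT", loinc = "2160-0"),                      # LOINC path
    lab_rec(name = "White Blood Cell Count", loinc = "", topo = "BLOOD",
            value = 8.4, unit = "10*3/uL"),                          # name path
    lab_rec(name = "glucose, CSF", loinc = "", topo = "CSF",
            value = 60, unit = "mg/dL")))                            # topo reject
  m <- match_lab_records(labs, cfg)
  expect_equal(nrow(m), 2L)
  expect_equal(m[1, test_id], "creatinine")
  expect_equal(m[1, match_path], "loinc")
  expect_equal(m[2, test_id], "wbc")
  expect_equal(m[2, match_path], "name")
  a <- attr(m, "audit")
  expect_equal(nrow(a$unmatched), 1L)
  expect_equal(a$name_only_blank_loinc, 1L)
  # conservation: matched + unmatched + conflicted = input
  expect_equal(nrow(m) + nrow(a$unmatched) + nrow(a$conflicts), nrow(labs))
})

test_that("a record matching two tests is routed to the conflict report", {
  # a LOINC from one test with another test's name
  labs <- lab_rec(name = "PLATELET COUNT", loinc = "2160-0", topo = "BLOOD",
                  value = 100, unit = "10*3/uL")
  m <- match_lab_records(labs, cfg)
  expect_equal(nrow(m), 0L)
  expect_equal(nrow(attr(m, "audit")$conflicts), 1L)
})

test_that("unit conversion: Fahrenheit, identity, unconvertible rejection", {
  tt <- cfg$vitals$temperature
  expect_equal(convert_units(98.6, "F", tt), 37.0, tolerance = 1e-9)
  expect_equal(convert_units(37.0, "C", tt), 37.0)
  expect_true(is.na(convert_units(98.6, "banana", tt)))
  # umol/L creatinine -> mg/dL (88.4 umol/L is 1 mg/dL)
  expect_equal(convert_units(88.4, "umol/L", cfg$labs$creatinine), 1.0,
               tolerance = 1e-3)

  recs <- rbindlist(list(lab_rec(value = 1.2, unit = "mg/dL"),
                         lab_rec(value = 1.2, unit = "banana")))
  m <- match_lab_records(recs, cfg)
  s <- standardize_units(m, cfg)
  expect_equal(nrow(s), 1L)
  expect_equal(nrow(attr(s, "audit")$unconvertible), 1L)
})

test_that("plausibility filter: impossible values out, in-range identity, rate recovery", {
  neg <- standardize_units(match_lab_records(lab_rec(value = -1), cfg), cfg)
  f <- apply_plausibility_filter(neg, cfg)
  expect_equal(nrow(f), 0L)
  expect_equal(nrow(attr(f, "audit")$rejected), 1L)

  ok <- standardize_units(match_lab_records(rbindlist(
    lapply(c(0.7, 1.1, 2.3), function(v) lab_rec(value = v))), cfg), cfg)
  expect_equal(nrow(apply_plausibility_filter(ok, cfg)), 3L)

  # inject 5% out-of-range values; rejected fraction within exact binomial CI
  set.seed(404)
  n <- 2000L
  bad <- runif(n) < 0.05
  vals <- ifelse(bad, 999, runif(n, 0.5, 3))
  recs <- rbindlist(lapply(vals, function(v) lab_rec(value = v)))
  fr <- apply_plausibility_filter(
    standardize_units(match_lab_records(recs, cfg), cfg), cfg)
  n_rej <- nrow(attr(fr, "audit")$rejected)
  ci <- binom_ci_exact(n_rej, n)
  expect_gte(0.05, ci["lower"]); expect_lte(0.05, ci["upper"])
})

test_that("daily extremes: singleton, min/max, two facilities, order invariance", {
  days <- rbindlist(list(day_grid(), day_grid(fid = "F2", ssh = "S2")))
  recs <- rbindlist(list(
    lab_rec(value = 3.1, when = "2014-02-02 06:00:00"),
    lab_rec(value = 2.8, when = "2014-02-02 12:00:00"),
    lab_rec(value = 4.0, when = "2014-02-02 18:00:00"),
    lab_rec(value = 1.0, when = "2014-02-03 06:00:00"),
    lab_rec(fid = "F2", value = 2.0, when = "2014-02-03 08:00:00")))
  p <- aggregate_daily_extremes(
    apply_plausibility_filter(standardize_units(match_lab_records(recs, cfg), cfg), cfg),
    days)
  d2 <- p[date == as.Date("2014-02-02")]
  expect_equal(d2$low, 2.8); expect_equal(d2$high, 4.0); expect_equal(d2$n_obs, 3L)
  d3 <- p[date == as.Date("2014-02-03")]
  expect_equal(nrow(d3), 2L)  # same-day values at two facilities: two rows
  single <- d3[facility_id == "F1"]
  expect_equal(single$low, single$high)

  # order invariance
  p2 <- aggregate_daily_extremes(
    apply_plausibility_filter(standardize_units(
      match_lab_records(recs[sample(.N, .N)], cfg), cfg), cfg), days)
  setkey(p, patient_id, facility_id, date, test_id)
  setkey(p2, patient_id, facility_id, date, test_id)
  expect_equal(p, p2)
})

test_that("records outside the day grid are reported as orphans", {
  days <- day_grid(from = "2014-02-01", to = "2014-02-03")
  recs <- rbindlist(list(lab_rec(when = "2014-02-02 06:00:00"),
                         lab_rec(when = "2014-06-01 06:00:00")))
  p <- aggregate_daily_extremes(
    standardize_units(match_lab_records(recs, cfg), cfg), days)
  expect_equal(nrow(p), 1L)
  expect_equal(nrow(attr(p, "audit")$orphans), 1L)
})

test_that("harmonization is idempotent on already-canonical data", {
  recs <- rbindlist(lapply(c(0.9, 1.4), function(v) lab_rec(value = v)))
  once <- standardize_units(match_lab_records(recs, cfg), cfg)
  twice <- standardize_units(once, cfg)
  expect_equal(twice$value, once$value)
  expect_equal(twice$unit, once$unit)
})

test_that("vitals match by type only and MAP derives from paired cuff readings", {
  vit <- data.table(
    patient_id = "P1", facility_id = "F1",
    vital_type = c("SYSTOLIC BP", "DIASTOLIC BP", "TEMPERATURE", "NONSENSE"),
    value = c(120, 60, 98.6, 1),
    unit = c("mmHg", "mmHg", "F", ""),
    taken_at = as.POSIXct("2014-02-01 07:00:00", tz = "UTC"))
  m <- match_vital_records(vit, cfg)
  expect_equal(nrow(attr(m, "audit")$unmatched), 1L)
  map <- m[test_id == "map"]
  expect_equal(nrow(map), 1L)
  expect_equal(map$value, (2 * 60 + 120) / 3)   # 80 mmHg
  expect_equal(map$match_path, "derived")
  s <- standardize_units(m, cfg, "vitals")
  expect_equal(s[test_id == "temperature", value], 37.0, tolerance = 1e-9)

  # a directly recorded MAP at the same timestamp suppresses derivation
  vit2 <- rbindlist(list(vit[1:2], data.table(
    patient_id = "P1", facility_id = "F1", vital_type = "MAP", value = 77,
    unit = "mmHg", taken_at = vit$taken_at[1])))
  m2 <- match_vital_records(vit2, cfg)
  expect_equal(nrow(m2[test_id == "map"]), 1L)
  expect_equal(m2[test_id == "map", value], 77)
})

test_that("blood-culture events are extracted by LOINC or name with topography", {
  labs <- rbindlist(list(
    lab_rec(name = "BLOOD CULTURE", loinc = "600-7", topo = "BLOOD",
            value = NA, unit = ""),
    lab_rec(name = "Blood cx x2", loinc = "", topo = "BLOOD",
            value = NA, unit = "", when = "2014-02-03 05:00:00"),
    lab_rec(name = "URINE CULTURE", loinc = "", topo = "URINE",
            value = NA, unit = "")))
  bc <- extract_blood_cultures(labs, cfg)
  expect_equal(nrow(bc), 2L)
})
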