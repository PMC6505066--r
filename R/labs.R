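# Laboratory and vital-sign harmonization: dual LOINC/name matching,
# unit standardization, plausibility filtering, daily high/low aggregation.

#' Match laboratory records to standard tests
#'
#' A record matches test T when its LOINC is in T's LOINC set OR its local
#' name contains (case-insensitive substring) one of T's synonym patterns,
#' AND its topography passes T's filter (blank topography passes). Records
#' matching two different tests are routed to a conflict report and excluded;
#' records matched by name despite a blank LOINC are counted separately,
#' capturing tests missed or misclassified by LOINC coding.
#'
#' @param labs Lab record table (`patient_id, facility_id, local_name, loinc,
#'   topography, value, unit, drawn_at`; `facility_lab_code` optional).
#' @param config Test definitions from [load_lab_config()].
#' @return Matched records with `test_id` and `match_path` ("loinc" or
#'   "name") columns. Attribute `"audit"` holds `unmatched`, `conflicts`, and
#'   `match_path_counts`. Conservation: matched + unmatched + conflicted =
#'   input rows.
#' @export
match_lab_records <- function(labs, config = load_lab_config()) {
  x <- as.data.table(labs)
  need <- c("patient_id", "facility_id", "local_name", "loinc", "topography",
            "value", "unit", "drawn_at")
  if (!all(need %in% names(x)))
    pd_stop(paste("lab table must have columns:", paste(need, collapse = ", ")),
            "pd_input_error")
  x <- copy(x)
  x[, value := as.numeric(value)]
  lo <- tolower(trimws(fifelse(is.na(x$local_name), "", as.character(x$local_name))))
  lc <- trimws(fifelse(is.na(x$loinc), "", as.character(x$loinc)))
  topo <- tolower(trimws(fifelse(is.na(x$topography), "", as.character(x$topography))))

  hits <- list()
  for (tid in names(config$labs)) {
    t <- config$labs[[tid]]
    topo_ok <- topo == "" | topo %in% tolower(unlist(t$topography_filter))
    by_loinc <- lc != "" & lc %in% unlist(t$loinc_set)
    by_name <- rep(FALSE, nrow(x))
    # case-insensitive fixed substring over the curated pattern list;
    # auditability beats cleverness here (no fuzzy matching)
    for (p in tolower(unlist(t$name_patterns)))
      by_name <- by_name | grepl(p, lo, fixed = TRUE)
    m <- which((by_loinc | by_name) & topo_ok)
    if (length(m) > 0L)
      hits[[tid]] <- data.table(row = m, test_id = tid,
                                match_path = fifelse(by_loinc[m], "loinc", "name"))
  }
  hh <- if (length(hits)) rbindlist(hits) else
    data.table(row = integer(), test_id = character(), match_path = character())
  n_tests <- hh[, .(n_matches = data.table::uniqueN(test_id)), by = row]
  conflict_rows <- n_tests[n_matches > 1L, row]
  ok <- hh[!row %in% conflict_rows]
  # one record can match one test via both paths; keep LOINC as primary path
  ok <- ok[order(row, match_path)][, .SD[1L], by = .(row, test_id)]
  out <- x[ok$row]
  out[, test_id := ok$test_id]
  out[, match_path := ok$match_path]
  matched_rows <- unique(ok$row)
  unmatched <- x[setdiff(seq_len(nrow(x)), c(matched_rows, conflict_rows))]
  audit <- list(
    unmatched = unmatched,
    conflicts = x[conflict_rows],
    match_path_counts = out[, .N, by = .(test_id, match_path)],
    name_only_blank_loinc = out[match_path == "name" & (is.na(loinc) | trimws(loinc) == ""), .N]
  )
  stopifnot(nrow(out) + nrow(unmatched) + length(conflict_rows) == nrow(x))
  setattr(out, "audit", audit)
  out[]
}

#' Convert a value to a test's canonical unit
#'
#' Linear conversion (`canonical = slope * value + intercept`) per the test's
#' conversion table; identity when already canonical. Unknown units yield NA
#' (callers flag the record "unconvertible").
#'
#' @param value Numeric vector.
#' @param unit Character vector of reported units (recycled).
#' @param test A single test definition (element of `config$labs`/`$vitals`).
#' @return Numeric vector in the canonical unit; NA where unconvertible.
#' @export
convert_units <- function(value, unit, test) {
  conv <- test$conversions
  unit <- fifelse(is.na(unit), "", trimws(as.character(unit)))
  out <- rep(NA_real_, length(value))
  for (u in names(conv)) {
    sel <- unit == u
    if (any(sel)) out[sel] <- conv[[u]][1] * value[sel] + conv[[u]][2]
  }
  out
}

#' Standardize units across a matched record table
#'
#' @param records Output of [match_lab_records()] (or matched vitals).
#' @param config Test definitions.
#' @param group `"labs"` or `"vitals"`.
#' @return Records with `value` in canonical units and a `unit` column set to
#'   the canonical unit; unconvertible records excluded and reported in
#'   attribute `"audit"$unconvertible`.
#' @export
standardize_units <- function(records, config = load_lab_config(), group = "labs") {
  x <- copy(as.data.table(records))
  if (nrow(x) == 0L) { setattr(x, "audit", list(unconvertible = x)); return(x[]) }
  defs <- config[[group]]
  x[, value := {
    t <- defs[[.BY$test_id]]
    convert_units(value, unit, t)
  }, by = test_id]
  bad <- x[is.na(value)]
  x <- x[!is.na(value)]
  x[, unit := vapply(test_id, function(tid) defs[[tid]]$canonical_unit, character(1))]
  setattr(x, "audit", list(unconvertible = bad))
  x[]
}

#' Remove physiologically implausible values
#'
#' Values outside each test's plausible range are removed and reported with
#' counts per facility and test, supporting the clinician-review loop over
#' per-facility value distributions.
#'
#' @param records Canonical-unit records with `test_id`.
#' @param config Test definitions.
#' @param group `"labs"` or `"vitals"`.
#' @return Kept records; attribute `"audit"` carries `rejected` rows and
#'   `rejected_counts` per (facility, test).
#' @export
apply_plausibility_filter <- function(records, config = load_lab_config(),
                                      group = "labs") {
  x <- copy(as.data.table(records))
  if (nrow(x) == 0L) {
    setattr(x, "audit", list(rejected = x, rejected_counts = data.table()))
    return(x[])
  }
  defs <- config[[group]]
  rng <- rbindlist(lapply(names(defs), function(tid)
    data.table(test_id = tid, lo = defs[[tid]]$plausible_range[1],
               hi = defs[[tid]]$plausible_range[2])))
  x[rng, on = "test_id", keep := value >= lo & value <= hi]
  rejected <- x[keep == FALSE | is.na(keep)][, keep := NULL]
  kept <- x[keep == TRUE][, keep := NULL]
  setattr(kept, "audit",
          list(rejected = rejected,
               rejected_counts = rejected[, .N, by = .(facility_id, test_id)]))
  kept[]
}

#' Match vital-sign records to the six standard vitals
#'
#' Vitals are matched only on the vital-type field, never by free text. Mean
#' arterial pressure is taken directly when recorded; otherwise it is derived
#' as (2 x diastolic + systolic) / 3 from cuff readings paired on the same
#' patient, facility and timestamp.
#'
#' @param vitals Vital record table (`patient_id, facility_id, vital_type,
#'   value, unit, taken_at`).
#' @param config Test definitions.
#' @return Matched records with `test_id`, including derived MAP rows
#'   (`match_path` = "derived"); attribute `"audit"$unmatched`.
#' @export
match_vital_records <- function(vitals, config = load_lab_config()) {
  x <- as.data.table(vitals)
  need <- c("patient_id", "facility_id", "vital_type", "value", "taken_at")
  if (!all(need %in% names(x)))
    pd_stop(paste("vitals table must have columns:", paste(need, collapse = ", ")),
            "pd_input_error")
  x <- copy(x)
  if (!"unit" %in% names(x)) x[, unit := NA_character_]
  x[, value := as.numeric(value)]
  vt <- toupper(trimws(as.character(x$vital_type)))
  x[, test_id := NA_character_]
  for (tid in names(config$vitals))
    x[vt %in% toupper(unlist(config$vitals[[tid]]$vital_types)), test_id := tid]
  unmatched <- x[is.na(test_id)]
  out <- x[!is.na(test_id)]
  out[, match_path := "type"]
  # default unit = canonical when unrecorded
  out[, unit := {
    cu <- config$vitals[[.BY$test_id]]$canonical_unit
    fifelse(is.na(unit) | trimws(unit) == "", cu, unit)
  }, by = test_id]
  # derive MAP where no direct MAP reading shares the timestamp
  sbp <- out[test_id == "systolic_bp"]
  dbp <- out[test_id == "diastolic_bp"]
  if (nrow(sbp) > 0L && nrow(dbp) > 0L) {
    key <- c("patient_id", "facility_id", "taken_at")
    pairs <- sbp[dbp, on = key, nomatch = NULL,
                 .(patient_id, facility_id, taken_at,
                   value = (2 * i.value + x.value) / 3)]
    direct <- out[test_id == "map", .(patient_id, facility_id, taken_at)]
    pairs <- pairs[!direct, on = key]
    if (nrow(pairs) > 0L) {
      pairs[, `:=`(vital_type = "MAP", test_id = "map", match_path = "derived",
                   unit = config$vitals$map$canonical_unit)]
      out <- rbindlist(list(out, pairs), use.names = TRUE, fill = TRUE)
    }
  }
  setattr(out, "audit", list(unmatched = unmatched))
  out[]
}

#' Aggregate matched records to daily high/low values
#'
#' For each (patient, facility, calendar date, test): low = minimum, high =
#' maximum over that day at that facility; same-day measurements at two
#' facilities aggregate into two separate rows. Records on days with no
#' corresponding patient-facility-day row are reported as orphans and
#' excluded.
#'
#' @param records Matched, converted, filtered records; the datetime column
#'   may be `drawn_at` or `taken_at`.
#' @param days PatientFacilityDay table from [expand_patient_facility_days()].
#' @return Long `data.table` (`patient_id, facility_id, date, test_id, low,
#'   high, n_obs`); attribute `"audit"$orphans`.
#' @export
aggregate_daily_extremes <- function(records, days) {
  x <- copy(as.data.table(records))
  dcol <- intersect(c("drawn_at", "taken_at"), names(x))[1]
  if (is.na(dcol)) pd_stop("records need a drawn_at or taken_at column", "pd_input_error")
  if (nrow(x) == 0L) {
    out <- data.table(patient_id = character(), facility_id = character(),
                      date = as.Date(character()), test_id = character(),
                      low = numeric(), high = numeric(), n_obs = integer())
    setattr(out, "audit", list(orphans = x))
    return(out[])
  }
  x[, date := pd_date(pd_parse_datetime(get(dcol)))]
  keys <- as.data.table(days)[, .(patient_id, facility_id, date)]
  x[, keep := FALSE]
  x[keys, on = .(patient_id, facility_id, date), keep := TRUE]
  orphans <- x[keep == FALSE][, keep := NULL]
  x <- x[keep == TRUE]
  out <- x[, .(low = min(value), high = max(value), n_obs = .N),
           by = .(patient_id, facility_id, date, test_id)]
  setorder(out, patient_id, facility_id, date, test_id)
  stopifnot(all(out$low <= out$high))
  setattr(out, "audit", list(orphans = orphans))
  out[]
}

#' Pivot daily physiology to one row per patient-facility-day
#'
#' @param phys Long output of [aggregate_daily_extremes()].
#' @return Wide `data.table` with `<test>_low` / `<test>_high` columns.
#' @export
daily_physiology_wide <- function(phys) {
  if (nrow(phys) == 0L)
    return(data.table(patient_id = character(), facility_id = character(),
                      date = as.Date(character())))
  w <- data.table::dcast(as.data.table(phys),
                         patient_id + facility_id + date ~ test_id,
                         value.var = c("low", "high"))
  # dcast names low_<test>; flip to <test>_low for readability
  old <- setdiff(names(w), c("patient_id", "facility_id", "date"))
  setnames(w, old, sub("^(low|high)_(.*)$", "\\2_\\1", old))
  w[]
}

#' Extract blood-culture collection events from raw lab records
#'
#' Blood cultures anchor the Adult Sepsis Event infection window. Matching
#' uses the `events$blood_culture` entry of the test config (LOINC set or
#' name patterns, blood topography).
#'
#' @param labs Raw lab record table.
#' @param config Test definitions.
#' @return `data.table(patient_id, facility_id, date)` of culture-draw days.
#' @export
extract_blood_cultures <- function(labs, config = load_lab_config()) {
  x <- as.data.table(labs)
  if (nrow(x) == 0L)
    return(data.table(patient_id = character(), facility_id = character(),
                      date = as.Date(character())))
  ev <- config$events$blood_culture
  lo <- tolower(fifelse(is.na(x$local_name), "", as.character(x$local_name)))
  lc <- trimws(fifelse(is.na(x$loinc), "", as.character(x$loinc)))
  hit <- lc %in% unlist(ev$loinc_set)
  for (p in tolower(unlist(ev$name_patterns))) hit <- hit | grepl(p, lo, fixed = TRUE)
  topo <- tolower(trimws(fifelse(is.na(x$topography), "", as.character(x$topography))))
  hit <- hit & (topo == "" | topo %in% tolower(unlist(ev$topography_filter)))
  out <- x[hit, .(patient_id, facility_id,
                  date = pd_date(pd_parse_datetime(drawn_at)))]
  unique(out)
}
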