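# Episode construction: specialty stay -> bedded stay -> single-site
# hospitalization (SSH) -> acute hospitalization -> episode of care, and the
# patient-facility-day expansion that is the database grain.

#' Classify treating-specialty codes as acute/non-acute and ICU/non-ICU
#'
#' Deterministic lookup against the specialty code-list. Unknown codes fall
#' back to the configured default and trigger one warning naming them.
#'
#' @param specialty_code Character vector of specialty codes.
#' @param map Specialty map from [load_specialty_map()].
#' @param default_acute,default_icu Classification for unregistered codes.
#' @return A `data.table` with columns `specialty_code, acute, icu`, one row
#'   per input element (in input order).
#' @export
classify_specialty <- function(specialty_code,
                               map = load_specialty_map(),
                               default_acute = FALSE, default_icu = FALSE) {
  key <- toupper(trimws(specialty_code))
  idx <- match(key, map$specialty_code)
  unknown <- unique(key[is.na(idx)])
  if (length(unknown) > 0L)
    warning(sprintf("unregistered specialty code(s) classified by default: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  data.table(specialty_code = specialty_code,
             acute = fifelse(is.na(idx), default_acute, map$acute[idx]),
             icu   = fifelse(is.na(idx), default_icu, map$icu[idx]))
}

# Annotate and order a raw specialty-transfer table; resolves same-facility
# overlaps by truncating the earlier stay at the later stay's admission
# (preserves the partition invariant). Truncations are recorded in the
# "audit" attribute.
#' @noRd
prepare_stays <- function(stays, map, default_acute = FALSE, default_icu = FALSE) {
  s <- as.data.table(stays)
  need <- c("patient_id", "facility_id", "specialty_code", "admit", "discharge")
  if (!all(need %in% names(s)))
    pd_stop(paste("specialty-transfer table must have columns:",
                  paste(need, collapse = ", ")), "pd_input_error")
  s <- copy(s)
  s[, admit := pd_parse_datetime(admit)]
  s[, discharge := pd_parse_datetime(discharge)]
  if (any(!is.na(s$discharge) & s$discharge < s$admit))
    pd_stop("stay with discharge before admit", "pd_input_error")
  cls <- classify_specialty(s$specialty_code, map,
                            default_acute = default_acute,
                            default_icu = default_icu)
  s[, acute := cls$acute]
  s[, icu := cls$icu]
  setorder(s, patient_id, facility_id, admit, discharge, na.last = TRUE)
  s[, stay_id := seq_len(.N)]
  # truncate overlapping stays at one facility
  audit <- list()
  s[, `:=`(admit_date = pd_date(admit), discharge_date = pd_date(discharge))]
  prev_end <- s[, shift(discharge)]
  same_grp <- s[, patient_id == shift(patient_id) & facility_id == shift(facility_id)]
  overlap <- which(!is.na(same_grp) & same_grp & !is.na(prev_end) & s$admit < prev_end)
  if (length(overlap) > 0L) {
    audit$overlap_truncated <- s[overlap - 1L, .(patient_id, facility_id, stay_id, admit, discharge)]
    for (i in overlap) {
      data.table::set(s, i - 1L, "discharge", s$admit[i])
      data.table::set(s, i - 1L, "discharge_date", pd_date(s$admit[i]))
    }
  }
  setattr(s, "audit", audit)
  s[]
}

# Gap-join grouping: within groups defined by `by`, stays (sorted by admit)
# are chained while each successor's admit date is <= the running maximum
# discharge date + gap_days. Censored (open) intervals hold the chain open.
# break_col, when given, additionally breaks the chain whenever that column
# changes (bedded stays break at specialty transfers).
#' @noRd
chain_intervals <- function(x, by, gap_days = 1L, break_col = NULL) {
  stopifnot(all(c("admit_date", "discharge_date") %in% names(x)))
  x <- copy(x)
  setorderv(x, c(by, "admit_date", "discharge_date"), na.last = TRUE)
  x[, grp := {
    end_num <- fifelse(is.na(discharge_date), Inf, as.numeric(discharge_date))
    run_end <- shift(cummax(end_num))
    brk <- is.na(run_end) | as.numeric(admit_date) > run_end + gap_days
    if (!is.null(break_col))
      brk <- brk | get(break_col) != shift(get(break_col), fill = "\r")
    cumsum(brk)
  }, by = by]
  x[]
}

#' Group specialty stays into bedded stays
#'
#' A bedded stay is a maximal run of temporally contiguous specialty-stay
#' records for one patient at one facility under a single treating
#' specialty: consecutive records with the same specialty merge (one bedded
#' stay composed of several specialty-stay records), while a specialty
#' transfer — MICU to ward, ward to nursing home — starts a new bedded stay
#' even at the same facility. Contiguity: the successor's admission date is
#' at most `gap_days` after the running latest discharge date.
#'
#' @param stays Specialty-transfer table (`patient_id, facility_id,
#'   specialty_code, admit, discharge`).
#' @param map Specialty map ([load_specialty_map()]).
#' @param gap_days Contiguity tolerance in calendar days (default 1).
#' @param default_acute,default_icu Defaults for unregistered codes.
#' @return `data.table` of bedded stays (`bedded_id, patient_id, facility_id,
#'   admit_date, discharge_date, n_stays`) with the annotated member stays in
#'   attribute `"member_stays"` (column `bedded_id`).
#' @export
build_bedded_stays <- function(stays, map = load_specialty_map(), gap_days = 1L,
                               default_acute = FALSE, default_icu = FALSE) {
  s <- prepare_stays(stays, map, default_acute, default_icu)
  if (nrow(s) == 0L)
    return(empty_group_table("bedded_id"))
  s <- chain_intervals(s, by = c("patient_id", "facility_id"),
                       gap_days = gap_days, break_col = "specialty_code")
  s[, bedded_id := .GRP, by = .(patient_id, facility_id, grp)]
  out <- s[, .(patient_id = patient_id[1L], facility_id = facility_id[1L],
               admit_date = min(admit_date),
               discharge_date = if (anyNA(discharge_date)) as.Date(NA) else max(discharge_date),
               censored = anyNA(discharge_date),
               n_stays = .N),
           by = bedded_id]
  out[, bedded_id := sprintf("B%05d", bedded_id)]
  s[, bedded_id := sprintf("B%05d", bedded_id)]
  s[, grp := NULL]
  setorder(out, patient_id, admit_date, facility_id)
  setattr(out, "member_stays", s[])
  out[]
}

#' @noRd
empty_group_table <- function(id_col) {
  out <- data.table(id = character(), patient_id = character(),
                    facility_id = character(), admit_date = as.Date(character()),
                    discharge_date = as.Date(character()), censored = logical(),
                    n_stays = integer())
  setnames(out, "id", id_col)
  setattr(out, "member_stays", data.table())
  out[]
}

#' Build single-site hospitalizations (SSHs)
#'
#' An SSH is one or more consecutive acute specialty stays at a single
#' facility: non-acute stays are dropped before grouping, so an acute run
#' interrupted by a nursing/domiciliary stay splits into two SSHs.
#'
#' @inheritParams build_bedded_stays
#' @return `data.table` of SSHs (`ssh_id, patient_id, facility_id, admit_date,
#'   discharge_date, censored, died_in_hospital, n_stays`) with member acute
#'   stays in attribute `"member_stays"`. `died_in_hospital` is TRUE when the
#'   final acute stay carries a `disposition` of "DIED" (if the input has a
#'   disposition column; otherwise NA, and [compute_outcomes()] derives it
#'   from the death-date table).
#' @export
build_single_site_hospitalizations <- function(stays, map = load_specialty_map(),
                                               gap_days = 1L,
                                               default_acute = FALSE,
                                               default_icu = FALSE) {
  s <- prepare_stays(stays, map, default_acute, default_icu)
  s <- s[acute == TRUE]
  if (nrow(s) == 0L) {
    out <- empty_group_table("ssh_id")
    out[, died_in_hospital := logical()]
    return(out[])
  }
  s <- chain_intervals(s, by = c("patient_id", "facility_id"), gap_days = gap_days)
  s[, ssh_id := .GRP, by = .(patient_id, facility_id, grp)]
  has_dispo <- "disposition" %in% names(s)
  out <- s[, {
    last <- which.max(as.numeric(fifelse(is.na(discharge_date), admit_date, discharge_date)))
    .(patient_id = patient_id[1L], facility_id = facility_id[1L],
      admit_date = min(admit_date),
      discharge_date = if (anyNA(discharge_date)) as.Date(NA) else max(discharge_date),
      censored = anyNA(discharge_date),
      died_in_hospital = if (has_dispo) identical(toupper(disposition[last]), "DIED") else NA,
      n_stays = .N)
  }, by = ssh_id]
  out[, ssh_id := sprintf("S%06d", ssh_id)]
  s[, ssh_id := sprintf("S%06d", ssh_id)]
  s[, grp := NULL]
  setorder(out, patient_id, admit_date, facility_id)
  setattr(out, "member_stays", s[])
  if (any(out$censored))
    warning(sprintf("%d SSH(s) censored at end of observation (missing discharge)",
                    sum(out$censored)), call. = FALSE)
  out[]
}

# Shared chaining of unit intervals (SSHs or bedded stays) per patient.
#' @noRd
link_units <- function(units, unit_id, out_id, gap_days, label_fmt) {
  u <- copy(as.data.table(units))
  if (nrow(u) == 0L) {
    out <- data.table(id = character(), patient_id = character(),
                      admit_date = as.Date(character()),
                      discharge_date = as.Date(character()),
                      n_units = integer(), unit_ids = list())
    setnames(out, "id", out_id)
    return(out[])
  }
  u <- chain_intervals(u, by = "patient_id", gap_days = gap_days)
  u[, (out_id) := .GRP, by = .(patient_id, grp)]
  out <- u[, .(patient_id = patient_id[1L],
               admit_date = min(admit_date),
               discharge_date = if (anyNA(discharge_date)) as.Date(NA) else max(discharge_date),
               n_units = .N,
               unit_ids = list(get(unit_id))),
           by = out_id]
  out[, (out_id) := sprintf(label_fmt, get(out_id))]
  setorder(out, patient_id, admit_date)
  out[]
}

#' Chain SSHs into acute hospitalizations
#'
#' Successive SSHs of one patient (typically at different facilities — an
#' inter-facility transfer) are chained when the next admission date is at
#' most `gap_days` after the previous discharge date; chains are maximal.
#'
#' @param sshs SSH table from [build_single_site_hospitalizations()].
#' @param gap_days Transfer-gap tolerance in calendar days (default 1).
#' @return `data.table` of acute hospitalizations (`hosp_id, patient_id,
#'   admit_date, discharge_date, n_units, unit_ids`).
#' @export
link_acute_hospitalizations <- function(sshs, gap_days = 1L) {
  link_units(sshs, "ssh_id", "hosp_id", gap_days, "H%06d")
}

#' Chain bedded stays into episodes of care
#'
#' Same chaining rule as [link_acute_hospitalizations()] but over bedded
#' stays of any treating specialty, so non-acute tails (nursing home,
#' domiciliary) extend the episode.
#'
#' @param bedded Bedded-stay table from [build_bedded_stays()].
#' @param gap_days Transfer-gap tolerance in calendar days (default 1).
#' @return `data.table` of episodes (`episode_id, patient_id, admit_date,
#'   discharge_date, n_units, unit_ids`).
#' @export
build_episodes_of_care <- function(bedded, gap_days = 1L) {
  link_units(bedded, "bedded_id", "episode_id", gap_days, "E%06d")
}

#' Expand SSHs to patient-facility-day rows
#'
#' One row per calendar date per facility per SSH, inclusive of both the
#' admission and discharge dates (a same-day admit/discharge yields one row).
#' A same-day inter-facility transfer yields one row per facility. `icu_day`
#' is TRUE when any ICU specialty stay overlaps that date at that facility —
#' the patient spent some time in an ICU on that calendar day.
#'
#' @param sshs SSH table from [build_single_site_hospitalizations()].
#' @param stays Annotated member stays; defaults to `attr(sshs, "member_stays")`.
#' @param cutoff Expansion end for censored SSHs (default: their last known
#'   admit/discharge date).
#' @return `data.table` with one row per (`patient_id, facility_id, date`):
#'   columns `ssh_id, patient_id, facility_id, date, day_number, icu_day`.
#' @export
expand_patient_facility_days <- function(sshs,
                                         stays = attr(sshs, "member_stays"),
                                         cutoff = NULL) {
  sshs <- as.data.table(sshs)
  if (nrow(sshs) == 0L)
    return(data.table(ssh_id = character(), patient_id = character(),
                      facility_id = character(), date = as.Date(character()),
                      day_number = integer(), icu_day = logical()))
  s <- copy(sshs)
  if (anyNA(s$discharge_date)) {
    st <- as.data.table(stays)
    last_known <- st[, .(last_seen = max(fifelse(is.na(discharge_date),
                                                 admit_date, discharge_date))),
                     by = ssh_id]
    s[last_known, on = "ssh_id",
      discharge_date := fifelse(is.na(discharge_date),
                                if (is.null(cutoff)) i.last_seen
                                else pmax(i.last_seen, pd_date(cutoff)),
                                discharge_date)]
  }
  days <- s[, .(date = seq(admit_date, discharge_date, by = "day")),
            by = .(ssh_id, patient_id, facility_id)]
  days[, day_number := seq_len(.N), by = ssh_id]
  # ICU flag: any ICU member stay whose [admit_date, discharge_date] covers the date
  icu_stays <- as.data.table(stays)[icu == TRUE]
  days[, icu_day := FALSE]
  if (nrow(icu_stays) > 0L) {
    icu_stays <- copy(icu_stays)
    icu_stays[, discharge_date := fifelse(is.na(discharge_date), admit_date, discharge_date)]
    days[icu_stays,
         on = .(patient_id, facility_id, date >= admit_date, date <= discharge_date),
         icu_day := TRUE]
  }
  stopifnot(!anyDuplicated(days[, .(patient_id, facility_id, date)]))
  setorder(days, patient_id, date, facility_id)
  days[]
}

#' Compute hospitalization-level outcomes per SSH
#'
#' In-hospital mortality: death on or before the SSH discharge date (and on
#' or after admission). 30-day mortality: death within 30 days counted from
#' the admission date. 30-day readmission: next SSH admission (any facility)
#' within 30 days of discharge, defined only for live, uncensored discharges
#' (NA otherwise) — died-in-hospital SSHs are excluded from the readmission
#' denominator.
#'
#' @param sshs SSH table.
#' @param deaths Optional `data.table(patient_id, death_date)`; one row per
#'   deceased patient.
#' @return `data.table` per SSH: `ssh_id, patient_id, los_days,
#'   in_hospital_mortality, mortality_30d, readmit_30d`.
#' @export
compute_outcomes <- function(sshs, deaths = NULL) {
  s <- copy(as.data.table(sshs))
  if (is.null(deaths) || nrow(as.data.table(deaths)) == 0L) {
    deaths <- data.table(patient_id = character(), death_date = as.Date(character()))
  } else {
    deaths <- as.data.table(deaths)
    deaths[, death_date := pd_date(death_date)]
    if (anyDuplicated(deaths$patient_id))
      pd_stop("multiple death dates for one patient", "pd_input_error")
  }
  s[deaths, on = "patient_id", death_date := i.death_date]
  if (!"death_date" %in% names(s)) s[, death_date := as.Date(NA)]
  bad <- s[!is.na(death_date) & death_date < admit_date]
  if (nrow(bad) > 0L)
    pd_stop(sprintf("death date precedes admission for: %s",
                    paste(unique(bad$patient_id), collapse = ", ")),
            "pd_input_error")
  s[, in_hospital_mortality := !is.na(death_date) & !censored & death_date <= discharge_date]
  s[, mortality_30d := !is.na(death_date) & death_date <= admit_date + 30L]
  s[, los_days := fifelse(censored, NA_integer_,
                          as.integer(discharge_date - admit_date))]
  setorder(s, patient_id, admit_date)
  s[, readmit_30d := {
    nxt <- shift(admit_date, type = "lead")
    fifelse(in_hospital_mortality | censored, NA,
            !is.na(nxt) & nxt <= discharge_date + 30L)
  }, by = patient_id]
  s[, .(ssh_id, patient_id, admit_date, discharge_date, los_days,
        in_hospital_mortality, mortality_30d, readmit_30d)]
}
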