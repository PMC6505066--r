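# Synthetic CDW-style raw tables with controlled ground truth: known
# hospitalization structure, sepsis prevalence and coding messiness, so the
# whole pipeline is testable without access to protected clinical data.

#' Build and validate a synthetic-cohort configuration
#'
#' Defaults are the published stated world of the source system: median
#' length of stay 4 days (log-normal, rounded to whole days, minimum 1),
#' in-hospital mortality 1.7%, 30-day mortality 4.4%, 30-day readmission
#' 15.3%, sepsis prevalence 4.8% of hospitalizations, and ICU exposure near
#' 14% of patient-days. Inter-facility transfer frequency is not published;
#' `transfer_prob` defaults to 0.05.
#'
#' @param n_patients,n_facilities Positive counts.
#' @param date_range Closed calendar interval `c(start, end)` (>= 60 days).
#' @param transfer_prob Probability a hospitalization transfers between
#'   facilities (same-day transfer, two SSHs).
#' @param icu_prob Probability a hospitalization starts with an ICU segment.
#' @param nonacute_tail_prob Probability a nursing-home (CLC) stay is
#'   appended after acute discharge.
#' @param sepsis_prevalence Probability per hospitalization of true sepsis.
#' @param lab_name_variant_rate Probability a lab record uses a
#'   facility-local name variant instead of the canonical name
#'   (applied by [inject_messiness()]).
#' @param missing_loinc_rate Probability a lab record's LOINC is blanked
#'   (applied by [inject_messiness()]).
#' @param readmit_prob Probability of a second hospitalization within 30
#'   days of live discharge.
#' @param mortality_inhosp,mortality_30d In-hospital and 30-day (from
#'   admission) death probabilities per hospitalization.
#' @param los_meanlog,los_sdlog Log-normal stay-duration parameters
#'   (`meanlog = log(4)` puts the median at 4 days).
#' @param seed Integer RNG seed; identical config + seed reproduces
#'   byte-identical tables.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 100, n_facilities = 6,
                          date_range = c("2014-01-01", "2014-12-31"),
                          transfer_prob = 0.05, icu_prob = 0.22,
                          nonacute_tail_prob = 0.10,
                          sepsis_prevalence = 0.048,
                          lab_name_variant_rate = 0, missing_loinc_rate = 0,
                          readmit_prob = 0.153,
                          mortality_inhosp = 0.017, mortality_30d = 0.044,
                          los_meanlog = log(4), los_sdlog = 0.6,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_facilities = as.integer(n_facilities),
              date_range = as.Date(date_range),
              transfer_prob = transfer_prob, icu_prob = icu_prob,
              nonacute_tail_prob = nonacute_tail_prob,
              sepsis_prevalence = sepsis_prevalence,
              lab_name_variant_rate = lab_name_variant_rate,
              missing_loinc_rate = missing_loinc_rate,
              readmit_prob = readmit_prob,
              mortality_inhosp = mortality_inhosp,
              mortality_30d = mortality_30d,
              los_meanlog = los_meanlog, los_sdlog = los_sdlog,
              seed = as.integer(seed))
  probs <- c("transfer_prob", "icu_prob", "nonacute_tail_prob",
             "sepsis_prevalence", "lab_name_variant_rate",
             "missing_loinc_rate", "readmit_prob", "mortality_inhosp",
             "mortality_30d")
  for (p in probs)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      pd_stop(sprintf("%s must be a probability in [0, 1]", p), "pd_config_error")
  if (cfg$n_patients < 1L || cfg$n_facilities < 1L)
    pd_stop("n_patients and n_facilities must be positive", "pd_config_error")
  if (anyNA(cfg$date_range) || length(cfg$date_range) != 2L ||
      diff(as.numeric(cfg$date_range)) < 60)
    pd_stop("date_range must be a nonempty interval of at least 60 days",
            "pd_config_error")
  structure(cfg, class = "cohort_config")
}

# Facility-local name variants per canonical test; the first entry is the
# clean default. All variants stay inside the harmonizer's curated synonym
# patterns — messiness emulates heterogeneity, not unmappable data.
#' @noRd
lab_name_variants <- function() {
  list(
    creatinine = c("CREATININE", "CREAT", "Creatinine, serum"),
    platelets = c("PLATELET COUNT", "PLT", "Platelets (auto)"),
    bilirubin_total = c("TOTAL BILIRUBIN", "TBILI", "Bilirubin, total"),
    sodium = c("SODIUM", "Sodium, serum", "SODIUM (NA+)"),
    wbc = c("WHITE BLOOD CELL COUNT", "WBC", "Leukocyte count"),
    lactate = c("LACTATE", "Lactic acid", "LACTATE, PLASMA"),
    bun = c("UREA NITROGEN", "BUN", "Urea nitrogen, blood"),
    glucose = c("GLUCOSE", "Glucose, serum", "GLU")
  )
}

#' @noRd
lab_loinc_defaults <- function() {
  c(creatinine = "2160-0", platelets = "777-3", bilirubin_total = "1975-2",
    sodium = "2951-2", wbc = "6690-2", lactate = "2524-7", bun = "3094-0",
    glucose = "2345-7")
}

# Generator-owned SOFA truth tables, coded independently of
# sofa_component_scores() so end-to-end recovery is a real check.
#' @noRd
truth_sofa <- function(plate, bili, creat, map, pressor_tier) {
  coag <- ifelse(is.na(plate), NA_integer_,
                 ifelse(plate < 20, 4L, ifelse(plate < 50, 3L,
                        ifelse(plate < 100, 2L, ifelse(plate < 150, 1L, 0L)))))
  liver <- ifelse(is.na(bili), NA_integer_,
                  ifelse(bili >= 12, 4L, ifelse(bili >= 6, 3L,
                         ifelse(bili >= 2, 2L, ifelse(bili >= 1.2, 1L, 0L)))))
  renal <- ifelse(is.na(creat), NA_integer_,
                  ifelse(creat >= 5, 4L, ifelse(creat >= 3.5, 3L,
                         ifelse(creat >= 2, 2L, ifelse(creat >= 1.2, 1L, 0L)))))
  mt <- ifelse(is.na(map), NA_integer_, ifelse(map < 70, 1L, 0L))
  cv <- ifelse(!is.na(pressor_tier) & pressor_tier > 0L,
               pmax(mt, pressor_tier, na.rm = TRUE), mt)
  list(coag = coag, liver = liver, renal = renal, cv = as.integer(cv))
}

#' Generate a synthetic raw-table bundle with ground truth
#'
#' Emits the five CDW-style tables (specialty transfers, labs, vitals,
#' medication administrations, diagnosis/procedure codes), a death-date
#' table, and ground truth (true SSH boundaries and sepsis flags per
#' hospitalization; true daily SOFA components). Sepsis-positive
#' hospitalizations contain a blood-culture event, a qualifying systemic
#' antibiotic run, and at least one organ-dysfunction signal (vasopressor
#' initiation plus a lactate rise); their discharge diagnoses carry an
#' explicit severe-sepsis code. Output is deterministic in the config seed.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"raw_tables"` with elements
#'   `specialty_transfers, labs, vitals, med_admins, codes, deaths,
#'   ground_truth, ground_truth_days`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  facilities <- sprintf("F%03d", seq_len(config$n_facilities))
  d0 <- config$date_range[1]
  d1 <- config$date_range[2]
  # leave room for stays + tails + readmissions inside the range
  margin <- 55L
  icd10_era <- function(d) d >= as.Date("2015-10-01")

  st <- list(); lb <- list(); vt <- list(); md <- list(); cd <- list()
  gt <- list(); gtd <- list(); dth <- list()

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%06d", i)
    age <- min(100L, max(20L, as.integer(round(rnorm(1, 66, 13)))))
    sick <- runif(1) < 0.10   # chronically abnormal physiology
    n_hosp <- 1L + (runif(1) < config$readmit_prob)
    admit <- d0 + sample.int(max(1L, as.integer(d1 - d0) - margin), 1L)
    death_date <- as.Date(NA)

    for (h in seq_len(n_hosp)) {
      if (!is.na(death_date)) break
      sepsis <- runif(1) < config$sepsis_prevalence
      los <- max(1L, min(30L, as.integer(round(
        rlnorm(1, config$los_meanlog, config$los_sdlog)))))
      if (sepsis) los <- max(los, 6L)
      fac <- sample(facilities, 1L)
      transfer <- config$n_facilities > 1L && runif(1) < config$transfer_prob
      icu <- runif(1) < config$icu_prob || sepsis
      disch <- admit + los

      # --- hospitalization-level fates
      died_in <- runif(1) < config$mortality_inhosp
      died_30 <- !died_in &&
        runif(1) < max(0, (config$mortality_30d - config$mortality_inhosp) /
                         max(1e-9, 1 - config$mortality_inhosp))
      if (died_in) death_date <- disch
      if (died_30) death_date <- min(admit + sample(los:30, 1L), d1)
      if (!is.na(death_date) && death_date <= disch && !died_in) {
        died_in <- TRUE; death_date <- disch
      }

      # --- specialty stays (true SSH structure)
      seg <- list()  # per-facility acute segments: list(fac, from, to)
      if (transfer) {
        fac2 <- sample(setdiff(facilities, fac), 1L)
        cut <- admit + sample.int(max(1L, los - 1L), 1L)
        seg <- list(list(fac = fac, from = admit, to = cut),
                    list(fac = fac2, from = cut, to = disch))
      } else {
        seg <- list(list(fac = fac, from = admit, to = disch))
      }
      stays_h <- list()
      for (k in seq_along(seg)) {
        s <- seg[[k]]
        seg_los <- as.integer(s$to - s$from)
        icu_here <- icu && k == 1L
        if (icu_here && seg_los >= 1L) {
          icu_end <- s$from + min(seg_los, sample(1:3, 1L))
          stays_h[[length(stays_h) + 1L]] <- data.table(
            patient_id = pid, facility_id = s$fac, specialty_code = "MICU",
            admit = as.POSIXct(paste(s$from, "08:00:00"), tz = "UTC"),
            discharge = as.POSIXct(paste(icu_end, "10:00:00"), tz = "UTC"),
            disposition = NA_character_)
          stays_h[[length(stays_h) + 1L]] <- data.table(
            patient_id = pid, facility_id = s$fac, specialty_code = "WARD",
            admit = as.POSIXct(paste(icu_end, "10:00:00"), tz = "UTC"),
            discharge = as.POSIXct(paste(s$to, "11:00:00"), tz = "UTC"),
            disposition = NA_character_)
        } else {
          stays_h[[length(stays_h) + 1L]] <- data.table(
            patient_id = pid, facility_id = s$fac, specialty_code = "WARD",
            admit = as.POSIXct(paste(s$from, "08:00:00"), tz = "UTC"),
            discharge = as.POSIXct(paste(s$to, "11:00:00"), tz = "UTC"),
            disposition = NA_character_)
        }
        gt[[length(gt) + 1L]] <- data.table(
          patient_id = pid, hosp_index = h, facility_id = s$fac,
          admit_date = s$from, discharge_date = s$to,
          sepsis = sepsis, died_in_hospital = died_in && k == length(seg))
      }
      stays_h <- rbindlist(stays_h)
      if (died_in) stays_h[.N, disposition := "DIED"]
      # non-acute tail (nursing/domiciliary stay appended at last facility)
      if (!died_in && runif(1) < config$nonacute_tail_prob) {
        last_fac <- seg[[length(seg)]]$fac
        tail_end <- min(disch + sample(3:10, 1L), d1)
        stays_h <- rbindlist(list(stays_h, data.table(
          patient_id = pid, facility_id = last_fac, specialty_code = "CLC",
          admit = as.POSIXct(paste(disch, "13:00:00"), tz = "UTC"),
          discharge = as.POSIXct(paste(tail_end, "11:00:00"), tz = "UTC"),
          disposition = NA_character_)))
      }
      st[[length(st) + 1L]] <- stays_h

      # --- daily physiology per acute day, with truth SOFA
      sep_day <- if (sepsis) admit + 1L else as.Date(NA)  # blood-culture day
      base_creat <- if (sick) runif(1, 1.8, 3.2) else runif(1, 0.6, 1.1)
      base_plt <- if (sick) runif(1, 90, 140) else runif(1, 180, 320)
      base_bili <- if (sick) runif(1, 1.5, 4.0) else runif(1, 0.3, 1.0)
      for (k in seq_along(seg)) {
        s <- seg[[k]]
        dates <- seq(s$from, s$to, by = "day")
        if (k > 1L) dates <- dates[-1L]  # transfer day measured at new site too,
                                         # but keep one draw set per site-day below
        for (dd in as.list(dates)) {
          septic_day <- sepsis && abs(as.integer(dd - sep_day)) <= 1L
          creat <- round(base_creat * runif(1, 0.9, 1.1) *
                           (if (septic_day) 2.2 else 1), 2)
          plate <- round(base_plt * runif(1, 0.92, 1.08) *
                           (if (septic_day) 0.45 else 1), 0)
          bili <- round(base_bili * runif(1, 0.9, 1.1), 2)
          lact <- round((if (septic_day) runif(1, 2.5, 5) else runif(1, 0.6, 1.6)), 1)
          sodium <- round(rnorm(1, 139, 3), 0)
          wbcv <- round((if (septic_day) runif(1, 12, 20) else runif(1, 5, 10)), 1)
          glu <- round(rnorm(1, 110, 20), 0)
          ts <- as.POSIXct(paste(dd, "06:00:00"), tz = "UTC")
          mk <- function(test, val) data.table(
            patient_id = pid, facility_id = s$fac,
            facility_lab_code = paste0(s$fac, "-", toupper(substr(test, 1, 4))),
            local_name = lab_name_variants()[[test]][1],
            loinc = lab_loinc_defaults()[[test]],
            topography = if (test %in% c("platelets", "wbc")) "BLOOD" else "SERUM",
            value = val, unit = switch(test,
              creatinine = "mg/dL", platelets = "10*3/uL",
              bilirubin_total = "mg/dL", sodium = "mmol/L", wbc = "10*3/uL",
              lactate = "mmol/L", bun = "mg/dL", glucose = "mg/dL"),
            drawn_at = ts)
          lb[[length(lb) + 1L]] <- rbindlist(list(
            mk("creatinine", creat), mk("platelets", plate),
            mk("bilirubin_total", bili), mk("sodium", sodium),
            mk("wbc", wbcv), mk("lactate", lact), mk("glucose", glu)))
          if (sepsis && dd == sep_day && s$fac == seg[[1L]]$fac)
            lb[[length(lb) + 1L]] <- data.table(
              patient_id = pid, facility_id = s$fac,
              facility_lab_code = paste0(s$fac, "-BCX"),
              local_name = "BLOOD CULTURE", loinc = "600-7",
              topography = "BLOOD", value = NA_real_, unit = "",
              drawn_at = as.POSIXct(paste(dd, "05:30:00"), tz = "UTC"))

          # vitals: one BP pair + temp + HR + RR per day
          sbp <- round(rnorm(1, 122, 10), 0); dbp <- round(rnorm(1, 72, 8), 0)
          if (septic_day) { sbp <- round(runif(1, 80, 95), 0); dbp <- round(runif(1, 40, 52), 0) }
          vts <- as.POSIXct(paste(dd, "07:00:00"), tz = "UTC")
          vt[[length(vt) + 1L]] <- data.table(
            patient_id = pid, facility_id = s$fac,
            vital_type = c("SYSTOLIC BP", "DIASTOLIC BP", "TEMPERATURE",
                           "PULSE", "RESPIRATION"),
            value = c(sbp, dbp,
                      round((if (septic_day) runif(1, 38.3, 39.5) else rnorm(1, 36.8, 0.3)), 1),
                      round(rnorm(1, if (septic_day) 105 else 78, 8), 0),
                      round(rnorm(1, if (septic_day) 24 else 16, 2), 0)),
            unit = c("mmHg", "mmHg", "C", "bpm", "/min"),
            taken_at = vts)
          mapv <- round((2 * dbp + sbp) / 3, 6)

          # medications
          pres_day <- sepsis && dd >= sep_day & dd <= sep_day + 1L
          if (pres_day)
            md[[length(md) + 1L]] <- data.table(
              patient_id = pid, facility_id = s$fac,
              drug_name_local = "NOREPINEPHRINE 4MG/250ML INJ",
              drug_name_national = "NOREPINEPHRINE BITARTRATE INJ",
              drug_class = "AUTONOMIC", dosage = "4MG/250ML", route = "IV",
              given_at = as.POSIXct(paste(dd, "09:00:00"), tz = "UTC"))
          abx_day <- sepsis && dd >= sep_day & dd <= min(sep_day + 3L, disch)
          if (abx_day)
            md[[length(md) + 1L]] <- data.table(
              patient_id = pid, facility_id = s$fac,
              drug_name_local = "VANCOMYCIN 1GM INJ",
              drug_name_national = "VANCOMYCIN HCL INJ",
              drug_class = "ANTIBIOTIC", dosage = "1GM", route = "IV",
              given_at = as.POSIXct(paste(dd, "10:00:00"), tz = "UTC"))
          if (runif(1) < 0.15)
            md[[length(md) + 1L]] <- data.table(
              patient_id = pid, facility_id = s$fac,
              drug_name_local = "FUROSEMIDE 40MG TAB",
              drug_name_national = "FUROSEMIDE TAB",
              drug_class = "DIURETIC", dosage = "40MG", route = "PO",
              given_at = as.POSIXct(paste(dd, "08:30:00"), tz = "UTC"))

          tier <- if (pres_day) 3L else 0L
          tr <- truth_sofa(plate, bili, creat, mapv, tier)
          gtd[[length(gtd) + 1L]] <- data.table(
            patient_id = pid, facility_id = s$fac, date = dd,
            sofa_coag = tr$coag, sofa_liver = tr$liver,
            sofa_cv = tr$cv, sofa_renal = tr$renal)
        }
      }

      # --- diagnosis / procedure codes, keyed by hospitalization span
      v10 <- icd10_era(disch)
      ver <- if (v10) 10L else 9L
      mkcode <- function(code, type, pos, fac_, ref)
        data.table(patient_id = pid, facility_id = fac_, ref_date = ref,
                   icd_version = ver, code = code, code_type = type,
                   position = pos)
      last_fac <- seg[[length(seg)]]$fac
      if (sepsis) {
        cd[[length(cd) + 1L]] <- mkcode(if (v10) "R6520" else "99592", "dx", 2L,
                                        last_fac, disch)
        cd[[length(cd) + 1L]] <- mkcode(if (v10) "A419" else "0389", "dx", 1L,
                                        last_fac, disch)
        if (runif(1) < 0.3)
          cd[[length(cd) + 1L]] <- mkcode(if (v10) "5A1945Z" else "9671",
                                          "proc", 1L, last_fac, disch)
      } else {
        benign <- if (v10) c("I10", "E119", "J449", "I509", "M545")
                  else c("4019", "25000", "496", "4280", "7242")
        cd[[length(cd) + 1L]] <- mkcode(sample(benign, 1L), "dx", 1L,
                                        last_fac, disch)
        if (runif(1) < 0.5)
          cd[[length(cd) + 1L]] <- mkcode(sample(benign, 1L), "dx", 2L,
                                          last_fac, disch)
      }

      # next admission (readmission) 3-25 days after live discharge
      if (h < n_hosp) admit <- disch + sample(3:25, 1L)
      if (admit > d1 - 35L) break
    }
    if (!is.na(death_date))
      dth[[length(dth) + 1L]] <- data.table(patient_id = pid,
                                            death_date = death_date)
  }

  out <- list(
    specialty_transfers = rbindlist(st),
    labs = rbindlist(lb),
    vitals = rbindlist(vt),
    med_admins = if (length(md)) rbindlist(md) else data.table(
      patient_id = character(), facility_id = character(),
      drug_name_local = character(), drug_name_national = character(),
      drug_class = character(), dosage = character(), route = character(),
      given_at = as.POSIXct(character(), tz = "UTC")),
    codes = rbindlist(cd),
    deaths = if (length(dth)) rbindlist(dth) else
      data.table(patient_id = character(), death_date = as.Date(character())),
    ground_truth = rbindlist(gt),
    ground_truth_days = rbindlist(gtd))
  structure(out, class = "raw_tables", config = config)
}

#' Generate the canonical worked-example patient
#'
#' One patient, two facilities, four specialty stays: Battle Creek MICU days
#' 1-3, same-day transfer to Ann Arbor MICU on day 3, MICU-to-ward transfer
#' within Ann Arbor on day 7, ward-to-CLC (nursing home) on day 10. Yields
#' two SSHs, one acute hospitalization (days 1-10), four bedded stays and
#' one episode of care; calendar day 3 produces two patient-facility-day
#' rows and day 7 one row flagged as an ICU day.
#'
#' @param day1 Calendar date of day 1 (default 2014-03-01).
#' @return A `"raw_tables"` list (labs/vitals/meds/codes empty).
#' @export
generate_worked_example <- function(day1 = as.Date("2014-03-01")) {
  day1 <- as.Date(day1)
  p <- function(d, t) as.POSIXct(paste(day1 + d - 1L, t), tz = "UTC")
  stays <- data.table(
    patient_id = "P000001",
    facility_id = c("F-BATTLE-CREEK", "F-ANN-ARBOR", "F-ANN-ARBOR", "F-ANN-ARBOR"),
    specialty_code = c("MICU", "MICU", "WARD", "CLC"),
    admit = c(p(1, "08:00:00"), p(3, "14:00:00"), p(7, "09:00:00"), p(10, "13:00:00")),
    discharge = c(p(3, "10:00:00"), p(7, "09:00:00"), p(10, "11:00:00"), p(14, "10:00:00")),
    disposition = NA_character_)
  empty <- generate_cohort(cohort_config(n_patients = 1, seed = 999))
  out <- list(
    specialty_transfers = stays,
    labs = empty$labs[0], vitals = empty$vitals[0],
    med_admins = empty$med_admins[0], codes = empty$codes[0],
    deaths = empty$deaths[0],
    ground_truth = data.table(
      patient_id = "P000001", hosp_index = 1L,
      facility_id = c("F-BATTLE-CREEK", "F-ANN-ARBOR"),
      admit_date = c(day1, day1 + 2L),
      discharge_date = c(day1 + 2L, day1 + 9L),
      sepsis = FALSE, died_in_hospital = FALSE),
    ground_truth_days = empty$ground_truth_days[0])
  structure(out, class = "raw_tables")
}

#' Inject coding messiness into generated raw tables
#'
#' Blanks a configurable fraction of lab LOINC codes, rewrites lab test
#' names with facility-specific synonyms, perturbs drug-name strings (case
#' changes, appended dosage text), and inserts decoy medication records
#' containing "research"/"study" tokens. Ground truth is never altered.
#'
#' @param tables Output of [generate_cohort()].
#' @param config The same (or an updated) [cohort_config()].
#' @return A `"raw_tables"` list with perturbed `labs` and `med_admins`.
#' @export
inject_messiness <- function(tables, config = attr(tables, "config")) {
  stopifnot(inherits(tables, "raw_tables"))
  set.seed(config$seed + 1000003L)
  out <- tables
  labs <- copy(tables$labs)
  if (nrow(labs) > 0L) {
    if (config$missing_loinc_rate > 0) {
      # blank LOINC but keep the local name (name-path capture downstream)
      blank <- runif(nrow(labs)) < config$missing_loinc_rate &
        labs$local_name != "BLOOD CULTURE"
      labs[blank, loinc := ""]
    }
    if (config$lab_name_variant_rate > 0) {
      vars <- lab_name_variants()
      base_names <- vapply(vars, `[`, character(1), 1L)
      swap <- runif(nrow(labs)) < config$lab_name_variant_rate
      idx <- match(labs$local_name, base_names)
      pick <- which(swap & !is.na(idx))
      if (length(pick) > 0L) {
        fac_ord <- as.integer(factor(labs$facility_id[pick]))
        labs[pick, local_name := vapply(seq_along(pick), function(j) {
          v <- vars[[idx[pick[j]]]]
          v[2L + (fac_ord[j] %% (length(v) - 1L))]
        }, character(1))]
      }
    }
  }
  out$labs <- labs
  meds <- copy(tables$med_admins)
  if (nrow(meds) > 0L) {
    flip <- runif(nrow(meds)) < 0.3
    meds[flip, drug_name_local := tolower(drug_name_local)]
    decoys <- data.table(
      patient_id = meds$patient_id[1L], facility_id = meds$facility_id[1L],
      drug_name_local = c("RIFAXIMIN 550MG TAB STUDY DRUG",
                          "VANCOMYCIN RESEARCH USE ONLY"),
      drug_name_national = c("RIFAXIMIN STUDY", "VANCOMYCIN RESEARCH"),
      drug_class = "INVESTIGATIONAL", dosage = "",
      route = "PO",
      given_at = meds$given_at[1L])
    meds <- rbindlist(list(meds, decoys), use.names = TRUE, fill = TRUE)
  }
  out$med_admins <- meds
  out$ground_truth <- tables$ground_truth
  out$ground_truth_days <- tables$ground_truth_days
  out
}

#' Write a raw-table bundle as delimited text files
#'
#' One comma-separated file per table (ISO-8601 datetimes, UTF-8, header
#' row): the five raw tables, deaths, and the two ground-truth files.
#'
#' @param tables A `"raw_tables"` list.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_raw_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(specialty_transfers = "specialty_transfers.csv",
             labs = "labs.csv", vitals = "vitals.csv",
             med_admins = "med_admins.csv", codes = "codes.csv",
             deaths = "deaths.csv", ground_truth = "ground_truth_ssh.csv",
             ground_truth_days = "ground_truth_days.csv")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  for (nm in names(files)) pd_write_table(tables[[nm]], paths[[nm]])
  invisible(paths)
}
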