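# End-to-end orchestration: episode construction -> lab/vital harmonization
# -> medication extraction -> clinical phenotypes, with audit reports and a
# run manifest. Deterministic: identical inputs and config give identical
# output bytes.

#' Read a raw-table bundle from a directory of delimited files
#'
#' @param dir Directory written by [write_raw_tables()].
#' @return A `"raw_tables"` list (ground-truth files loaded when present).
#' @export
read_raw_tables <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) pd_read_table(p) else NULL
  }
  out <- list(specialty_transfers = rd("specialty_transfers.csv"),
              labs = rd("labs.csv"), vitals = rd("vitals.csv"),
              med_admins = rd("med_admins.csv"), codes = rd("codes.csv"),
              deaths = rd("deaths.csv"),
              ground_truth = rd("ground_truth_ssh.csv"),
              ground_truth_days = rd("ground_truth_days.csv"))
  if (is.null(out$specialty_transfers))
    pd_stop(sprintf("no specialty_transfers.csv under %s", dir), "pd_config_error")
  if (!is.null(out$deaths) && nrow(out$deaths) > 0L)
    out$deaths[, death_date := pd_date(death_date)]
  structure(out, class = "raw_tables")
}

#' Attach diagnosis/procedure codes to built SSHs
#'
#' A code record joins the SSH of the same patient and facility whose
#' inclusive admission-discharge span contains the record's reference date.
#' Unattached codes are reported, not dropped silently.
#'
#' @param codes Code table (`patient_id, facility_id, ref_date, icd_version,
#'   code, code_type, position`).
#' @param sshs SSH table.
#' @return Codes with an `ssh_id` column; attribute `"audit"$orphans`.
#' @export
attach_codes <- function(codes, sshs) {
  x <- copy(as.data.table(codes))
  if (nrow(x) == 0L) {
    x[, ssh_id := character(0)]
    setattr(x, "audit", list(orphans = x))
    return(x[])
  }
  x[, ref_date := pd_date(ref_date)]
  s <- as.data.table(sshs)[, .(ssh_id, patient_id, facility_id,
                               admit_date, discharge_date)]
  x[, ssh_id := NA_character_]
  x[s, on = .(patient_id, facility_id, ref_date >= admit_date,
              ref_date <= discharge_date),
    ssh_id := i.ssh_id]
  orphans <- x[is.na(ssh_id)]
  out <- x[!is.na(ssh_id)]
  setattr(out, "audit", list(orphans = orphans))
  out[]
}

#' Run the full patient-facility-day construction pipeline
#'
#' Executes episode construction, lab/vital harmonization, medication
#' extraction and clinical phenotyping in order, collecting audit reports
#' and a run manifest (row counts and rejection counts per stage). With
#' `out_dir` set, writes the patient-facility-day file, SSH file, phenotype
#' file, daily physiology and medication indicator files, audit reports and
#' the manifest; re-running on identical inputs is byte-identical.
#'
#' @param input A `"raw_tables"` list or a directory path of raw files.
#' @param out_dir Optional output directory.
#' @param specialty_map,lab_config,lexicon,sofa_config,code_lists,ase_config
#'   Configuration objects (shipped defaults).
#' @param gap_days Contiguity / transfer-gap tolerance in calendar days.
#' @return A list: `ssh, bedded, hospitalizations, episodes, patient_days,
#'   daily_physiology, meds_daily, phenotypes, outcomes, audits, manifest`.
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         specialty_map = load_specialty_map(),
                         lab_config = load_lab_config(),
                         lexicon = load_drug_lexicon(),
                         sofa_config = load_sofa_config(),
                         code_lists = load_code_lists(),
                         ase_config = load_ase_config(),
                         gap_days = 1L) {
  raw <- if (is.character(input)) read_raw_tables(input) else input
  audits <- list()
  mani <- list(gap_days = gap_days)
  empty_dt <- function(...) data.table(...)
  n_or_0 <- function(x) if (is.null(x)) 0L else nrow(as.data.table(x))
  for (nm in c("specialty_transfers", "labs", "vitals", "med_admins", "codes"))
    mani[[paste0("input_rows_", nm)]] <- n_or_0(raw[[nm]])

  # --- stage 1: episodes
  sshs <- build_single_site_hospitalizations(raw$specialty_transfers,
                                             specialty_map, gap_days = gap_days)
  bedded <- build_bedded_stays(raw$specialty_transfers, specialty_map,
                               gap_days = gap_days)
  hosps <- link_acute_hospitalizations(sshs, gap_days = gap_days)
  episodes <- build_episodes_of_care(bedded, gap_days = gap_days)
  days <- expand_patient_facility_days(sshs)
  mani$n_ssh <- nrow(sshs); mani$n_bedded <- nrow(bedded)
  mani$n_acute_hospitalizations <- nrow(hosps); mani$n_episodes <- nrow(episodes)
  mani$n_patient_facility_days <- nrow(days)

  # --- stage 2: labs and vitals
  phys <- empty_dt(patient_id = character(), facility_id = character(),
                   date = as.Date(character()), test_id = character(),
                   low = numeric(), high = numeric(), n_obs = integer())
  if (n_or_0(raw$labs) > 0L) {
    m <- match_lab_records(raw$labs, lab_config)
    audits$lab_match <- attr(m, "audit")
    s <- standardize_units(m, lab_config, "labs")
    audits$lab_units <- attr(s, "audit")
    f <- apply_plausibility_filter(s, lab_config, "labs")
    audits$lab_range <- attr(f, "audit")
    a <- aggregate_daily_extremes(f, days)
    audits$lab_orphans <- attr(a, "audit")
    phys <- rbindlist(list(phys, a), use.names = TRUE, fill = TRUE)
    mani$labs_matched <- nrow(m)
    mani$labs_unmatched <- nrow(audits$lab_match$unmatched)
    mani$labs_conflicted <- nrow(audits$lab_match$conflicts)
    mani$labs_unconvertible <- nrow(audits$lab_units$unconvertible)
    mani$labs_out_of_range <- nrow(audits$lab_range$rejected)
  }
  if (n_or_0(raw$vitals) > 0L) {
    mv <- match_vital_records(raw$vitals, lab_config)
    audits$vital_match <- attr(mv, "audit")
    sv <- standardize_units(mv, lab_config, "vitals")
    fv <- apply_plausibility_filter(sv, lab_config, "vitals")
    audits$vital_range <- attr(fv, "audit")
    av <- aggregate_daily_extremes(fv, days)
    audits$vital_orphans <- attr(av, "audit")
    phys <- rbindlist(list(phys, av), use.names = TRUE, fill = TRUE)
    mani$vitals_matched <- nrow(mv)
    mani$vitals_unmatched <- nrow(audits$vital_match$unmatched)
  }
  setorder(phys, patient_id, facility_id, date, test_id)

  # --- stage 3: medications
  meds_daily <- daily_medication_indicators(
    if (n_or_0(raw$med_admins) > 0L) raw$med_admins else
      empty_dt(patient_id = character(), facility_id = character(),
               drug_name_local = character(), drug_name_national = character(),
               route = character(), given_at = character()),
    days, lexicon)
  audits$meds <- attr(meds_daily, "audit")
  mani$med_indicator_rows <- nrow(meds_daily)
  mani$meds_vetoed <- nrow(audits$meds$vetoed)
  mani$meds_orphaned <- nrow(audits$meds$orphans)

  # --- stage 4: phenotypes
  sofa <- sofa_component_scores(phys, meds_daily, days, sofa_config, lexicon)
  audits$sofa <- attr(sofa, "audit")
  fail <- organ_failure_days(sofa)
  patient_days <- fail$days[days, on = .(patient_id, facility_id, date)]
  setcolorder(patient_days, c("ssh_id", "patient_id", "facility_id", "date",
                              "day_number", "icu_day"))
  setorder(patient_days, patient_id, date, facility_id)

  codes_attached <- attach_codes(
    if (n_or_0(raw$codes) > 0L) raw$codes else
      empty_dt(patient_id = character(), facility_id = character(),
               ref_date = as.Date(character()), icd_version = integer(),
               code = character(), code_type = character(), position = integer()),
    sshs)
  audits$codes <- attr(codes_attached, "audit")
  vent <- detect_mechanical_ventilation(codes_attached, code_lists, sshs = sshs)
  angus <- angus_sepsis_flags(codes_attached, code_lists)
  bc <- extract_blood_cultures(
    if (n_or_0(raw$labs) > 0L) raw$labs else
      empty_dt(patient_id = character(), facility_id = character(),
               local_name = character(), loinc = character(),
               topography = character(), drawn_at = character()),
    lab_config)
  days_keyed <- patient_days[, .(ssh_id, patient_id, facility_id, date)]
  ase <- cdc_ase_sepsis(sshs, days_keyed, bc, meds_daily, phys,
                        vent_flags = vent, deaths = raw$deaths,
                        config = ase_config)
  outcomes <- compute_outcomes(sshs, raw$deaths)

  phen <- sshs[, .(ssh_id, patient_id, facility_id, admit_date, discharge_date)]
  phen[angus, on = "ssh_id", angus_sepsis := i.angus_sepsis]
  phen[is.na(angus_sepsis), angus_sepsis := FALSE]
  phen[ase, on = "ssh_id", `:=`(cdc_ase = i.cdc_ase, culture_date = i.culture_date)]
  phen[vent, on = "ssh_id", mechanical_ventilation := i.mechanical_ventilation]
  phen[outcomes, on = "ssh_id",
       `:=`(los_days = i.los_days,
            in_hospital_mortality = i.in_hospital_mortality,
            mortality_30d = i.mortality_30d, readmit_30d = i.readmit_30d)]
  mani$n_angus_sepsis <- sum(phen$angus_sepsis)
  mani$n_cdc_ase <- sum(phen$cdc_ase)
  mani$organ_failure_days <- paste(fail$totals$component,
                                   fail$totals$n_days, sep = ":", collapse = ",")

  out <- list(ssh = sshs, bedded = bedded, hospitalizations = hosps,
              episodes = episodes, patient_days = patient_days,
              daily_physiology = phys, meds_daily = meds_daily,
              phenotypes = phen, outcomes = outcomes,
              audits = audits, manifest = mani)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @noRd
write_pipeline_outputs <- function(out, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pd_write_table(out$ssh[, !"died_in_hospital"], file.path(out_dir, "ssh.csv"))
  pd_write_table(out$patient_days, file.path(out_dir, "patient_days.csv"))
  pd_write_table(out$daily_physiology, file.path(out_dir, "daily_physiology.csv"))
  pd_write_table(out$meds_daily, file.path(out_dir, "meds_daily.csv"))
  pd_write_table(out$phenotypes, file.path(out_dir, "phenotypes.csv"))
  pd_write_table(out$outcomes, file.path(out_dir, "outcomes.csv"))
  # audit reports
  adir <- file.path(out_dir, "audit")
  if (!dir.exists(adir)) dir.create(adir)
  for (stage in names(out$audits)) {
    a <- out$audits[[stage]]
    for (nm in names(a)) {
      x <- a[[nm]]
      if (is.data.frame(x) && nrow(x) > 0L)
        pd_write_table(x, file.path(adir, sprintf("%s_%s.csv", stage, nm)))
    }
  }
  # manifest: key-value text, one record per line
  mani <- out$manifest
  tf <- tempfile(); on.exit(unlink(tf))
  jsonlite::write_json(mani, tf, auto_unbox = TRUE)
  mani$config_hash <- unname(tools::md5sum(tf))
  writeLines(paste0(names(mani), "=", vapply(mani, as.character, character(1))),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' Spot-check pipeline outputs against raw records
#'
#' Samples `n` patient-facility-days uniformly (seeded) and recomputes, for
#' each, the daily lab/vital extremes and drug indicators directly from the
#' raw records by an independent per-day scan, reporting agree/disagree per
#' field — the desk-scale analogue of chart-review spot checks.
#'
#' @param outputs Result of [run_pipeline()].
#' @param raw The `"raw_tables"` input the pipeline consumed.
#' @param n Number of patient-facility-days to sample.
#' @param seed RNG seed for sampling.
#' @param lab_config,lexicon Configurations (must match the run's).
#' @return `data.table(patient_id, facility_id, date, field, expected,
#'   observed, agree)`; zero rows when `n = 0`.
#' @export
spot_check_sample <- function(outputs, raw, n = 50L, seed = 1L,
                              lab_config = load_lab_config(),
                              lexicon = load_drug_lexicon()) {
  empty <- data.table(patient_id = character(), facility_id = character(),
                      date = as.Date(character()), field = character(),
                      expected = numeric(), observed = numeric(),
                      agree = logical())
  days <- outputs$patient_days
  if (n <= 0L || nrow(days) == 0L) return(empty)
  set.seed(seed)
  idx <- sample.int(nrow(days), min(n, nrow(days)), replace = nrow(days) < n)
  phys <- outputs$daily_physiology
  meds <- outputs$meds_daily

  recompute_day <- function(pid, fid, dd) {
    rows <- list()
    # labs: independent per-day scan (LOINC or name, topography, range)
    labs <- as.data.table(raw$labs)
    if (nrow(labs) > 0L) {
      labs <- labs[patient_id == pid & facility_id == fid &
                     pd_date(pd_parse_datetime(drawn_at)) == dd]
      for (tid in names(lab_config$labs)) {
        t <- lab_config$labs[[tid]]
        vals <- c()
        for (j in seq_len(nrow(labs))) {
          nm <- tolower(fifelse(is.na(labs$local_name[j]), "",
                                as.character(labs$local_name[j])))
          lc <- trimws(as.character(labs$loinc[j]))
          tp <- tolower(trimws(as.character(labs$topography[j])))
          hit <- (!is.na(lc) && lc %in% unlist(t$loinc_set)) ||
            any(vapply(tolower(unlist(t$name_patterns)), grepl, logical(1),
                       x = nm, fixed = TRUE))
          if (!hit || !(is.na(tp) || tp == "" || tp %in% tolower(unlist(t$topography_filter))))
            next
          v <- convert_units(as.numeric(labs$value[j]), labs$unit[j], t)
          if (!is.na(v) && v >= t$plausible_range[1] && v <= t$plausible_range[2])
            vals <- c(vals, v)
        }
        if (length(vals) > 0L)
          rows[[length(rows) + 1L]] <- data.table(
            field = c(paste0(tid, "_low"), paste0(tid, "_high")),
            expected = c(min(vals), max(vals)))
      }
    }
    # vitals: type match, conversion, range, plus MAP derivation from pairs
    vit <- as.data.table(raw$vitals)
    if (nrow(vit) > 0L) {
      vit <- vit[patient_id == pid & facility_id == fid &
                   pd_date(pd_parse_datetime(taken_at)) == dd]
      vvals <- list()
      for (tid in names(lab_config$vitals)) {
        t <- lab_config$vitals[[tid]]
        keep_v <- c(); keep_ts <- c()
        for (j in seq_len(nrow(vit))) {
          vt_j <- toupper(trimws(as.character(vit$vital_type[j])))
          if (!vt_j %in% toupper(unlist(t$vital_types))) next
          u <- if ("unit" %in% names(vit)) vit$unit[j] else NA_character_
          if (is.na(u) || trimws(u) == "") u <- t$canonical_unit
          v <- convert_units(as.numeric(vit$value[j]), u, t)
          if (!is.na(v) && v >= t$plausible_range[1] && v <= t$plausible_range[2]) {
            keep_v <- c(keep_v, v)
            keep_ts <- c(keep_ts, as.character(vit$taken_at[j]))
          }
        }
        if (length(keep_v) > 0L) vvals[[tid]] <- list(v = keep_v, ts = keep_ts)
      }
      if (is.null(vvals$map) && !is.null(vvals$systolic_bp) && !is.null(vvals$diastolic_bp)) {
        common <- intersect(vvals$systolic_bp$ts, vvals$diastolic_bp$ts)
        if (length(common) > 0L) {
          mv <- vapply(common, function(ts) {
            s <- vvals$systolic_bp$v[match(ts, vvals$systolic_bp$ts)]
            d <- vvals$diastolic_bp$v[match(ts, vvals$diastolic_bp$ts)]
            (2 * d + s) / 3
          }, numeric(1))
          vvals$map <- list(v = mv, ts = common)
        }
      }
      for (tid in names(vvals))
        rows[[length(rows) + 1L]] <- data.table(
          field = c(paste0(tid, "_low"), paste0(tid, "_high")),
          expected = c(min(vvals[[tid]]$v), max(vvals[[tid]]$v)))
    }
    # drugs: any non-vetoed token match that day
    ma <- as.data.table(raw$med_admins)
    if (nrow(ma) > 0L) {
      ma <- ma[patient_id == pid & facility_id == fid &
                 pd_date(pd_parse_datetime(given_at)) == dd]
      if (nrow(ma) > 0L) {
        hits <- unique(unlist(lapply(seq_len(nrow(ma)), function(j)
          match_drug(ma[j], lexicon))))
        for (dg in hits)
          rows[[length(rows) + 1L]] <- data.table(
            field = paste0("drug_", dg), expected = 1)
      }
    }
    if (length(rows) == 0L) return(data.table(field = character(), expected = numeric()))
    rbindlist(rows)
  }

  res <- lapply(idx, function(i) {
    pid <- days$patient_id[i]; fid <- days$facility_id[i]; dd <- days$date[i]
    exp <- recompute_day(pid, fid, dd)
    # observed values from the pipeline outputs
    obs_phys <- phys[patient_id == pid & facility_id == fid & date == dd]
    obs_meds <- meds[patient_id == pid & facility_id == fid & date == dd]
    obs <- rbindlist(list(
      if (nrow(obs_phys)) obs_phys[, .(field = paste0(test_id, "_low"), observed = low)],
      if (nrow(obs_phys)) obs_phys[, .(field = paste0(test_id, "_high"), observed = high)],
      if (nrow(obs_meds)) obs_meds[, .(field = paste0("drug_", drug), observed = 1)]))
    cmp <- merge(exp, obs, by = "field", all = TRUE)
    if (nrow(cmp) == 0L)
      return(data.table(patient_id = pid, facility_id = fid, date = dd,
                        field = "(no data)", expected = NA_real_,
                        observed = NA_real_, agree = TRUE))
    cmp[, `:=`(patient_id = pid, facility_id = fid, date = dd,
               agree = !is.na(expected) & !is.na(observed) &
                 abs(expected - observed) < 1e-9)]
    cmp[is.na(expected) & is.na(observed), agree := TRUE]
    cmp[, .(patient_id, facility_id, date, field, expected, observed, agree)]
  })
  rbindlist(res)
}
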