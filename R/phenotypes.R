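# Clinical phenotypes: daily SOFA subscores (coagulation, liver,
# cardiovascular, renal), organ-failure days, claims-based (Angus) and
# EHR-based (CDC Adult Sepsis Event) sepsis, ventilation detection,
# severity-score components.

#' @noRd
score_tiers <- function(value, cuts, direction) {
  if (direction == "low") {
    sc <- rowSums(outer(value, cuts, "<"))
  } else {
    sc <- rowSums(outer(value, cuts, ">="))
  }
  as.integer(sc)  # NA value propagates to NA score
}

#' Daily SOFA component scores from worst daily values
#'
#' Coagulation from the daily platelet low, liver from the bilirubin high,
#' renal from the creatinine high, cardiovascular from the MAP low combined
#' with any administered vasopressor (extended agent list; dose-free tiers
#' via the lexicon's `cv_tier`). Each component is 0-4; a missing input
#' yields a missing component, never an imputed 0.
#'
#' @param day_physiology Long daily physiology from
#'   [aggregate_daily_extremes()].
#' @param day_meds Daily medication indicators from
#'   [daily_medication_indicators()].
#' @param days PatientFacilityDay table (the scoring grid).
#' @param sofa_config Cutoffs from [load_sofa_config()].
#' @param lexicon Drug lexicon (vasoactive tiers).
#' @return `data.table` keyed by (`patient_id, facility_id, date`) with
#'   integer columns `sofa_coag, sofa_liver, sofa_cv, sofa_renal`. Physiology
#'   rows without a matching day key go to attribute `"audit"$unkeyed`.
#' @export
sofa_component_scores <- function(day_physiology, day_meds, days,
                                  sofa_config = load_sofa_config(),
                                  lexicon = load_drug_lexicon()) {
  grid <- as.data.table(days)[, .(patient_id, facility_id, date)]
  phys <- as.data.table(day_physiology)
  unkeyed <- phys[!grid, on = .(patient_id, facility_id, date)]
  if (nrow(unkeyed) > 0L)
    phys <- phys[grid, on = .(patient_id, facility_id, date), nomatch = NULL]
  out <- copy(grid)

  pull <- function(test, side) {
    if (nrow(phys) == 0L) return(out[, rep(NA_real_, .N)])
    sel <- phys[test_id == test, .(patient_id, facility_id, date, v = get(side))]
    out[sel, on = .(patient_id, facility_id, date), x.v := i.v][["x.v"]] -> v
    out[, x.v := NULL]
    v
  }

  cc <- sofa_config$coagulation
  out[, sofa_coag := score_tiers(pull(cc$variable, cc$source), cc$cuts, cc$direction)]
  cl <- sofa_config$liver
  out[, sofa_liver := score_tiers(pull(cl$variable, cl$source), cl$cuts, cl$direction)]
  cr <- sofa_config$renal
  out[, sofa_renal := score_tiers(pull(cr$variable, cr$source), cr$cuts, cr$direction)]

  map_low <- pull(sofa_config$cardiovascular$map_variable, "low")
  map_tier <- fifelse(is.na(map_low), NA_integer_,
                      fifelse(map_low < sofa_config$cardiovascular$map_cut, 1L, 0L))
  meds <- as.data.table(day_meds)
  pressor_tier <- rep(NA_integer_, nrow(out))
  pmeds <- if (nrow(meds) > 0L) meds[category == "vasoactive" & !is.na(cv_tier)]
           else meds
  if (nrow(pmeds) > 0L) {
    pt <- pmeds[, .(tier = max(cv_tier)), by = .(patient_id, facility_id, date)]
    if (nrow(pt) > 0L) {
      out[, x.t := NA_integer_]
      out[pt, on = .(patient_id, facility_id, date), x.t := i.tier]
      pressor_tier <- out$x.t
      out[, x.t := NULL]
    }
  }
  # vasopressor branch dominates the MAP branch; a pressor day with missing
  # MAP still scores (treatment is direct evidence of cardiovascular support)
  out[, sofa_cv := fifelse(!is.na(pressor_tier), pmax(map_tier, pressor_tier, na.rm = TRUE),
                           map_tier)]
  setattr(out, "audit", list(unkeyed = unkeyed))
  out[]
}

#' Organ-failure flags and totals from SOFA components
#'
#' Organ failure on a patient-facility-day is a component score of 3 or 4.
#'
#' @param scores Output of [sofa_component_scores()].
#' @return List: `days` (per-day logical `fail_coag, fail_liver, fail_cv,
#'   fail_renal`) and `totals` (count of flagged patient-facility-days per
#'   component).
#' @export
organ_failure_days <- function(scores) {
  x <- copy(as.data.table(scores))
  comp <- c(coag = "sofa_coag", liver = "sofa_liver",
            cv = "sofa_cv", renal = "sofa_renal")
  for (nm in names(comp))
    x[, (paste0("fail_", nm)) := !is.na(get(comp[[nm]])) & get(comp[[nm]]) >= 3L]
  totals <- data.table(component = names(comp),
                       n_days = vapply(names(comp), function(nm)
                         sum(x[[paste0("fail_", nm)]]), integer(1)))
  list(days = x[], totals = totals[])
}

#' Angus claims-based sepsis for one hospitalization
#'
#' TRUE iff the hospitalization carries (at least one infection code AND at
#' least one acute organ-dysfunction code) OR at least one explicit severe
#' sepsis / septic shock code. ICD-10-era hospitalizations are evaluated
#' against the converted (GEM-mapped, manually curated) lists.
#'
#' @param codes Character vector of diagnosis codes for one SSH.
#' @param icd_version 9 or 10 (scalar or per-code vector).
#' @param lists Code lists from [load_code_lists()].
#' @return Logical scalar.
#' @export
angus_sepsis <- function(codes, icd_version, lists = load_code_lists()) {
  codes <- normalize_icd(codes)
  v <- as.integer(icd_version)
  if (length(v) == 1L) v <- rep(v, length(codes))
  if (length(v) != length(codes) || !all(v %in% c(9L, 10L)))
    pd_stop("icd_version must be 9 or 10 per code", "pd_input_error")
  in_list <- function(nm) {
    l <- lists[[nm]]
    any(paste(v, codes) %in% paste(l$icd_version, l$code))
  }
  in_list("angus_explicit") ||
    (in_list("angus_infection") && in_list("angus_organ_dysfunction"))
}

#' Angus sepsis flags for a diagnosis-code table
#'
#' @param codes_dt `data.table(ssh_id, icd_version, code)` (diagnosis codes;
#'   a `code_type` column, if present, is filtered to "dx").
#' @param lists Code lists.
#' @return `data.table(ssh_id, angus_sepsis)`.
#' @export
angus_sepsis_flags <- function(codes_dt, lists = load_code_lists()) {
  x <- as.data.table(codes_dt)
  if ("code_type" %in% names(x)) x <- x[code_type == "dx"]
  if (nrow(x) == 0L)
    return(data.table(ssh_id = character(), angus_sepsis = logical()))
  x[, .(angus_sepsis = angus_sepsis(code, icd_version, lists)), by = ssh_id]
}

#' Convert an ICD-9 code list to ICD-10 via GEM forward/backward mapping
#'
#' Union of the forward images of the ICD-9 codes and the backward
#' pre-images (ICD-10 codes that map back to a listed ICD-9 code), then
#' de-duplicated, sorted, and filtered by a manual-review exclusion list.
#'
#' @param icd9_list Character vector of ICD-9 codes.
#' @param gem_table GEM-style table from [load_gem_table()].
#' @param exclusions ICD-10 codes rejected at manual review.
#' @return Sorted character vector of ICD-10 codes; attribute `"unmapped"`
#'   lists input codes with no image in either direction.
#' @export
convert_code_lists <- function(icd9_list, gem_table = load_gem_table(),
                               exclusions = character()) {
  src <- normalize_icd(icd9_list)
  g <- as.data.table(gem_table)
  fwd <- g[direction == "forward" & source %in% src]
  bwd <- g[direction == "backward" & target %in% src]
  out <- sort(unique(c(fwd$target, bwd$source)))
  out <- setdiff(out, normalize_icd(exclusions))
  mapped_src <- unique(c(fwd$source, bwd$target))
  structure(out, unmapped = sort(setdiff(src, mapped_src)))
}

#' CDC Adult Sepsis Event (EHR-based) sepsis per hospitalization
#'
#' Presumed infection: a blood culture drawn during the SSH with the first
#' systemic antibiotic day within +/- `window_days`, and the antibiotic run
#' lasting at least `min_qad` consecutive days (or until discharge or death
#' if earlier). Sepsis: presumed infection AND at least one acute
#' organ-dysfunction criterion within +/- `window_days` of the culture day —
#' vasopressor initiation, invasive mechanical ventilation, or a configured
#' abnormal-lab criterion (lactate, platelet fall, creatinine or bilirubin
#' doubling against the SSH baseline).
#'
#' @param sshs SSH table.
#' @param days PatientFacilityDay table (with `ssh_id`).
#' @param blood_cultures Culture-draw days from [extract_blood_cultures()].
#' @param day_meds Daily medication indicators.
#' @param day_physiology Long daily physiology.
#' @param vent_flags Optional `data.table(ssh_id, mechanical_ventilation)`.
#' @param deaths Optional death-date table.
#' @param config ASE parameters from [load_ase_config()].
#' @return `data.table(ssh_id, cdc_ase, culture_date)`; `culture_date` is the
#'   earliest qualifying culture day (NA when not septic).
#' @export
cdc_ase_sepsis <- function(sshs, days, blood_cultures, day_meds,
                           day_physiology, vent_flags = NULL, deaths = NULL,
                           config = load_ase_config()) {
  sshs <- as.data.table(sshs)
  if (nrow(sshs) == 0L)
    return(data.table(ssh_id = character(), cdc_ase = logical(),
                      culture_date = as.Date(character())))
  days <- as.data.table(days)
  bc <- as.data.table(blood_cultures)
  meds <- as.data.table(day_meds)
  phys <- as.data.table(day_physiology)
  W <- as.integer(config$window_days)
  od <- config$organ_dysfunction

  death_of <- function(pid) {
    if (is.null(deaths)) return(as.Date(NA))
    d <- as.data.table(deaths)[patient_id == pid, death_date]
    if (length(d)) pd_date(d[1]) else as.Date(NA)
  }
  vent_of <- function(sid) {
    if (is.null(vent_flags)) return(FALSE)
    v <- as.data.table(vent_flags)[ssh_id == sid]
    nrow(v) > 0L && isTRUE(v$mechanical_ventilation[1])
  }

  res <- lapply(seq_len(nrow(sshs)), function(i) {
    sid <- sshs$ssh_id[i]; pid <- sshs$patient_id[i]; fid <- sshs$facility_id[i]
    d <- days[ssh_id == sid]
    if (nrow(d) == 0L)
      return(data.table(ssh_id = sid, cdc_ase = FALSE, culture_date = as.Date(NA)))
    span <- range(d$date)
    end_of_stay <- min(c(span[2], death_of(pid)), na.rm = TRUE)
    cultures <- bc[patient_id == pid & facility_id == fid &
                     date >= span[1] & date <= span[2], sort(unique(date))]
    if (length(cultures) == 0L)
      return(data.table(ssh_id = sid, cdc_ase = FALSE, culture_date = as.Date(NA)))
    m <- meds[patient_id == pid & facility_id == fid &
                date >= span[1] & date <= span[2]]
    abx_days <- m[category == "antibiotic" & systemic == TRUE, sort(unique(date))]
    pressor_days <- m[category == "vasoactive", sort(unique(date))]
    p <- phys[patient_id == pid & facility_id == fid &
                date >= span[1] & date <= span[2]]
    base_plt <- if (nrow(p[test_id == "platelets"])) max(p[test_id == "platelets", high]) else NA_real_
    base_cre <- if (nrow(p[test_id == "creatinine"])) min(p[test_id == "creatinine", low]) else NA_real_
    base_bil <- if (nrow(p[test_id == "bilirubin_total"])) min(p[test_id == "bilirubin_total", low]) else NA_real_

    for (cd in as.list(cultures)) {
      # --- infection arm: first systemic antibiotic day within the window,
      #     sustained for min_qad consecutive days or until end of stay
      win_abx <- abx_days[abs(as.integer(abx_days - cd)) <= W]
      if (length(win_abx) == 0L) next
      a0 <- min(win_abx)
      run <- abx_days[abx_days >= a0]
      run_len <- if (length(run) == 0L) 0L else {
        brk <- which(diff(run) > 1L)
        if (length(brk) == 0L) length(run) else brk[1]
      }
      run_end <- if (run_len > 0L) run[run_len] else as.Date(NA)
      infection <- run_len >= config$min_qad ||
        (run_len > 0L && run_end >= end_of_stay)
      if (!infection) next
      # --- organ dysfunction arm within +/- W of the culture day
      in_win <- function(dd) length(dd) > 0L && any(abs(as.integer(dd - cd)) <= W)
      dysfunction <- FALSE
      if (isTRUE(od$vasopressor_initiation) && length(pressor_days) > 0L)
        dysfunction <- dysfunction || abs(as.integer(min(pressor_days) - cd)) <= W
      if (!dysfunction && isTRUE(od$mechanical_ventilation))
        dysfunction <- vent_of(sid)
      if (!dysfunction && nrow(p) > 0L) {
        lac <- p[test_id == "lactate" & high >= od$lactate_threshold, date]
        dysfunction <- dysfunction || in_win(lac)
        if (!dysfunction && !is.na(base_plt) && base_plt >= od$platelet_threshold) {
          plt <- p[test_id == "platelets" & low < od$platelet_threshold &
                     low <= (1 - od$platelet_decline) * base_plt, date]
          dysfunction <- in_win(plt)
        }
        if (!dysfunction && !is.na(base_cre)) {
          cre <- p[test_id == "creatinine" & high >= od$creatinine_ratio * base_cre, date]
          dysfunction <- in_win(cre)
        }
        if (!dysfunction && !is.na(base_bil)) {
          bil <- p[test_id == "bilirubin_total" & high >= od$bilirubin_min &
                     high >= od$bilirubin_ratio * base_bil, date]
          dysfunction <- in_win(bil)
        }
      }
      if (dysfunction)
        return(data.table(ssh_id = sid, cdc_ase = TRUE, culture_date = cd))
    }
    data.table(ssh_id = sid, cdc_ase = FALSE, culture_date = as.Date(NA))
  })
  rbindlist(res)
}

#' Detect invasive mechanical ventilation at the hospitalization level
#'
#' Ventilation is detected from procedure codes and emitted only per
#' hospitalization: day-by-day ventilation cannot be distinguished reliably
#' from these data, so `level = "day"` is an unsupported operation.
#'
#' @param codes_dt `data.table(ssh_id, icd_version, code)`; a `code_type`
#'   column, if present, is filtered to "proc".
#' @param lists Code lists (uses `ventilation_procedure`).
#' @param sshs Optional SSH table so SSHs with no codes get FALSE rows.
#' @param level Must be `"hospitalization"`.
#' @return `data.table(ssh_id, mechanical_ventilation)`.
#' @export
detect_mechanical_ventilation <- function(codes_dt, lists = load_code_lists(),
                                          sshs = NULL,
                                          level = "hospitalization") {
  if (!identical(level, "hospitalization"))
    pd_stop("day-level ventilation detection is not supported: procedure codes identify ventilation only at the hospitalization level",
            "pd_unsupported")
  x <- as.data.table(codes_dt)
  if ("code_type" %in% names(x)) x <- x[code_type == "proc"]
  vl <- lists$ventilation_procedure
  out <- if (nrow(x) == 0L) data.table(ssh_id = character(), mechanical_ventilation = logical())
  else {
    x[, code := normalize_icd(code)]
    x[, .(mechanical_ventilation = any(paste(icd_version, code) %in%
                                         paste(vl$icd_version, vl$code))),
      by = ssh_id]
  }
  if (!is.null(sshs)) {
    all_ids <- as.data.table(sshs)[, .(ssh_id)]
    out <- out[all_ids, on = "ssh_id"]
    out[is.na(mechanical_ventilation), mechanical_ventilation := FALSE]
  }
  out[]
}

#' Assemble severity-score components per hospitalization
#'
#' Emits the raw components of an admission illness-severity model — age,
#' admission diagnosis category (configured grouper), 30 comorbidity flags
#' (configured code-prefix sets, provisional seed), and admission-day values
#' for 11 laboratory tests — and deliberately does NOT compute a composite
#' predicted mortality (see [composite_risk_score()]).
#'
#' @param sshs SSH table.
#' @param demographics `data.table(patient_id, age)` (optionally `sex`).
#' @param codes_dt Diagnosis-code table (`ssh_id, icd_version, code,
#'   position`).
#' @param day_physiology Long daily physiology.
#' @param dx_groups,comorbidity_map Configured groupers.
#' @param admission_labs The 11 component labs (admission-day high value).
#' @return One row per SSH: age, `admission_dx_category`, 30 logical
#'   comorbidity columns, 11 `<lab>_adm` columns.
#' @export
assemble_risk_components <- function(sshs, demographics, codes_dt,
                                     day_physiology,
                                     dx_groups = load_dx_groups(),
                                     comorbidity_map = load_comorbidity_map(),
                                     admission_labs = c(
                                       "albumin", "bun", "creatinine", "glucose",
                                       "sodium", "potassium", "bicarbonate",
                                       "wbc", "hematocrit", "bilirubin_total",
                                       "platelets")) {
  sshs <- as.data.table(sshs)
  out <- sshs[, .(ssh_id, patient_id, facility_id, admit_date)]
  demo <- as.data.table(demographics)
  out[demo, on = "patient_id", age := i.age]

  x <- as.data.table(codes_dt)
  if ("code_type" %in% names(x)) x <- x[code_type == "dx"]
  x <- x[ssh_id %in% out$ssh_id]
  x[, code := normalize_icd(code)]

  # admission diagnosis category: primary (position 1) code, longest prefix wins
  prim <- if ("position" %in% names(x)) x[position == 1L] else x[, .SD[1L], by = ssh_id]
  cat_of <- function(code, ver) {
    g <- dx_groups[icd_version == ver]
    hit <- g[vapply(prefix, function(p) startsWith(code, p), logical(1))]
    if (nrow(hit) == 0L) "other" else hit[which.max(nchar(prefix)), category]
  }
  out[, admission_dx_category := "other"]
  if (nrow(prim) > 0L) {
    pc <- prim[, .(admission_dx_category = cat_of(code[1L], icd_version[1L])), by = ssh_id]
    out[pc, on = "ssh_id", admission_dx_category := i.admission_dx_category]
  }

  # 30 comorbidity flags by code prefix
  for (cm in unique(comorbidity_map$comorbidity)) {
    pf <- comorbidity_map[comorbidity == cm]
    flag_ids <- if (nrow(x) == 0L) character(0) else {
      hit <- x[, {
        ok <- rep(FALSE, .N)
        for (j in seq_len(nrow(pf)))
          ok <- ok | (icd_version == pf$icd_version[j] & startsWith(code, pf$prefix[j]))
        .(hit = any(ok))
      }, by = ssh_id][hit == TRUE, ssh_id]
    }
    out[, (cm) := ssh_id %in% flag_ids]
  }

  # 11 admission-day laboratory values (high value on the admission date)
  phys <- as.data.table(day_physiology)
  for (lab in admission_labs) {
    col <- paste0(lab, "_adm")
    out[, (col) := NA_real_]
    if (nrow(phys) > 0L) {
      sel <- phys[test_id == lab,
                  .(patient_id, facility_id, date, v = high)]
      out[sel, on = .(patient_id, facility_id, admit_date = date), (col) := i.v]
    }
  }
  out[]
}

#' Composite illness-severity score (unsupported by design)
#'
#' The package provides severity-score components only; the fitted composite
#' model coefficients are not public, so requesting a composite score is an
#' unsupported operation.
#'
#' @param ... Ignored.
#' @export
composite_risk_score <- function(...) {
  pd_stop("composite illness-severity scores are not computed: only the components are provided (the fitted coefficients are not public)",
          "pd_unsupported")
}
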