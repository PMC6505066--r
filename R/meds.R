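# Barcode-medication-administration extraction: free-text drug-name search
# with research/study exclusion, antibiotic classification, daily indicators.

#' @noRd
med_search_text <- function(x) {
  l <- tolower(fifelse(is.na(x$drug_name_local), "", as.character(x$drug_name_local)))
  n <- tolower(fifelse(is.na(x$drug_name_national), "", as.character(x$drug_name_national)))
  list(local = l, national = n, both = paste(l, n))
}

#' Match one medication-administration record to drug indicators
#'
#' Case-insensitive token search across all name fields (local and national,
#' with or without appended dosage text). Any exclusion token appearing
#' anywhere in any name field vetoes the record entirely — veto dominates
#' every match.
#'
#' @param record A one-row list/data.frame with `drug_name_local` and
#'   `drug_name_national`.
#' @param lexicon Drug lexicon from [load_drug_lexicon()].
#' @return Character vector of matched canonical drug names (empty if vetoed
#'   or no token matches).
#' @export
match_drug <- function(record, lexicon = load_drug_lexicon()) {
  x <- as.data.table(record)[1L]
  if (!"drug_name_national" %in% names(x)) x[, drug_name_national := NA_character_]
  txt <- med_search_text(x)$both
  for (tok in lexicon$exclusion_tokens)
    if (grepl(tok, txt, fixed = TRUE)) return(character(0))
  hits <- vapply(seq_len(nrow(lexicon$drugs)), function(i) {
    pos <- any(vapply(lexicon$drugs$tokens[[i]], grepl, logical(1),
                      x = txt, fixed = TRUE))
    neg <- length(lexicon$drugs$not_tokens[[i]]) > 0L &&
      any(vapply(lexicon$drugs$not_tokens[[i]], grepl, logical(1),
                 x = txt, fixed = TRUE))
    pos && !neg
  }, logical(1))
  lexicon$drugs$drug[hits]
}

#' Match a medication-administration table against the lexicon
#'
#' Table-level version of [match_drug()]: one output row per (record, drug)
#' match; vetoed records are reported, never matched.
#'
#' @param med_admins BCMA table (`patient_id, facility_id, drug_name_local,
#'   drug_name_national, route, given_at`; `drug_class`, `dosage` optional).
#' @param lexicon Drug lexicon.
#' @return Matched rows with `drug, category, abx_class, cv_tier` columns;
#'   attribute `"audit"` holds `vetoed` and `unmatched` record tables.
#' @export
match_drugs <- function(med_admins, lexicon = load_drug_lexicon()) {
  x <- as.data.table(med_admins)
  need <- c("patient_id", "facility_id", "drug_name_local", "given_at")
  if (!all(need %in% names(x)))
    pd_stop(paste("med table must have columns:", paste(need, collapse = ", ")),
            "pd_input_error")
  x <- copy(x)
  if (!"drug_name_national" %in% names(x)) x[, drug_name_national := NA_character_]
  if (!"route" %in% names(x)) x[, route := NA_character_]
  if (nrow(x) == 0L) {
    out <- cbind(x, data.table(drug = character(), category = character(),
                               abx_class = character(), cv_tier = integer())[0])
    setattr(out, "audit", list(vetoed = x, unmatched = x))
    return(out)
  }
  txt <- med_search_text(x)$both
  veto <- rep(FALSE, nrow(x))
  for (tok in lexicon$exclusion_tokens) veto <- veto | grepl(tok, txt, fixed = TRUE)
  hits <- list()
  for (i in seq_len(nrow(lexicon$drugs))) {
    m <- rep(FALSE, nrow(x))
    for (tok in lexicon$drugs$tokens[[i]]) m <- m | grepl(tok, txt, fixed = TRUE)
    # drug-specific negative tokens (e.g. "norepinephrine" must not count as
    # epinephrine under plain substring search)
    for (tok in lexicon$drugs$not_tokens[[i]]) m <- m & !grepl(tok, txt, fixed = TRUE)
    m <- m & !veto
    if (any(m))
      hits[[length(hits) + 1L]] <- data.table(
        row = which(m), drug = lexicon$drugs$drug[i],
        category = lexicon$drugs$category[i],
        abx_class = lexicon$drugs$abx_class[i],
        cv_tier = lexicon$drugs$cv_tier[i])
  }
  hh <- if (length(hits)) rbindlist(hits) else
    data.table(row = integer(), drug = character(), category = character(),
               abx_class = character(), cv_tier = integer())
  out <- cbind(x[hh$row], hh[, !"row"])
  setattr(out, "audit",
          list(vetoed = x[veto],
               unmatched = x[setdiff(which(!veto), unique(hh$row))]))
  out
}

#' Classify an antibiotic administration by class and route group
#'
#' Deterministic lookup: antibiotic class from the lexicon, route group from
#' the configured route map (`systemic-IV`, `systemic-oral`, `non-systemic`).
#' Unknown routes fall to non-systemic with a warning — the conservative
#' choice for the Adult Sepsis Event infection arm.
#'
#' @param drug Canonical drug name (lexicon `category` must be "antibiotic").
#' @param route Recorded route string.
#' @param lexicon Drug lexicon.
#' @return `list(abx_class =, route_group =)`.
#' @export
classify_antibiotic <- function(drug, route, lexicon = load_drug_lexicon()) {
  i <- match(drug, lexicon$drugs$drug)
  if (is.na(i) || lexicon$drugs$category[i] != "antibiotic")
    pd_stop(sprintf("'%s' is not an antibiotic in the lexicon", drug),
            "pd_input_error")
  rg <- route_group_of(route, lexicon)
  if (is.na(rg)) {
    warning(sprintf("unknown route '%s'; classified non-systemic", route),
            call. = FALSE)
    rg <- "non-systemic"
  }
  list(abx_class = lexicon$drugs$abx_class[i], route_group = rg)
}

#' @noRd
route_group_of <- function(route, lexicon) {
  r <- toupper(trimws(fifelse(is.na(route), "", as.character(route))))
  out <- rep(NA_character_, length(r))
  for (g in names(lexicon$route_groups))
    out[r %in% lexicon$route_groups[[g]]] <- g
  out
}

#' Daily drug indicators on the patient-facility-day grid
#'
#' An indicator is TRUE iff at least one non-vetoed administration of that
#' drug occurred on that patient-facility-day (calendar date of the
#' administration timestamp). Administrations on days without a
#' patient-facility-day row are reported as orphans, never silently dropped.
#'
#' @param med_admins BCMA table.
#' @param days PatientFacilityDay table.
#' @param lexicon Drug lexicon.
#' @return Long `data.table` (`patient_id, facility_id, date, drug, category,
#'   abx_class, systemic, n_admin`); `systemic` is TRUE when any same-day
#'   administration of the drug used a systemic (IV or oral) route. Attribute
#'   `"audit"` carries `vetoed`, `unmatched`, `orphans`.
#' @export
daily_medication_indicators <- function(med_admins, days,
                                        lexicon = load_drug_lexicon()) {
  m <- match_drugs(med_admins, lexicon)
  audit <- attr(m, "audit")
  if (nrow(m) == 0L) {
    out <- data.table(patient_id = character(), facility_id = character(),
                      date = as.Date(character()), drug = character(),
                      category = character(), abx_class = character(),
                      cv_tier = integer(), systemic = logical(),
                      n_admin = integer())
    setattr(out, "audit", c(audit, list(orphans = m)))
    return(out[])
  }
  m[, date := pd_date(pd_parse_datetime(given_at))]
  m[, route_group := route_group_of(route, lexicon)]
  keys <- as.data.table(days)[, .(patient_id, facility_id, date)]
  m[, keep := FALSE]
  m[keys, on = .(patient_id, facility_id, date), keep := TRUE]
  orphans <- m[keep == FALSE][, keep := NULL]
  m <- m[keep == TRUE]
  out <- m[, .(category = category[1L], abx_class = abx_class[1L],
               cv_tier = if (all(is.na(cv_tier))) NA_integer_ else
                 max(cv_tier, na.rm = TRUE),
               systemic = any(route_group %in% c("systemic-IV", "systemic-oral"),
                              na.rm = TRUE),
               n_admin = .N),
           by = .(patient_id, facility_id, date, drug)]
  setorder(out, patient_id, facility_id, date, drug)
  setattr(out, "audit", c(audit, list(orphans = orphans)))
  out[]
}
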