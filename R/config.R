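#' Path to a configuration file shipped with the package
#'
#' @param name File name under `inst/extdata`.
#' @return Absolute path.
#' @export
pd_config_path <- function(name) {
  p <- system.file("extdata", name, package = "patientday")
  if (!nzchar(p)) pd_stop(sprintf("no shipped config named '%s'", name),
                          "pd_config_error")
  p
}

#' Load the treating-specialty classification code-list
#'
#' Maps specialty codes to acute / non-acute and ICU / non-ICU. The shipped
#' default covers common unit names; real deployments replace it with the
#' local treating-specialty dictionary.
#'
#' @param path CSV with columns `specialty_code, acute, icu`. Defaults to the
#'   shipped list.
#' @return A `data.table` keyed by `specialty_code`.
#' @export
load_specialty_map <- function(path = pd_config_path("specialty_classes.csv")) {
  m <- pd_read_table(path)
  need <- c("specialty_code", "acute", "icu")
  if (!all(need %in% names(m)))
    pd_stop("specialty map must have columns specialty_code, acute, icu",
            "pd_config_error")
  m[, specialty_code := toupper(trimws(specialty_code))]
  m[, acute := as.logical(acute)]
  m[, icu := as.logical(icu)]
  if (anyDuplicated(m$specialty_code))
    pd_stop("duplicate specialty codes in map", "pd_config_error")
  m[]
}

#' Load standard test definitions (16 laboratory tests + 6 vital signs)
#'
#' Each test carries a LOINC set, local-name synonym patterns, a topography
#' filter, a canonical unit with linear conversions, and a plausible range.
#' Defaults are implementer-seeded clinical standards, editable per site.
#'
#' @param path JSON definition file; defaults to the shipped config.
#' @return A list with elements `labs`, `vitals`, `events`.
#' @export
load_lab_config <- function(path = pd_config_path("lab_tests.json")) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (grp in c("labs", "vitals")) {
    for (tid in names(cfg[[grp]])) {
      t <- cfg[[grp]][[tid]]
      if (!(is.numeric(t$plausible_range) && length(t$plausible_range) == 2 &&
            t$plausible_range[1] < t$plausible_range[2]))
        pd_stop(sprintf("test '%s': plausible_range must be [low, high], low < high", tid),
                "pd_config_error")
    }
  }
  cfg
}

#' Load the drug lexicon
#'
#' Search tokens, global exclusion tokens, six-way category, antibiotic class
#' and route grouping, and the cardiovascular SOFA tier per vasoactive agent.
#'
#' @param path JSON lexicon; defaults to the shipped starter set.
#' @return A list with `drugs` (data.table), `exclusion_tokens`, `route_groups`.
#' @export
load_drug_lexicon <- function(path = pd_config_path("drug_lexicon.json")) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cats <- c("antibiotic", "vasoactive", "sedative", "analgesic", "paralytic", "other")
  drugs <- rbindlist(lapply(cfg$drugs, function(d) {
    if (!d$category %in% cats)
      pd_stop(sprintf("drug '%s': category '%s' not one of the fixed six",
                      d$name, d$category), "pd_config_error")
    data.table(drug = d$name,
               tokens = list(tolower(unlist(d$tokens))),
               not_tokens = list(tolower(unlist(d$not_tokens %||% character(0)))),
               category = d$category,
               abx_class = d$abx_class %||% NA_character_,
               cv_tier = as.integer(d$cv_tier %||% NA_integer_))
  }))
  list(drugs = drugs,
       exclusion_tokens = tolower(unlist(cfg$exclusion_tokens)),
       route_groups = lapply(cfg$route_groups, toupper))
}

#' Load SOFA component cutoffs
#'
#' @param path JSON threshold file; defaults to the shipped standard table.
#' @return Nested list keyed by component.
#' @export
load_sofa_config <- function(path = pd_config_path("sofa_thresholds.json")) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Load diagnosis/procedure code lists for sepsis and ventilation
#'
#' Codes are normalized (dots stripped, upper-cased). The shipped lists are
#' representative seeds, editable per deployment.
#'
#' @param path CSV with columns `list_name, icd_version, code`.
#' @return Named list of data.tables split by `list_name`.
#' @export
load_code_lists <- function(path = pd_config_path("sepsis_codes.csv")) {
  x <- pd_read_table(path)
  x[, code := normalize_icd(code)]
  x[, icd_version := as.integer(icd_version)]
  split(x[, .(icd_version, code)], x$list_name)
}

#' Load Adult Sepsis Event surveillance parameters
#'
#' @param path JSON file; defaults to the shipped CDC-toolkit values.
#' @return A list.
#' @export
load_ase_config <- function(path = pd_config_path("ase_criteria.json")) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Load the comorbidity code-prefix map (30 conditions, provisional seed)
#'
#' The national severity-score component lists are not public; this map ships
#' an Elixhauser-style 30-condition seed by ICD prefix and is expected to be
#' replaced for real analyses.
#'
#' @param path CSV with columns `comorbidity, icd_version, prefix`.
#' @return A `data.table`.
#' @export
load_comorbidity_map <- function(path = pd_config_path("comorbidity_codes.csv")) {
  x <- pd_read_table(path)
  x[, prefix := normalize_icd(prefix)]
  x[, icd_version := as.integer(icd_version)]
  x[]
}

#' Load the admission-diagnosis category grouper
#'
#' Longest matching prefix wins; codes matching nothing fall into "other".
#'
#' @param path CSV with columns `icd_version, prefix, category`.
#' @return A `data.table`.
#' @export
load_dx_groups <- function(path = pd_config_path("admission_dx_groups.csv")) {
  x <- pd_read_table(path)
  x[, prefix := normalize_icd(prefix)]
  x[, icd_version := as.integer(icd_version)]
  x[]
}

#' Load a GEM-style ICD-9 <-> ICD-10 mapping table
#'
#' Three-column dialect: `source, target, direction` where direction is
#' "forward" (ICD-9 source -> ICD-10 target) or "backward" (ICD-10 source ->
#' ICD-9 target). The shipped `gem_synthetic.csv` is a small synthetic
#' stand-in for testing; real use supplies the CMS crosswalk.
#'
#' @param path CSV mapping file.
#' @return A `data.table` with normalized codes.
#' @export
load_gem_table <- function(path = pd_config_path("gem_synthetic.csv")) {
  x <- pd_read_table(path)
  need <- c("source", "target", "direction")
  if (!all(need %in% names(x)))
    pd_stop("GEM table must have columns source, target, direction",
            "pd_config_error")
  x[, source := normalize_icd(source)]
  x[, target := normalize_icd(target)]
  x[, direction := tolower(direction)]
  if (!all(x$direction %in% c("forward", "backward")))
    pd_stop("GEM direction must be forward or backward", "pd_config_error")
  x[]
}

#' Normalize an ICD code: strip dots/whitespace, upper-case
#'
#' @param x Character vector of codes.
#' @return Normalized character vector.
#' @export
normalize_icd <- function(x) toupper(gsub("[. ]", "", as.character(x)))
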