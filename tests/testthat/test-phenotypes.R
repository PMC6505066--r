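lex <- load_drug_lexicon()
sofa_cfg <- load_sofa_config()
lists <- load_code_lists()

phys_row <- function(test, low, high = low, pid = "P1", fid = "F1",
                     date = as.Date("2014-02-02")) {
  data.table(patient_id = pid, facility_id = fid, date = date,
             test_id = test, low = low, high = high, n_obs = 1L)
}
med_row <- function(drug, category, cv_tier = NA_integer_, systemic = TRUE,
                    pid = "P1", fid = "F1", date = as.Date("2014-02-02")) {
  data.table(patient_id = pid, facility_id = fid, date = date, drug = drug,
             category = category, abx_class = NA_character_,
             cv_tier = cv_tier, systemic = systemic, n_admin = 1L)
}
no_meds <- med_row("x", "other")[0]

test_that("SOFA scoring: normal zeros, threshold tiers, vasopressor branch", {
  days <- day_grid(from = "2014-02-01", to = "2014-02-03")
  normal <- rbindlist(list(phys_row("platelets", 250), phys_row("bilirubin_total", 0.8),
                           phys_row("creatinine", 0.9), phys_row("map", 85)))
  s <- sofa_component_scores(normal, no_meds, days, sofa_cfg, lex)
  d2 <- s[date == as.Date("2014-02-02")]
  expect_equal(unlist(d2[, .(sofa_coag, sofa_liver, sofa_cv, sofa_renal)]),
               c(sofa_coag = 0L, sofa_liver = 0L, sofa_cv = 0L, sofa_renal = 0L))

  # standard threshold-table lookups
  s2 <- sofa_component_scores(phys_row("platelets", 45), no_meds, days, sofa_cfg, lex)
  expect_equal(s2[date == as.Date("2014-02-02"), sofa_coag], 3L)
  s3 <- sofa_component_scores(rbindlist(list(
    phys_row("bilirubin_total", 7.5), phys_row("creatinine", 2.1))),
    no_meds, days, sofa_cfg, lex)
  expect_equal(s3[date == as.Date("2014-02-02"), sofa_liver], 3L)
  expect_equal(s3[date == as.Date("2014-02-02"), sofa_renal], 2L)

  # vasopressor administration overrides a normal MAP
  s4 <- sofa_component_scores(phys_row("map", 80),
                              med_row("norepinephrine", "vasoactive", 3L),
                              days, sofa_cfg, lex)
  expect_gte(s4[date == as.Date("2014-02-02"), sofa_cv], 2L)
  # MAP below 70 without pressors scores 1
  s5 <- sofa_component_scores(phys_row("map", 65), no_meds, days, sofa_cfg, lex)
  expect_equal(s5[date == as.Date("2014-02-02"), sofa_cv], 1L)
})

test_that("missing inputs give missing components, never zero", {
  days <- day_grid(from = "2014-02-01", to = "2014-02-03")
  s <- sofa_component_scores(phys_row("bilirubin_total", 0.5), no_meds, days,
                             sofa_cfg, lex)
  d2 <- s[date == as.Date("2014-02-02")]
  expect_true(is.na(d2$sofa_coag))
  expect_true(is.na(d2$sofa_renal))
  expect_true(is.na(d2$sofa_cv))
  expect_equal(d2$sofa_liver, 0L)
  # days with no data at all are fully missing
  expect_true(all(is.na(s[date == as.Date("2014-02-01"),
                          .(sofa_coag, sofa_liver, sofa_cv, sofa_renal)])))
})

test_that("SOFA monotonicity: worsening an input never lowers its component", {
  days <- day_grid(from = "2014-02-02", to = "2014-02-02")
  set.seed(99)
  for (rep in 1:30) {
    plt <- runif(1, 5, 400); bil <- runif(1, 0.2, 15)
    cre <- runif(1, 0.4, 7); mp <- runif(1, 40, 110)
    base <- rbindlist(list(phys_row("platelets", plt), phys_row("bilirubin_total", bil),
                           phys_row("creatinine", cre), phys_row("map", mp)))
    s0 <- sofa_component_scores(base, no_meds, days, sofa_cfg, lex)
    worse <- rbindlist(list(phys_row("platelets", plt * 0.5),
                            phys_row("bilirubin_total", bil * 1.5),
                            phys_row("creatinine", cre * 1.5),
                            phys_row("map", mp - 15)))
    s1 <- sofa_component_scores(worse, no_meds, days, sofa_cfg, lex)
    expect_gte(s1$sofa_coag, s0$sofa_coag)
    expect_gte(s1$sofa_liver, s0$sofa_liver)
    expect_gte(s1$sofa_renal, s0$sofa_renal)
    expect_gte(s1$sofa_cv, s0$sofa_cv)
    # adding a vasopressor never lowers the cardiovascular score
    s2 <- sofa_component_scores(base, med_row("norepinephrine", "vasoactive", 3L),
                                days, sofa_cfg, lex)
    expect_gte(s2$sofa_cv, s0$sofa_cv)
  }
})

test_that("organ failure is exactly component in {3, 4}", {
  days <- day_grid(from = "2014-02-01", to = "2014-02-04")
  phys <- rbindlist(list(
    phys_row("platelets", 45, date = as.Date("2014-02-01")),   # coag 3
    phys_row("platelets", 15, date = as.Date("2014-02-02")),   # coag 4
    phys_row("platelets", 120, date = as.Date("2014-02-03")),  # coag 2
    phys_row("platelets", 200, date = as.Date("2014-02-04")))) # coag 0
  s <- sofa_component_scores(phys, no_meds, days, sofa_cfg, lex)
  f <- organ_failure_days(s)
  expect_equal(f$days[order(date), fail_coag], c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(f$totals[component == "coag", n_days], 2L)
  # totals equal a brute-force scan over all rows
  expect_equal(f$totals[component == "coag", n_days],
               sum(s$sofa_coag %in% c(3L, 4L)))
})

test_that("Angus definition: explicit code, concurrency requirement", {
  expect_true(angus_sepsis("99592", 9, lists))            # explicit alone
  expect_true(angus_sepsis("R65.20", 10, lists))          # dot-normalized
  expect_false(angus_sepsis("0389", 9, lists))            # infection alone
  expect_false(angus_sepsis("5845", 9, lists))            # organ dysfunction alone
  expect_true(angus_sepsis(c("0389", "5845"), 9, lists))  # concurrent pair
  expect_true(angus_sepsis(c("A419", "N179"), 10, lists))
  # mixed-era codes evaluated per record version
  expect_true(angus_sepsis(c("0389", "N179"), c(9, 10), lists))
  expect_error(angus_sepsis("0389", 7, lists), class = "pd_input_error")
})

test_that("GEM conversion equals the hand-computed union on a toy table", {
  toy <- data.table(
    source    = c("0389", "0389", "99592", "A419", "A409", "R6520"),
    target    = c("A419", "A415", "R6520", "0389", "0389", "99592"),
    direction = c("forward", "forward", "forward", "backward", "backward", "backward"))
  out <- convert_code_lists(c("0389", "99592"), toy)
  # forward images: A419, A415, R6520; backward pre-images: A419, A409, R6520
  expect_equal(as.character(out), c("A409", "A415", "A419", "R6520"))
  # de-duplication: A419 reachable both ways appears once
  expect_equal(sum(out == "A419"), 1L)
  # manual-review exclusion applied last
  out2 <- convert_code_lists(c("0389", "99592"), toy, exclusions = "A415")
  expect_false("A415" %in% out2)
  # unmapped codes reported
  out3 <- convert_code_lists(c("0389", "V1234"), toy)
  expect_equal(attr(out3, "unmapped"), "V1234")
})

ase_fixture <- function(shift = 0L, abx_days = 0:4, culture_offset = 1L,
                        pressor_offset = 2L, los = 9L) {
  d0 <- as.Date("2014-02-01") + shift
  sshs <- data.table(ssh_id = "S1", patient_id = "P1", facility_id = "F1",
                     admit_date = d0, discharge_date = d0 + los,
                     censored = FALSE)
  days <- day_grid(from = d0, to = d0 + los)
  bc <- data.table(patient_id = "P1", facility_id = "F1",
                   date = d0 + culture_offset)
  meds <- rbindlist(c(
    lapply(abx_days, function(k)
      med_row("vancomycin", "antibiotic", systemic = TRUE, date = d0 + k)),
    if (!is.null(pressor_offset))
      list(med_row("norepinephrine", "vasoactive", 3L, date = d0 + pressor_offset))))
  list(sshs = sshs, days = days, bc = bc, meds = meds,
       phys = phys_row("creatinine", 1.0)[0])
}

test_that("ASE rule trace: culture day 2, antibiotics days 2-6, pressor day 3", {
  fx <- ase_fixture(abx_days = 1:5, culture_offset = 1L, pressor_offset = 2L)
  res <- cdc_ase_sepsis(fx$sshs, fx$days, fx$bc, fx$meds, fx$phys)
  expect_true(res$cdc_ase)
  expect_equal(res$culture_date, fx$bc$date)

  # no blood culture: infection arm unmet
  res0 <- cdc_ase_sepsis(fx$sshs, fx$days, fx$bc[0], fx$meds, fx$phys)
  expect_false(res0$cdc_ase)

  # too-short antibiotic run (3 days, discharge much later) fails
  fx3 <- ase_fixture(abx_days = 1:3)
  expect_false(cdc_ase_sepsis(fx3$sshs, fx3$days, fx3$bc, fx3$meds, fx3$phys)$cdc_ase)

  # but a short run reaching discharge qualifies ("or until discharge")
  fx4 <- ase_fixture(abx_days = 1:3, los = 3L)
  expect_true(cdc_ase_sepsis(fx4$sshs, fx4$days, fx4$bc, fx4$meds, fx4$phys)$cdc_ase)

  # first systemic antibiotic outside the +/-2-day window fails
  fx5 <- ase_fixture(abx_days = 5:9, culture_offset = 1L, pressor_offset = 2L)
  expect_false(cdc_ase_sepsis(fx5$sshs, fx5$days, fx5$bc, fx5$meds, fx5$phys)$cdc_ase)

  # organ dysfunction outside the window fails
  fx6 <- ase_fixture(abx_days = 1:5, pressor_offset = 6L)
  expect_false(cdc_ase_sepsis(fx6$sshs, fx6$days, fx6$bc, fx6$meds, fx6$phys)$cdc_ase)

  # abnormal-lab criterion: lactate >= 2 inside the window qualifies
  fx7 <- ase_fixture(abx_days = 1:5, pressor_offset = NULL)
  phys7 <- phys_row("lactate", 2.4, date = fx7$bc$date)
  expect_true(cdc_ase_sepsis(fx7$sshs, fx7$days, fx7$bc, fx7$meds, phys7)$cdc_ase)
})

test_that("ASE window property: shifting all events leaves the flag unchanged", {
  for (k in c(-7L, 0L, 11L)) {
    fx <- ase_fixture(shift = k, abx_days = 1:5)
    expect_true(cdc_ase_sepsis(fx$sshs, fx$days, fx$bc, fx$meds, fx$phys)$cdc_ase)
    fx3 <- ase_fixture(shift = k, abx_days = 1:3)
    expect_false(cdc_ase_sepsis(fx3$sshs, fx3$days, fx3$bc, fx3$meds, fx3$phys)$cdc_ase)
  }
})

test_that("ventilation: hospitalization-level only; day-level is unsupported", {
  codes <- data.table(ssh_id = c("S1", "S2"), icd_version = c(10L, 10L),
                      code = c("5A1945Z", "I10"), code_type = "proc")
  v <- detect_mechanical_ventilation(codes, lists)
  expect_true(v[ssh_id == "S1", mechanical_ventilation])
  expect_false(v[ssh_id == "S2", mechanical_ventilation])
  # SSHs without any codes default to FALSE when the SSH table is supplied
  sshs <- data.table(ssh_id = c("S1", "S2", "S3"))
  v2 <- detect_mechanical_ventilation(codes, lists, sshs = sshs)
  expect_false(v2[ssh_id == "S3", mechanical_ventilation])
  expect_error(detect_mechanical_ventilation(codes, lists, level = "day"),
               class = "pd_unsupported")
})

test_that("risk components: age, dx grouping, comorbidity flags, no composite", {
  sshs <- data.table(ssh_id = "S1", patient_id = "P1", facility_id = "F1",
                     admit_date = as.Date("2014-02-01"),
                     discharge_date = as.Date("2014-02-05"), censored = FALSE)
  demo <- data.table(patient_id = "P1", age = 66L)
  rc0 <- assemble_risk_components(sshs, demo, data.table(
    ssh_id = character(), icd_version = integer(), code = character(),
    position = integer()), phys_row("creatinine", 1)[0])
  expect_equal(rc0$age, 66L)
  como_cols <- unique(load_comorbidity_map()$comorbidity)
  expect_length(como_cols, 30L)
  expect_true(all(como_cols %in% names(rc0)))
  expect_false(any(unlist(rc0[, ..como_cols])))
  expect_equal(rc0$admission_dx_category, "other")

  codes <- data.table(ssh_id = "S1", icd_version = 10L,
                      code = c("J189", "E119"), position = c(1L, 2L))
  phys <- phys_row("creatinine", 1.4, date = as.Date("2014-02-01"))
  rc <- assemble_risk_components(sshs, demo, codes, phys)
  expect_true(rc$diabetes_uncomplicated)
  expect_equal(rc$admission_dx_category, "respiratory")
  expect_equal(rc$creatinine_adm, 1.4)
  expect_error(composite_risk_score(), class = "pd_unsupported")
})
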