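library(data.table)

# --- random specialty-stay instances (no same-facility overlaps by
#     construction: each patient's stays advance monotonically in time)
random_stays <- function(n, n_patients = 3L, n_facilities = 3L, seed = 1L) {
  set.seed(seed)
  pts <- sprintf("P%02d", seq_len(n_patients))
  rows <- list()
  remaining <- n
  while (remaining > 0L) {
    pid <- sample(pts, 1L)
    k <- min(remaining, sample(1:6, 1L))
    t0 <- as.Date("2014-01-01") + sample(0:40, 1L)
    for (j in seq_len(k)) {
      len <- sample(0:6, 1L)
      gap <- sample(0:8, 1L, prob = c(4, 4, 2, 1, 1, 1, 1, 1, 1) / 16)
      rows[[length(rows) + 1L]] <- data.table(
        patient_id = pid,
        facility_id = sprintf("F%d", sample.int(n_facilities, 1L)),
        specialty_code = sample(c("MICU", "WARD", "CLC"), 1L,
                                prob = c(0.25, 0.55, 0.20)),
        admit = as.POSIXct(paste(t0, "08:00:00"), tz = "UTC"),
        discharge = as.POSIXct(paste(t0 + len, "16:00:00"), tz = "UTC"))
      t0 <- t0 + len + gap
    }
    remaining <- remaining - k
  }
  rbindlist(rows)
}

# --- brute-force transitive-closure oracle for interval chaining.
# Pairwise contiguity: two stays with identical keys are linked when their
# intervals, inflated by gap_days, touch; groups are the connected
# components (computed by boolean matrix closure, independent of the
# package's sequential gap-join).
closure_components <- function(admit, discharge, key, gap_days = 1L) {
  n <- length(admit)
  if (n == 0L) return(integer(0))
  a <- as.numeric(as.Date(admit)); d <- as.numeric(as.Date(discharge))
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    key[i] == key[j] & a[j] <= d[i] + gap_days & a[i] <= d[j] + gap_days)
  reach <- adj | diag(n) > 0
  repeat {
    r2 <- (reach %*% reach) > 0
    if (identical(r2, reach)) break
    reach <- r2
  }
  match(apply(reach, 1L, function(r) paste(which(r), collapse = ",")),
        unique(apply(reach, 1L, function(r) paste(which(r), collapse = ","))))
}

# two labelings describe the same partition?
same_partition <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) <= 1L) return(TRUE)
  identical(as.integer(factor(x, levels = unique(x))),
            as.integer(factor(y, levels = unique(y))))
}

# --- small lab-record builder
lab_rec <- function(pid = "P1", fid = "F1", name = "CREATININE",
                    loinc = "2160-0", topo = "SERUM", value = 1.0,
                    unit = "mg/dL", when = "2014-02-01 06:00:00") {
  data.table(patient_id = pid, facility_id = fid,
             facility_lab_code = "X", local_name = name, loinc = loinc,
             topography = topo, value = value, unit = unit,
             drawn_at = as.POSIXct(when, tz = "UTC"))
}

med_rec <- function(pid = "P1", fid = "F1", local = "VANCOMYCIN 1GM INJ",
                    national = "VANCOMYCIN HCL INJ", route = "IV",
                    when = "2014-02-01 10:00:00") {
  data.table(patient_id = pid, facility_id = fid, drug_name_local = local,
             drug_name_national = national, drug_class = "", dosage = "",
             route = route, given_at = as.POSIXct(when, tz = "UTC"))
}

day_grid <- function(pid = "P1", fid = "F1", from = "2014-02-01", to = "2014-02-10",
                     ssh = "S1") {
  dts <- seq(as.Date(from), as.Date(to), by = "day")
  data.table(ssh_id = ssh, patient_id = pid, facility_id = fid, date = dts,
             day_number = seq_along(dts), icu_day = FALSE)
}
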