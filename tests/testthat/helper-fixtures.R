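# Shared fixture builders. Everything is generated in code; no data files.

# a single patient-day row with every rule input normal, overridable
normal_day <- function(..., day = 1, patient_id = "P1") {
  base <- list(
    patient_id = patient_id, day = day,
    temp_low = 36.8, temp_high = 37.4, heart_rate = 110, resp_rate = 22,
    sbp = 100, gcs = 15, hemoglobin = 12, wbc = 9, platelets = 250,
    inr = 1.0, alc = 2.5, crp = 1, ferritin = 80, creatinine = 0.4,
    alt = 30, bilirubin = 0.3, pf_ratio = 400, urine_output = 1.5,
    on_vasoactive = FALSE, intubated = FALSE, mech_vent = FALSE,
    sedated = FALSE, tnf_response = 600, adamts13 = 100, sfasl = 50)
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(base, stringsAsFactors = FALSE)
}

# a multi-day series from per-day overrides: days(list(day1 overrides), ...)
day_series <- function(..., patient_id = "P1") {
  overs <- list(...)
  do.call(rbind, lapply(seq_along(overs), function(i) {
    do.call(normal_day, c(overs[[i]], list(day = i, patient_id = patient_id)))
  }))
}

# small default cohort shared across expensive tests (cached per session)
small_cohort <- local({
  cache <- NULL
  function(seed = 11) {
    if (is.null(cache)) cache <<- generate_cohort(sim_config(), seed = seed)
    cache
  }
})

# tiny two-cloud matrix for clustering sanity checks
two_clouds <- function(n_per = 20, sep = 50, p = 4, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * p), n_per),
             matrix(stats::rnorm(n_per * p, mean = sep), n_per))
  scale(x)
}
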