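#' Clinical rule thresholds
#'
#' Threshold set for the organ failure index (OFI) and the empirical
#' multiple-organ-failure phenotype rules. All inequalities in the rules are
#' strict, so boundary values do not fire. Defaults:
#' hyperferritinemia > 500 ng/mL; thrombocytopenia < 100 K/mm3; INR > 1.5;
#' ALT > 100 U/L; bilirubin > 1 mg/dL; creatinine > 1 mg/dL; oliguria
#' < 0.5 mL/kg/h; PaO2/FiO2 < 300; GCS < 12; ADAMTS13 activity < 57% of
#' control; ex vivo TNF response < 200 pg/mL beyond day `tnf_day`; soluble
#' FasL > 200 pg/mL; sequential-liver-failure lag >= 7 days; >= 2 organ
#' failures for immunoparalysis-associated MOF.
#'
#' @param ... named overrides of the default thresholds; overrides are
#'   recorded in the object's `overrides` attribute.
#' @return an object of class `pedsep_rules`.
#' @export
rule_set <- function(...) {
  defaults <- list(
    ferritin_mas = 500, platelet_low = 100, inr_high = 1.5, alt_high = 100,
    bilirubin_high = 1, creatinine_high = 1, oliguria = 0.5, pf_low = 300,
    gcs_low = 12, adamts13_low = 57, tnf_low = 200, tnf_day = 3,
    sfasl_high = 200, smof_lag = 7, min_of_for_mof = 2)
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    stop("unknown rule threshold(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, overrides)
  if (any(unlist(out) <= 0)) {
    stop("all rule thresholds must be strictly positive", call. = FALSE)
  }
  structure(out, overrides = names(overrides), class = "pedsep_rules")
}

#' @export
print.pedsep_rules <- function(x, ...) {
  cat("Clinical rule thresholds:\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-16s %s\n", nm, x[[nm]]))
  ov <- attr(x, "overrides")
  if (length(ov)) cat("  (overridden:", paste(ov, collapse = ", "), ")\n")
  invisible(x)
}

# collapse possibly-multiple rows per (patient, day) to the most abnormal
# value of each variable; used wherever rules see "a day"
collapse_days <- function(days) {
  key <- paste(days$patient_id, days$day, sep = "\r")
  if (!anyDuplicated(key)) {
    out <- days[, setdiff(names(days), "window"), drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  out <- days[first, c("patient_id", "day"), drop = FALSE]
  ngrp <- max(grp)
  # pick the per-group extreme by sorting (group, NA-last, sort key) and
  # keeping each group's final row; vectorized over all rows at once
  pick <- function(x, sort_key) {
    o <- order(grp, !is.na(x), sort_key, na.last = FALSE)
    take <- o[!duplicated(grp[o], fromLast = TRUE)]
    res <- rep(NA_real_, ngrp)
    res[grp[take]] <- x[take]
    res
  }
  for (v in intersect(names(VAR_DIRECTION), names(days))) {
    x <- days[[v]]
    out[[v]] <- switch(VAR_DIRECTION[[v]],
                       high = pick(x, x),
                       low = pick(x, -x),
                       both = pick(x, abs(x - VAR_ANCHORS[[v]])))
  }
  for (v in intersect(c("on_vasoactive", "mech_vent", "intubated", "sedated"),
                      names(days))) {
    x <- days[[v]]
    s <- rowsum(ifelse(is.na(x), 0, as.numeric(x)), grp)
    nobs <- rowsum(as.numeric(!is.na(x)), grp)
    agg <- as.vector(s > 0)
    agg[as.vector(nobs) == 0] <- NA
    out[[v]] <- agg
  }
  rownames(out) <- NULL
  out
}

# per-row organ-failure flags; a criterion with any missing component scores
# FALSE (the organ is unevaluable, not failed)
organ_flags <- function(daily, rules = rule_set()) {
  f <- function(x) {
    x[is.na(x)] <- FALSE
    x
  }
  sed <- daily$sedated
  cns_gcs <- daily$gcs < rules$gcs_low
  cns <- ifelse(is.na(sed), cns_gcs, cns_gcs & !sed)
  cbind(
    cardiovascular = f(daily$on_vasoactive),
    pulmonary = f(daily$mech_vent & daily$pf_ratio < rules$pf_low),
    hepatic = f(daily$bilirubin > rules$bilirubin_high &
                  daily$alt > rules$alt_high),
    renal = f(daily$creatinine > rules$creatinine_high &
                daily$urine_output < rules$oliguria),
    hematologic = f(daily$platelets < rules$platelet_low &
                      daily$inr > rules$inr_high),
    cns = f(cns))
}

#' Organ failure index for one patient-day
#'
#' Integer 0-6 counting failing organ systems: cardiovascular (vasoactive
#' infusion), pulmonary (mechanical ventilation with PaO2/FiO2 < 300),
#' hepatic (bilirubin > 1 mg/dL and ALT > 100 U/L), renal (creatinine
#' > 1 mg/dL and oliguria), hematologic (platelets < 100 K/mm3 and
#' INR > 1.5), and CNS (GCS < 12 in the absence of sedation). An organ with
#' any missing component is scored 0 and flagged unevaluable. A missing
#' sedation flag evaluates the CNS criterion on GCS alone, with a warning.
#'
#' @param day a one-row data.frame (or list) of patient-day values.
#' @param rules a [rule_set()].
#' @return integer score with attributes `flags` (named logical 6-vector)
#'   and `unevaluable` (names of organs with missing inputs).
#' @export
ofi_score <- function(day, rules = rule_set()) {
  day <- as.data.frame(day, stringsAsFactors = FALSE)
  stopifnot(nrow(day) == 1)
  if (is.null(day$sedated) || is.na(day$sedated)) {
    warning("sedation flag missing; CNS criterion evaluated on GCS alone",
            call. = FALSE)
    day$sedated <- NA
  }
  needed <- list(
    cardiovascular = "on_vasoactive",
    pulmonary = c("mech_vent", "pf_ratio"),
    hepatic = c("bilirubin", "alt"),
    renal = c("creatinine", "urine_output"),
    hematologic = c("platelets", "inr"),
    cns = "gcs")
  for (v in unique(unlist(needed))) if (is.null(day[[v]])) day[[v]] <- NA
  flags <- organ_flags(day, rules)[1, ]
  unev <- names(needed)[vapply(needed, function(v) {
    any(is.na(unlist(day[v])))
  }, logical(1))]
  structure(sum(flags), flags = flags, unevaluable = unev)
}

#' SIRS criterion count for one patient-day
#'
#' Counts abnormal heart rate, respiratory rate, temperature and white blood
#' cell count (0-4) against age-banded pediatric reference ranges shipped
#' with the package (`inst/extdata/sirs_age_bands.csv`, following the
#' pediatric consensus bands; the file can be swapped via `bands`).
#' Temperature is abnormal above `temp_high` or below `temp_low`; heart rate
#' below the band's `hr_low` also counts where a low bound is defined
#' (infants). A missing value leaves its criterion uncounted.
#'
#' @param day one-row patient-day data (needs `heart_rate`, `resp_rate`,
#'   `temp_low`, `temp_high`, `wbc`).
#' @param age age in years; must fall inside a band.
#' @param bands reference table, defaulting to the shipped file.
#' @return integer 0-4.
#' @export
sirs_count <- function(day, age, bands = sirs_bands()) {
  day <- as.data.frame(day, stringsAsFactors = FALSE)
  b <- bands[age >= bands$age_min & age < bands$age_max, ]
  if (nrow(b) != 1) stop("no SIRS reference band for age ", age, call. = FALSE)
  crit <- c(
    hr = isTRUE(day$heart_rate > b$hr_high) ||
      (!is.na(b$hr_low) && isTRUE(day$heart_rate < b$hr_low)),
    rr = isTRUE(day$resp_rate > b$rr_high),
    temp = isTRUE(day$temp_high > b$temp_high) ||
      isTRUE(day$temp_low < b$temp_low),
    wbc = isTRUE(day$wbc > b$wbc_high) || isTRUE(day$wbc < b$wbc_low))
  sum(crit)
}

sirs_bands <- function() {
  path <- system.file("extdata", "sirs_age_bands.csv", package = "pedsep",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# series: patient-day rows for ONE patient (possibly with day-1 window rows)
series_daily <- function(series, rules) {
  collapse_days(series)
}

#' Empirical MOF phenotype classifiers
#'
#' Each classifier scans one patient's day series for the rule pattern.
#' All inequalities are strict. `classify_mas`: some day jointly has
#' ferritin > 500 ng/mL, platelets < 100 K/mm3, INR > 1.5, ALT > 100 U/L
#' and bilirubin > 1 mg/dL. `classify_tamof`: some day jointly has ADAMTS13
#' < 57% of control, platelets < 100 K/mm3, oliguria and creatinine
#' > 1 mg/dL. `classify_ipmof`: some day with index > `tnf_day` has TNF
#' response < 200 pg/mL and OFI >= 2. `classify_smof`: a day with soluble
#' FasL > 200 pg/mL, PaO2/FiO2 < 300 and mechanical ventilation is followed
#' `smof_lag` (7) or more days later by ALT > 100 U/L and bilirubin
#' > 1 mg/dL. `classify_npmof`: an organ failure appears after day 1 that
#' was absent on day 1.
#'
#' @param series patient-day data.frame for a single patient.
#' @param rules a [rule_set()].
#' @return logical; `classify_tamof` carries an `unevaluable` attribute when
#'   ADAMTS13 was never measured.
#' @name mof_classifiers
NULL

#' @rdname mof_classifiers
#' @export
classify_mas <- function(series, rules = rule_set()) {
  stopifnot(nrow(series) > 0)
  d <- series_daily(series, rules)
  hit <- d$ferritin > rules$ferritin_mas & d$platelets < rules$platelet_low &
    d$inr > rules$inr_high & d$alt > rules$alt_high &
    d$bilirubin > rules$bilirubin_high
  any(hit, na.rm = TRUE)
}

#' @rdname mof_classifiers
#' @export
classify_tamof <- function(series, rules = rule_set()) {
  stopifnot(nrow(series) > 0)
  d <- series_daily(series, rules)
  if (all(is.na(d$adamts13))) {
    return(structure(FALSE, unevaluable = "adamts13"))
  }
  hit <- d$adamts13 < rules$adamts13_low & d$platelets < rules$platelet_low &
    d$urine_output < rules$oliguria & d$creatinine > rules$creatinine_high
  any(hit, na.rm = TRUE)
}

#' @rdname mof_classifiers
#' @export
classify_ipmof <- function(series, rules = rule_set()) {
  stopifnot(nrow(series) > 0)
  d <- series_daily(series, rules)
  ofi <- rowSums(organ_flags(d, rules))
  hit <- d$day > rules$tnf_day & d$tnf_response < rules$tnf_low &
    ofi >= rules$min_of_for_mof
  any(hit, na.rm = TRUE)
}

#' @rdname mof_classifiers
#' @export
classify_smof <- function(series, rules = rule_set()) {
  stopifnot(nrow(series) > 0)
  d <- series_daily(series, rules)
  first <- d$sfasl > rules$sfasl_high & d$pf_ratio < rules$pf_low &
    d$mech_vent
  liver <- d$alt > rules$alt_high & d$bilirubin > rules$bilirubin_high
  d1 <- d$day[which(first)]
  d2 <- d$day[which(liver)]
  length(d1) > 0 && length(d2) > 0 &&
    any(outer(d2, d1, `-`) >= rules$smof_lag)
}

#' @rdname mof_classifiers
#' @export
classify_npmof <- function(series, rules = rule_set()) {
  stopifnot(nrow(series) > 0)
  d <- series_daily(series, rules)
  flags <- organ_flags(d, rules)
  base <- flags[d$day == 1, , drop = FALSE]
  if (nrow(base) == 0) return(FALSE)
  base <- base[1, ]
  later <- flags[d$day > 1, , drop = FALSE]
  nrow(later) > 0 && any(later[, !base, drop = FALSE])
}

#' Label a whole cohort with MOF phenotypes and daily OFI
#'
#' Applies the five empirical MOF phenotype classifiers and the daily organ
#' failure index to every patient in a cohort.
#'
#' @param cohort a `pedsep_cohort` (or a list with a `days` data.frame).
#' @param rules a [rule_set()].
#' @return list with `labels` (patient_id, ipmof, tamof, smof, mas, npmof,
#'   max_ofi) and `ofi_daily` (patient_id, day, ofi plus the six per-organ
#'   flags).
#' @export
mof_labels <- function(cohort, rules = rule_set()) {
  days <- if (is.data.frame(cohort)) cohort else cohort$days
  daily <- collapse_days(days)
  flags <- organ_flags(daily, rules)
  ofi_daily <- cbind(daily[, c("patient_id", "day")],
                     ofi = rowSums(flags), as.data.frame(flags))
  ids <- unique(daily$patient_id)
  per <- split(daily, daily$patient_id)[ids]
  labels <- data.frame(
    patient_id = ids,
    ipmof = vapply(per, classify_ipmof, logical(1), rules = rules),
    tamof = vapply(per, function(s) as.logical(classify_tamof(s, rules)),
                   logical(1)),
    smof = vapply(per, classify_smof, logical(1), rules = rules),
    mas = vapply(per, classify_mas, logical(1), rules = rules),
    npmof = vapply(per, classify_npmof, logical(1), rules = rules),
    max_ofi = as.integer(tapply(ofi_daily$ofi, ofi_daily$patient_id,
                                max)[ids]),
    row.names = NULL, stringsAsFactors = FALSE)
  list(labels = labels, ofi_daily = ofi_daily)
}
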