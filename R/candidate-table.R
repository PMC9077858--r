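# The 52-variable candidate superset: the 25 clustering inputs plus 27
# columns designed to fail the screening rules, mimicking the bedside
# variables collected in the parent study that were either too sparse at
# 24 h or redundant with a retained variable.

# 13 redundant re-expressions of retained variables (unit conversions,
# repeat measurements, derived indices); each is dropped by the correlation
# rule in favour of its less-missing partner
CANDIDATE_DERIVED <- list(
  age_months = list(partner = "age",
                    fn = function(v, n) v * 12),
  weight_kg = list(partner = "age",
                   fn = function(v, n) pmax(2.5, 3.5 + 2.6 * v * exp(stats::rnorm(n, 0, 0.12)))),
  hematocrit = list(partner = "hemoglobin",
                    fn = function(v, n) v * 3 * exp(stats::rnorm(n, 0, 0.03))),
  diastolic_bp = list(partner = "sbp",
                      fn = function(v, n) v * 0.62 + stats::rnorm(n, 0, 4)),
  mean_arterial_pressure = list(partner = "sbp",
                                fn = function(v, n) v * 0.75 + stats::rnorm(n, 0, 3)),
  temperature_f = list(partner = "temp_high",
                       fn = function(v, n) v * 9 / 5 + 32),
  crp_mg_l = list(partner = "crp",
                  fn = function(v, n) v * 10),
  creatinine_umol = list(partner = "creatinine",
                         fn = function(v, n) v * 88.4),
  ferritin_ug_l = list(partner = "ferritin",
                       fn = function(v, n) v * exp(stats::rnorm(n, 0, 0.05))),
  lymphocytes_repeat = list(partner = "alc",
                            fn = function(v, n) v * exp(stats::rnorm(n, 0, 0.15))),
  gcs_motor = list(partner = "gcs",
                   fn = function(v, n) pmin(6, pmax(1, round(v * 6 / 15)))),
  platelets_repeat = list(partner = "platelets",
                          fn = function(v, n) pmax(1, v + stats::rnorm(n, 0, 15))),
  heart_rate_repeat = list(partner = "heart_rate",
                           fn = function(v, n) v + stats::rnorm(n, 0, 8))
)

# 14 sparse labs: plausible values but too much missingness at 24 h
CANDIDATE_SPARSE <- list(
  lactate = list(meanlog = log(2.2), sdlog = 0.6, miss = 0.35),
  albumin = list(meanlog = log(3.0), sdlog = 0.25, miss = 0.30),
  ph = list(meanlog = log(7.33), sdlog = 0.01, miss = 0.28),
  pao2 = list(meanlog = log(85), sdlog = 0.35, miss = 0.40),
  paco2 = list(meanlog = log(42), sdlog = 0.25, miss = 0.40),
  base_excess = list(meanlog = log(6), sdlog = 0.5, miss = 0.33),
  fibrinogen = list(meanlog = log(300), sdlog = 0.4, miss = 0.45),
  d_dimer = list(meanlog = log(2.5), sdlog = 0.9, miss = 0.50),
  ldh = list(meanlog = log(400), sdlog = 0.6, miss = 0.42),
  ast = list(meanlog = log(60), sdlog = 0.9, miss = 0.25),
  bun = list(meanlog = log(18), sdlog = 0.6, miss = 0.27),
  calcium = list(meanlog = log(8.8), sdlog = 0.1, miss = 0.30),
  magnesium = list(meanlog = log(2.0), sdlog = 0.15, miss = 0.38),
  troponin = list(meanlog = log(0.05), sdlog = 1.2, miss = 0.55)
)

#' Build the 52-column candidate variable table
#'
#' Produces the wide candidate table fed to [screen_variables()]: the 25
#' day-1 clustering inputs, 13 redundant re-expressions of retained
#' variables (unit conversions, repeat measurements) that fail the
#' correlation rule, and 14 sparse labs that fail the missingness rule.
#' The expected violation status and reason for every column are attached
#' as the `candidate_meta` attribute.
#'
#' @param cohort a `pedsep_cohort`.
#' @param seed integer seed for the derived-column noise and sparse-lab
#'   masking; defaults to the cohort seed + 2.
#' @param derived_miss missingness rate given to the redundant columns
#'   (kept below the screening threshold, but above the retained columns'
#'   rates so the correlation tie-break removes the redundant member).
#' @return data.frame with `patient_id` and 52 candidate columns.
#' @export
make_candidate_table <- function(cohort, seed = NULL,
                                 derived_miss = 0.08) {
  stopifnot(inherits(cohort, "pedsep_cohort"))
  set.seed(seed %||% (cohort$seed + 2L))
  feats <- extract_day1_features(cohort)
  n <- nrow(feats)
  out <- as.data.frame(feats)
  for (nm in names(CANDIDATE_DERIVED)) {
    spec <- CANDIDATE_DERIVED[[nm]]
    v <- out[[spec$partner]]
    col <- spec$fn(v, n)
    col[stats::runif(n) < derived_miss] <- NA
    out[[nm]] <- col
  }
  for (nm in names(CANDIDATE_SPARSE)) {
    spec <- CANDIDATE_SPARSE[[nm]]
    col <- stats::rlnorm(n, spec$meanlog, spec$sdlog)
    col[stats::runif(n) < spec$miss] <- NA
    out[[nm]] <- col
  }
  meta <- data.frame(
    variable = setdiff(names(out), "patient_id"),
    expected = c(rep("retain", nrow(default_schema())),
                 rep("correlation", length(CANDIDATE_DERIVED)),
                 rep("missingness", length(CANDIDATE_SPARSE))),
    stringsAsFactors = FALSE)
  attr(out, "candidate_meta") <- meta
  out
}
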