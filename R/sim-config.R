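#' Simulation configuration for a synthetic sepsis cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults encode the reference-cohort calibration: a four-component mixture
#' (phenotypes PedSep-A, B, C and D with prevalences 34/25/27/14%) over the
#' day-1 clinical variables, phenotype-conditional organ-failure rates,
#' subsequent multiple-organ-failure (MOF) phenotype rates, mortality, length
#' of stay, and therapy exposure. Continuous right-skewed laboratory values
#' (ferritin, absolute lymphocyte count, creatinine, C-reactive protein) are
#' modelled log-normal; approximately symmetric vitals and counts (heart rate,
#' systolic blood pressure, temperature, hemoglobin, platelets) are truncated
#' normal at physiologic bounds; the Glasgow Coma Scale is a truncated
#' discrete normal on 3..15.
#'
#' @param n_patients number of patients to simulate.
#' @param mixture_weights named probabilities for phenotypes A..D; must sum
#'   to 1.
#' @param n_days maximum follow-up in days.
#' @param separation multiplier on between-phenotype differences. 1 is the
#'   calibrated cohort; 0 collapses all phenotypes onto the pooled location;
#'   2 doubles every location gap (binary rates are scaled on the logit
#'   scale).
#' @param persistence day-to-day autocorrelation of the latent normal score
#'   driving each variable's within-patient trajectory, in `[0, 1)`.
#' @param missingness named per-column missing-completely-at-random rates
#'   applied to the patient-day table; unnamed columns default to 0.
#' @param interaction_effect list with elements `therapy1`, `therapy2`,
#'   `phenotype` and `odds_multiplier`: the mortality odds for patients of
#'   that phenotype exposed to both therapies are multiplied by
#'   `odds_multiplier`. The default multiplier 1 encodes no effect.
#' @param seed optional integer stored with the config and used as the
#'   default seed by [generate_cohort()].
#'
#' @return an object of class `pedsep_sim_config` (a validated list).
#' @seealso [generate_cohort()], [read_sim_config()], [write_sim_config()]
#' @export
sim_config <- function(n_patients = 404,
                       mixture_weights = c(A = 0.34, B = 0.25, C = 0.27, D = 0.14),
                       n_days = 28,
                       separation = 1,
                       persistence = 0.85,
                       missingness = NULL,
                       interaction_effect = NULL,
                       seed = NULL) {
  cfg <- default_sim_parameters()
  cfg$n_patients <- n_patients
  cfg$mixture_weights <- mixture_weights
  cfg$n_days <- n_days
  cfg$separation <- separation
  cfg$persistence <- persistence
  if (!is.null(missingness)) {
    cfg$missingness[names(missingness)] <- unlist(missingness)
  }
  if (!is.null(interaction_effect)) {
    cfg$interaction_effect[names(interaction_effect)] <- interaction_effect
  }
  cfg$seed <- seed
  class(cfg) <- "pedsep_sim_config"
  validate_sim_config(cfg)
  cfg
}

# Reference-cohort calibration tables. Phenotype order is always A, B, C, D.
default_sim_parameters <- function() {
  ph <- c("A", "B", "C", "D")
  v4 <- function(a, b, c, d) stats::setNames(c(a, b, c, d), ph)

  continuous <- list(
    age        = list(family = "truncnorm", mean = v4(3, 8, 10, 8),
                      sd = v4(4, 6, 5, 6), lo = 0.08, hi = 18),
    heart_rate = list(family = "truncnorm", mean = v4(168.1, 146.5, 150.4, 150.6),
                      sd = v4(30.8, 27.9, 27.6, 35.8), lo = 40, hi = 250),
    sbp        = list(family = "truncnorm", mean = v4(85.0, 74.8, 86.3, 78.9),
                      sd = v4(15.7, 22.0, 17.2, 21.9), lo = 30, hi = 180),
    hemoglobin = list(family = "truncnorm", mean = v4(10.1, 9.4, 10.2, 9.1),
                      sd = v4(1.8, 2.1, 2.1, 1.8), lo = 3, hi = 20),
    # platelet counts are right-skewed (the SD approaches or exceeds the
    # mean in the sicker phenotypes), so a moment-matched log-normal is used
    platelets  = list(family = "lognorm_ms", mean = v4(260.1, 154.3, 118.8, 88.2),
                      sd = v4(122.0, 95.1, 83.5, 108.0)),
    # temperature is modelled as a daily midpoint plus a nonnegative
    # half-range so that the daily low and high keep their calibrated means
    # without being near-collinear
    # midpoint and half-range variances are balanced so the daily low and
    # high temperatures are nearly uncorrelated within a phenotype
    temp_mid   = list(family = "truncnorm", mean = v4(37.25, 36.7, 37.7, 37.05),
                      sd = v4(0.65, 0.95, 0.70, 0.80), lo = 32, hi = 43),
    temp_range = list(family = "truncnorm", mean = v4(0.55, 0.70, 0.60, 0.75),
                      sd = v4(0.65, 0.95, 0.70, 0.80), lo = 0.02, hi = 5),
    gcs        = list(family = "discnorm", mean = v4(8.5, 4.7, 13.2, 7.9),
                      sd = v4(5.2, 3.4, 3.1, 5.5), lo = 3, hi = 15),
    alc        = list(family = "lognorm_mq",
                      median = v4(1.9, 1.1, 0.6, 1.1),
                      q1 = v4(1.3, 0.6, 0.2, 0.6), q3 = v4(3.2, 1.9, 1.0, 2.1)),
    ferritin   = list(family = "lognorm_mq",
                      median = v4(125, 223, 405, 610),
                      q1 = v4(69.8, 116.5, 176.2, 221.1),
                      q3 = v4(207.8, 544.2, 1485.7, 2482.0)),
    creatinine = list(family = "lognorm_mq",
                      median = v4(0.3, 0.6, 0.6, 1.4),
                      q1 = v4(0.2, 0.4, 0.4, 0.6), q3 = v4(0.4, 1.0, 0.7, 2.6)),
    crp        = list(family = "lognorm_ms", mean = v4(7.3, 13.2, 15.2, 13.1),
                      sd = v4(7.3, 11.5, 10.4, 11.2)),
    # supporting variables without published per-phenotype summaries;
    # locations chosen once as clinically plausible for septic children
    wbc        = list(family = "lognorm_mq", median = v4(12, 13, 14, 11),
                      q1 = v4(8, 8.5, 9, 7), q3 = v4(18, 20, 22, 18)),
    resp_rate  = list(family = "truncnorm", mean = v4(32, 30, 34, 30),
                      sd = v4(12, 10, 12, 12), lo = 8, hi = 90),
    tnf_response = list(family = "lognorm_mq", median = v4(500, 300, 250, 150),
                        q1 = v4(290, 175, 145, 85), q3 = v4(860, 515, 430, 260)),
    adamts13   = list(family = "truncnorm", mean = v4(95, 80, 75, 55),
                      sd = v4(25, 25, 25, 22), lo = 0, hi = 150),
    sfasl      = list(family = "lognorm_mq", median = v4(80, 100, 120, 160),
                      q1 = v4(50, 62, 75, 100), q3 = v4(128, 161, 192, 256)),
    prism      = list(family = "lognorm_mq", median = v4(8, 12, 10, 17),
                      q1 = v4(5, 8, 7, 11), q3 = v4(13, 18, 15, 26))
  )

  binary <- list(
    male         = v4(0.463, 0.667, 0.536, 0.607),
    hispanic     = v4(0.206, 0.118, 0.209, 0.071),
    prev_healthy = v4(0.706, 0.275, 0.336, 0.339),
    post_op      = v4(0.044, 0.186, 0.109, 0.214),
    white        = v4(0.75, 0.78, 0.70, 0.80),
    intubated    = v4(0.529, 0.922, 0.136, 0.536),
    mech_vent    = v4(0.985, 0.990, 0.718, 0.929)
  )

  # day-1 organ-failure flag prevalences; the generator couples the
  # component criteria of each organ so these rates are met (capped at what
  # the marginal lab distributions allow)
  ofi_targets <- list(
    cardiovascular = v4(0.463, 0.902, 0.773, 0.786),
    pulmonary      = v4(0.794, 0.853, 0.336, 0.679),
    renal          = v4(0.000, 0.000, 0.000, 0.536),
    hepatic        = v4(0.022, 0.088, 0.100, 0.304),
    hematologic    = v4(0.000, 0.000, 0.073, 0.554),
    cns            = v4(0.088, 0.235, 0.055, 0.214)
  )

  outcome_rates <- list(
    mortality = v4(0.022, 0.117, 0.100, 0.339),
    smof      = v4(0.000, 0.000, 0.009, 0.107),
    mas       = v4(0.000, 0.029, 0.018, 0.339),
    tamof     = v4(0.000, 0.059, 0.027, 0.500),
    npmof     = v4(0.206, 0.245, 0.291, 0.571),
    ipmof     = v4(0.088, 0.284, 0.200, 0.393)
  )

  los <- list(median = v4(9, 10.5, 6, 12.5),
              q1 = v4(5.8, 5.3, 2.3, 7.0),
              q3 = v4(15, 17, 15, 26.5))

  therapies <- list(
    ecmo               = v4(0.037, 0.088, 0.055, 0.179),
    crrt               = v4(0.007, 0.069, 0.064, 0.661),
    decadron           = v4(0.368, 0.216, 0.127, 0.143),
    methylprednisolone = v4(0.397, 0.225, 0.218, 0.286),
    ivig               = v4(0.044, 0.098, 0.173, 0.286),
    plasma_exchange    = v4(0.037, 0.039, 0.036, 0.214),
    hydrocortisone     = v4(0.20, 0.25, 0.22, 0.30),
    prednisone         = v4(0.05, 0.04, 0.05, 0.04),
    anakinra           = v4(0.01, 0.02, 0.03, 0.09),
    rituximab          = v4(0.01, 0.02, 0.02, 0.04),
    tocilizumab        = v4(0.005, 0.01, 0.02, 0.03),
    etoposide          = v4(0.005, 0.01, 0.01, 0.05),
    tacrolimus         = v4(0.03, 0.05, 0.04, 0.06)
  )
  # joint exposure rates for the two combinations tracked explicitly
  therapy_joint <- list(
    methylprednisolone_ivig = v4(0.022, 0.039, 0.082, 0.125),
    ecmo_plasma_exchange    = v4(0.007, 0.010, 0.009, 0.054)
  )

  missingness <- c(crp = 0.06, alc = 0.04, hemoglobin = 0.02, sbp = 0.01)

  list(
    continuous = continuous,
    binary = binary,
    ofi_targets = ofi_targets,
    outcome_rates = outcome_rates,
    los = los,
    therapies = therapies,
    therapy_joint = therapy_joint,
    missingness = as.list(missingness),
    interaction_effect = list(therapy1 = "methylprednisolone",
                              therapy2 = "ivig",
                              phenotype = "D",
                              odds_multiplier = 1)
  )
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      cfg$n_patients < 1) {
    fail("n_patients", "must be a positive count")
  }
  w <- cfg$mixture_weights
  if (length(w) != 4 || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    fail("mixture_weights", "must be 4 nonnegative probabilities summing to 1")
  }
  if (!is.numeric(cfg$n_days) || cfg$n_days < 1) fail("n_days", "must be >= 1")
  if (!is.numeric(cfg$separation) || cfg$separation < 0) {
    fail("separation", "must be >= 0")
  }
  if (cfg$persistence < 0 || cfg$persistence >= 1) {
    fail("persistence", "must be in [0, 1)")
  }
  for (nm in names(cfg$continuous)) {
    sp <- cfg$continuous[[nm]]
    scale_par <- switch(sp$family,
      truncnorm = , lognorm_ms = , discnorm = sp$sd,
      lognorm_mq = sp$q3 - sp$q1
    )
    if (any(scale_par <= 0)) {
      fail(nm, "scale parameters must be strictly positive")
    }
  }
  probs <- c(unlist(cfg$binary), unlist(cfg$ofi_targets),
             unlist(cfg$outcome_rates), unlist(cfg$therapies),
             unlist(cfg$therapy_joint), unlist(cfg$missingness))
  if (any(probs < 0 | probs > 1)) {
    bad <- names(probs)[which(probs < 0 | probs > 1)[1]]
    fail(bad, "probabilities must be in [0, 1]")
  }
  om <- cfg$interaction_effect$odds_multiplier
  if (!is.numeric(om) || om <= 0) {
    fail("interaction_effect", "odds_multiplier must be > 0")
  }
  invisible(cfg)
}

#' @export
print.pedsep_sim_config <- function(x, ...) {
  cat("Synthetic sepsis cohort configuration\n")
  cat(sprintf("  patients: %d, follow-up: %d days\n", x$n_patients, x$n_days))
  cat(sprintf("  phenotype weights: %s\n",
              paste(sprintf("%s=%.2f", names(x$mixture_weights),
                            x$mixture_weights), collapse = ", ")))
  cat(sprintf("  separation: %g, persistence: %g\n", x$separation,
              x$persistence))
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' The configuration round-trips losslessly: `read_sim_config(write_sim_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg a `pedsep_sim_config` object.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `pedsep_sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pedsep_sim_config"))
  # named atomic vectors must become lists so YAML writes maps, not
  # sequences (sequences would lose the phenotype names)
  listify <- function(x) {
    if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else if (is.list(x)) {
      lapply(x, listify)
    } else {
      x
    }
  }
  yaml::write_yaml(listify(unclass(cfg)), path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  template <- default_sim_parameters()
  # restore names on phenotype-indexed vectors (yaml keeps maps, relist them)
  relist4 <- function(x) {
    if (is.list(x) && all(c("A", "B", "C", "D") %in% names(x))) {
      unlist(x)[c("A", "B", "C", "D")]
    } else if (is.list(x)) {
      lapply(x, relist4)
    } else {
      x
    }
  }
  keep_as_list <- c("missingness", "interaction_effect")
  for (nm in names(obj)) {
    if (!(nm %in% keep_as_list)) obj[[nm]] <- relist4(obj[[nm]])
  }
  obj$mixture_weights <- unlist(obj$mixture_weights)
  class(obj) <- "pedsep_sim_config"
  validate_sim_config(obj)
  obj
}
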