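# Synthetic cohort generator: determinism, mixture and outcome calibration,
# rule-rate consistency, missingness, and the candidate table contract.

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_patients = 60, n_days = 6)
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a$days, b$days)
  expect_identical(a$patients, b$patients)
  expect_identical(a$therapies, b$therapies)
  c2 <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a$days, c2$days))
})

test_that("config validation names the offending field", {
  expect_error(sim_config(mixture_weights = c(0.5, 0.5, 0.2, 0)),
               "mixture_weights")
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(persistence = 1.2), "persistence")
  cfg <- sim_config()
  cfg$continuous$ferritin$q1 <- cfg$continuous$ferritin$q3 + 1
  expect_error(validate_sim_config(cfg), "ferritin")
})

test_that("latent phenotypes follow the mixture weights", {
  co <- generate_cohort(sim_config(n_patients = 4040, n_days = 1), seed = 2)
  counts <- table(co$truth$designations$phenotype)
  for (k in names(counts)) {
    p <- sim_config()$mixture_weights[[k]]
    expect_lt(abs(counts[[k]] - 4040 * p), 3 * sqrt(4040 * p * (1 - p)),
              label = paste("phenotype", k))
  }
  # degenerate mixture
  pure <- generate_cohort(sim_config(n_patients = 50, n_days = 1,
                                     mixture_weights = c(A = 1, B = 0,
                                                         C = 0, D = 0)),
                          seed = 3)
  expect_true(all(pure$truth$designations$phenotype == "A"))
})

test_that("phenotype-D mortality matches the configured rate", {
  cfg <- sim_config(n_patients = 4000, n_days = 1,
                    mixture_weights = c(A = 0, B = 0, C = 0, D = 1))
  co <- generate_cohort(cfg, seed = 4)
  p <- 0.339
  expect_lt(abs(mean(co$patients$died) - p), 3 * sqrt(p * (1 - p) / 4000))
})

test_that("continuous marginals are calibrated to the resolved means", {
  cfg <- sim_config(n_patients = 20000, n_days = 1)
  cfg$missingness <- list()
  co <- generate_cohort(cfg, seed = 5)
  res <- pedsep:::resolve_all(cfg)
  d1 <- co$days[co$days$day == 1 & co$days$window == "6-24h", ]
  ph <- co$truth$designations$phenotype[
    match(d1$patient_id, co$truth$designations$patient_id)]
  stopifnot(nrow(d1) == 20000)
  checks <- list(heart_rate = "hr_is_6h", ferritin = NULL, crp = NULL,
                 alc = NULL)
  for (v in c("ferritin", "crp", "alc", "hemoglobin")) {
    d6 <- co$days[co$days$day == 1 & co$days$window == "0-6h", ]
    col <- if (v %in% c("hemoglobin")) {
      d6[[v]][match(d1$patient_id, d6$patient_id)]
    } else {
      d1[[v]]
    }
    for (k in c("A", "D")) {
      i <- ph == k
      target <- res$cont[[v]][[k]]$mean
      se <- sd(col[i]) / sqrt(sum(i))
      expect_lt(abs(mean(col[i]) - target), 4 * se,
                label = sprintf("%s mean in phenotype %s", v, k))
    }
  }
  # medians of the IQR-calibrated labs match the configured medians
  cfgd <- sim_config()
  for (v in c("ferritin", "creatinine", "alc")) {
    d6 <- co$days[co$days$day == 1 & co$days$window == "0-6h", ]
    col6 <- if (v == "creatinine") {
      d6[[v]][match(d1$patient_id, d6$patient_id)]
    } else {
      d1[[v]]
    }
    for (k in c("A", "D")) {
      med <- median(col6[ph == k])
      expect_lt(abs(med / cfgd$continuous[[v]]$median[[k]] - 1), 0.06,
                label = sprintf("%s median in %s", v, k))
    }
  }
})

test_that("MOF rule prevalences converge to the configured rates", {
  cfg <- sim_config(n_patients = 1200,
                    mixture_weights = c(A = 0, B = 0, C = 0, D = 1))
  co <- generate_cohort(cfg, seed = 6)
  mof <- mof_labels(co)
  rates <- sim_config()$outcome_rates
  for (r in c("mas", "tamof", "smof", "npmof", "ipmof")) {
    p <- rates[[r]][["D"]]
    tol <- 3 * sqrt(p * (1 - p) / 1200) + 0.02
    expect_lt(abs(mean(mof$labels[[r]]) - p), tol, label = r)
  }
})

test_that("injected missingness is MCAR at the requested rate", {
  cfg <- sim_config(n_patients = 1500, n_days = 1)
  cfg$missingness <- list()
  co <- generate_cohort(cfg, seed = 7)
  masked <- inject_missingness(co, c(ferritin = 0.5), seed = 9)
  frac <- mean(is.na(masked$days$ferritin))
  expect_gt(frac, 0.485)
  expect_lt(frac, 0.515)
  # truth log retains the complete values
  expect_false(anyNA(masked$truth$days_complete$ferritin))
  # rate 0 leaves the cohort unchanged; rate 1 empties the column
  same <- inject_missingness(co, c(ferritin = 0), seed = 9)
  expect_identical(same$days$ferritin, co$days$ferritin)
  gone <- inject_missingness(co, c(crp = 1), seed = 9)
  expect_true(all(is.na(gone$days$crp)))
  expect_error(inject_missingness(co, c(crp = 1.2)), "0, 1")
  expect_error(inject_missingness(co, c(bogus = 0.1)), "unknown")
})

test_that("series respect stay, death and day ordering", {
  co <- small_cohort()
  p <- co$patients
  expect_true(all(p$last_day >= 1 & p$last_day <= co$config$n_days))
  expect_true(all(is.na(p$death_day) != p$died))
  expect_true(all(xor(is.na(p$death_day), is.na(p$discharge_day))))
  per <- split(co$days$day, co$days$patient_id)
  for (pid in names(per)[1:20]) {
    d <- sort(unique(per[[pid]]))
    expect_equal(d, seq_len(p$last_day[p$patient_id == pid]))
  }
  # day 1 has both window rows, later days one
  d1 <- co$days[co$days$day == 1, ]
  expect_setequal(unique(d1$window), c("0-6h", "6-24h"))
  expect_equal(nrow(d1), 2 * nrow(p))
})

test_that("clinical values respect physiologic bounds", {
  co <- small_cohort()
  d <- co$days
  expect_true(all(d$gcs >= 3 & d$gcs <= 15, na.rm = TRUE))
  expect_true(all(d$adamts13 >= 0 & d$adamts13 <= 150, na.rm = TRUE))
  expect_true(all(d$temp_high >= d$temp_low, na.rm = TRUE))
  num <- c("heart_rate", "sbp", "platelets", "ferritin", "creatinine",
           "alt", "bilirubin", "pf_ratio", "urine_output", "alc", "crp")
  for (v in num) expect_true(all(d[[v]] >= 0, na.rm = TRUE), label = v)
})

test_that("therapy exposure rates track the configured prevalences", {
  cfg <- sim_config(n_patients = 3000, n_days = 1,
                    mixture_weights = c(A = 0, B = 0, C = 0, D = 1))
  co <- generate_cohort(cfg, seed = 8)
  ex <- therapy_exposures(co)
  for (tn in c("crrt", "ivig", "plasma_exchange")) {
    p <- sim_config()$therapies[[tn]][["D"]]
    expect_lt(abs(mean(ex[[tn]]) - p), 3 * sqrt(p * (1 - p) / 3000) + 0.005,
              label = tn)
  }
  both <- mean(ex$methylprednisolone == 1 & ex$ivig == 1)
  expect_lt(abs(both - 0.125), 0.025)
})

test_that("a planted protective combination lowers mortality as configured", {
  cfg <- sim_config(n_patients = 6000, n_days = 1,
                    mixture_weights = c(A = 0, B = 0, C = 0, D = 1),
                    interaction_effect = list(odds_multiplier = 0.05))
  co <- generate_cohort(cfg, seed = 9)
  ex <- therapy_exposures(co)
  both <- ex$methylprednisolone == 1 & ex$ivig == 1
  died <- co$patients$died
  or <- (sum(died & both) / sum(!died & both)) /
    (sum(died & !both) / sum(!died & !both))
  expect_lt(or, 0.3)
})

test_that("sim config round-trips through YAML", {
  cfg <- sim_config(n_patients = 123, separation = 1.5,
                    missingness = list(crp = 0.11))
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$n_patients, cfg$n_patients)
  expect_equal(back$separation, cfg$separation)
  expect_equal(back$missingness$crp, 0.11)
  expect_equal(back$continuous, cfg$continuous, tolerance = 1e-12)
  expect_equal(back$mixture_weights, cfg$mixture_weights)
  # a cohort generated from the round-tripped config is identical
  expect_identical(generate_cohort(cfg, seed = 3)$days,
                   generate_cohort(back, seed = 3)$days)
})
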