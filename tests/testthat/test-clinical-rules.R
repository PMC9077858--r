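# Rule engine: organ failure index, SIRS count, and the empirical MOF
# phenotype classifiers (MAS, TAMOF, IPMOF, SMOF, NPMOF).

test_that("ofi_score counts failing organ systems", {
  expect_equal(as.integer(ofi_score(normal_day())), 0L)
  expect_equal(as.integer(ofi_score(normal_day(on_vasoactive = TRUE))), 1L)
  all6 <- normal_day(on_vasoactive = TRUE, mech_vent = TRUE, pf_ratio = 250,
                     bilirubin = 2, alt = 150, creatinine = 1.5,
                     urine_output = 0.2, platelets = 80, inr = 2, gcs = 8)
  s <- ofi_score(all6)
  expect_equal(as.integer(s), 6L)
  expect_true(all(attr(s, "flags")))
})

test_that("organ criteria are conjunctions: one component alone never fires", {
  # platelets low but INR normal -> no hematologic failure, and so on
  partial <- list(
    list(platelets = 80), list(inr = 2),
    list(bilirubin = 2), list(alt = 150),
    list(creatinine = 1.5), list(urine_output = 0.2),
    list(mech_vent = TRUE), list(pf_ratio = 250))
  for (ov in partial) {
    expect_equal(as.integer(ofi_score(do.call(normal_day, ov))), 0L,
                 info = paste(names(ov), collapse = ","))
  }
})

test_that("boundary values do not fire (strict inequalities)", {
  expect_equal(as.integer(ofi_score(normal_day(platelets = 100, inr = 1.5))),
               0L)
  expect_equal(as.integer(ofi_score(normal_day(creatinine = 1,
                                               urine_output = 0.5))), 0L)
  expect_equal(as.integer(ofi_score(normal_day(bilirubin = 1, alt = 100))),
               0L)
  expect_equal(as.integer(ofi_score(normal_day(mech_vent = TRUE,
                                               pf_ratio = 300))), 0L)
  expect_equal(as.integer(ofi_score(normal_day(gcs = 12))), 0L)
})

test_that("CNS criterion respects sedation and warns when flag is missing", {
  expect_equal(as.integer(ofi_score(normal_day(gcs = 8))), 1L)
  expect_equal(as.integer(ofi_score(normal_day(gcs = 8, sedated = TRUE))), 0L)
  d <- normal_day(gcs = 8)
  d$sedated <- NA
  expect_warning(s <- ofi_score(d), "sedation")
  expect_equal(as.integer(s), 1L)
})

test_that("missing inputs score the organ 0 and mark it unevaluable", {
  d <- normal_day(on_vasoactive = TRUE)
  d$platelets <- NA
  s <- ofi_score(d)
  expect_equal(as.integer(s), 1L)
  expect_true("hematologic" %in% attr(s, "unevaluable"))
})

test_that("sirs_count scores abnormal vitals against age bands", {
  d <- normal_day(heart_rate = 120, resp_rate = 18, temp_high = 37.2,
                  temp_low = 36.5, wbc = 9)
  expect_equal(sirs_count(d, age = 8), 0L)
  worst <- normal_day(heart_rate = 150, resp_rate = 30, temp_high = 39.5,
                      wbc = 20)
  expect_equal(sirs_count(worst, age = 8), 4L)
  # fever alone is a single criterion
  expect_equal(sirs_count(normal_day(heart_rate = 120, resp_rate = 16,
                                     temp_high = 38.6, wbc = 9), age = 8),
               1L)
  # the same heart rate can be abnormal for an adolescent but not a toddler
  hr120 <- normal_day(heart_rate = 120, resp_rate = 10, wbc = 9)
  expect_equal(sirs_count(hr120, age = 15), 1L)
  expect_equal(sirs_count(hr120, age = 3), 0L)
  expect_error(sirs_count(hr120, age = 25), "band")
})

test_that("classify_mas requires all five conditions on the same day", {
  pos <- day_series(list(), list(ferritin = 610, platelets = 88, inr = 1.6,
                                 alt = 150, bilirubin = 1.2))
  expect_true(classify_mas(pos))
  # ferritin at the threshold does not fire
  boundary <- day_series(list(ferritin = 499, platelets = 88, inr = 1.6,
                              alt = 150, bilirubin = 1.2))
  expect_false(classify_mas(boundary))
  # conditions crossed on different days but never jointly
  split_days <- day_series(list(ferritin = 610, platelets = 88),
                           list(inr = 1.6, alt = 150, bilirubin = 1.2))
  expect_false(classify_mas(split_days))
})

test_that("classify_tamof joins microangiopathy with same-day AKI", {
  pos <- day_series(list(adamts13 = 40, platelets = 80, urine_output = 0.3,
                         creatinine = 1.4))
  expect_true(classify_tamof(pos))
  expect_false(classify_tamof(day_series(list(adamts13 = 57, platelets = 80,
                                              urine_output = 0.3,
                                              creatinine = 1.4))))
  never <- day_series(list(platelets = 80, urine_output = 0.3,
                           creatinine = 1.4))
  never$adamts13 <- NA
  res <- classify_tamof(never)
  expect_false(as.logical(res))
  expect_equal(attr(res, "unevaluable"), "adamts13")
})

test_that("classify_ipmof needs low TNF beyond day 3 with two organ failures", {
  mk <- function(day_n, tnf, n_organs) {
    overs <- rep(list(list()), day_n - 1)
    last <- list(tnf_response = tnf)
    if (n_organs >= 1) last$on_vasoactive <- TRUE
    if (n_organs >= 2) {
      last$mech_vent <- TRUE
      last$pf_ratio <- 250
    }
    do.call(day_series, c(overs, list(last)))
  }
  expect_true(classify_ipmof(mk(5, 150, 2)))
  expect_false(classify_ipmof(mk(2, 150, 2)))   # not beyond day 3
  expect_false(classify_ipmof(mk(5, 150, 1)))   # only one organ failure
  expect_false(classify_ipmof(mk(5, 200, 2)))   # TNF at threshold
})

test_that("classify_smof enforces the seven-day lag", {
  mk <- function(first_day, liver_day, n_days = 10) {
    overs <- rep(list(list()), n_days)
    overs[[first_day]] <- list(sfasl = 300, pf_ratio = 250, mech_vent = TRUE)
    overs[[liver_day]] <- c(overs[[liver_day]],
                            list(alt = 150, bilirubin = 1.5))
    do.call(day_series, overs)
  }
  expect_true(classify_smof(mk(1, 8)))
  expect_false(classify_smof(mk(1, 5)))   # lag unmet
  # two candidate trigger days; only the earlier pairs with a valid liver day
  two <- day_series(list(sfasl = 300, pf_ratio = 250, mech_vent = TRUE),
                    list(), list(),
                    list(sfasl = 300, pf_ratio = 250, mech_vent = TRUE),
                    list(), list(), list(),
                    list(alt = 150, bilirubin = 1.5))
  expect_true(classify_smof(two))
})

test_that("classify_npmof detects organ failures new after day 1", {
  expect_true(classify_npmof(day_series(list(on_vasoactive = TRUE),
                                        list(),
                                        list(on_vasoactive = TRUE,
                                             creatinine = 1.5,
                                             urine_output = 0.2))))
  expect_false(classify_npmof(day_series(list(on_vasoactive = TRUE),
                                         list(on_vasoactive = TRUE),
                                         list())))
  all6 <- list(on_vasoactive = TRUE, mech_vent = TRUE, pf_ratio = 250,
               bilirubin = 2, alt = 150, creatinine = 1.5,
               urine_output = 0.2, platelets = 80, inr = 2, gcs = 8)
  expect_false(classify_npmof(do.call(day_series, list(all6, all6))))
})

test_that("monotonicity: relaxing a threshold never turns a positive negative", {
  pos <- day_series(list(), list(ferritin = 610, platelets = 88, inr = 1.6,
                                 alt = 150, bilirubin = 1.2))
  relaxed <- rule_set(ferritin_mas = 400, platelet_low = 120, inr_high = 1.2,
                      alt_high = 80, bilirubin_high = 0.8)
  expect_true(classify_mas(pos, relaxed))
})

test_that("knockout: removing any single conjunct defeats each rule", {
  mas_day <- list(ferritin = 610, platelets = 88, inr = 1.6, alt = 150,
                  bilirubin = 1.2)
  mas_normal <- list(ferritin = 80, platelets = 250, inr = 1.0, alt = 30,
                     bilirubin = 0.3)
  for (v in names(mas_day)) {
    ko <- mas_day
    ko[[v]] <- mas_normal[[v]]
    expect_false(classify_mas(day_series(ko)), info = paste("MAS ko:", v))
  }
  ta_day <- list(adamts13 = 40, platelets = 80, urine_output = 0.3,
                 creatinine = 1.4)
  ta_normal <- list(adamts13 = 100, platelets = 250, urine_output = 1.5,
                    creatinine = 0.4)
  for (v in names(ta_day)) {
    ko <- ta_day
    ko[[v]] <- ta_normal[[v]]
    expect_false(classify_tamof(day_series(ko)), info = paste("TAMOF ko:", v))
  }
  smof_trigger <- list(sfasl = 300, pf_ratio = 250, mech_vent = TRUE)
  smof_normal <- list(sfasl = 50, pf_ratio = 400, mech_vent = FALSE)
  for (v in names(smof_trigger)) {
    ko <- smof_trigger
    ko[[v]] <- smof_normal[[v]]
    overs <- c(list(ko), rep(list(list()), 6),
               list(list(alt = 150, bilirubin = 1.5)))
    expect_false(classify_smof(do.call(day_series, overs)),
                 info = paste("SMOF ko:", v))
  }
})

test_that("ofi_score agrees with a shuffled-predicate re-implementation", {
  # independent oracle: evaluate the six organ predicates in random order
  oracle_ofi <- function(day, order) {
    preds <- list(
      cardiovascular = function(d) isTRUE(d$on_vasoactive),
      pulmonary = function(d) isTRUE(d$mech_vent) && isTRUE(d$pf_ratio < 300),
      hepatic = function(d) isTRUE(d$bilirubin > 1) && isTRUE(d$alt > 100),
      renal = function(d) isTRUE(d$creatinine > 1) &&
        isTRUE(d$urine_output < 0.5),
      hematologic = function(d) isTRUE(d$platelets < 100) &&
        isTRUE(d$inr > 1.5),
      cns = function(d) isTRUE(d$gcs < 12) && !isTRUE(d$sedated))
    sum(vapply(preds[order], function(f) f(day), logical(1)))
  }
  set.seed(7)
  for (i in 1:40) {
    d <- normal_day(
      on_vasoactive = runif(1) < 0.5, mech_vent = runif(1) < 0.5,
      pf_ratio = runif(1, 100, 500), bilirubin = runif(1, 0.1, 3),
      alt = runif(1, 10, 300), creatinine = runif(1, 0.2, 3),
      urine_output = runif(1, 0.1, 3), platelets = runif(1, 20, 400),
      inr = runif(1, 0.8, 3), gcs = sample(3:15, 1),
      sedated = runif(1) < 0.3)
    expect_equal(as.integer(ofi_score(d)), oracle_ofi(d, sample(6)))
  }
})

test_that("mof_labels is consistent with per-patient classifiers", {
  co <- small_cohort()
  mof <- mof_labels(co)
  expect_setequal(mof$labels$patient_id, co$patients$patient_id)
  expect_equal(mof$labels$max_ofi,
               as.integer(tapply(mof$ofi_daily$ofi, mof$ofi_daily$patient_id,
                                 max)[mof$labels$patient_id]),
               ignore_attr = TRUE)
  # spot-check a handful of patients against the scalar classifiers
  ids <- mof$labels$patient_id[c(1, 50, 100, 200, 300)]
  for (pid in ids) {
    series <- co$days[co$days$patient_id == pid, ]
    expect_equal(mof$labels$mas[mof$labels$patient_id == pid],
                 as.logical(classify_mas(series)))
    expect_equal(mof$labels$npmof[mof$labels$patient_id == pid],
                 as.logical(classify_npmof(series)))
  }
})

test_that("rule thresholds validate and report overrides", {
  expect_error(rule_set(nonsense = 1), "unknown")
  expect_error(rule_set(ferritin_mas = -1), "positive")
  rs <- rule_set(adamts13_low = 60)
  expect_equal(rs$adamts13_low, 60)
  expect_equal(attr(rs, "overrides"), "adamts13_low")
})
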