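# Association statistics: group comparisons, odds ratios, rate tables,
# curves, chord links, biomarker log-ratios, standardized profiles.

test_that("rate_table reproduces reference percentage arithmetic", {
  r <- rate_table(c(45, 3, 19), c(404, 136, 56))
  expect_equal(r$percent, c(11.1, 2.2, 33.9))
  expect_equal(rate_table(0, 136)$percent, 0)
  expect_error(rate_table(1, 0), "denominator")
  expect_error(rate_table(10, 5), "exceeds")
})

test_that("unadjusted_or matches the cross-product and the saturated logistic MLE", {
  expect_equal(unadjusted_or(1, 1, 1, 1)$odds_ratio, 1)
  # phenotype-D vs rest mortality cells
  r <- unadjusted_or(19, 37, 26, 322)
  expect_equal(r$odds_ratio, (19 * 322) / (37 * 26), tolerance = 1e-12)
  expect_lt(abs(r$odds_ratio - 6.36), 0.01)
  # oracle: saturated logistic regression on the expanded 2 x 2
  y <- c(rep(1, 19), rep(0, 37), rep(1, 26), rep(0, 322))
  x <- c(rep(1, 56), rep(0, 348))
  fit <- glm(y ~ x, family = binomial())
  expect_equal(r$odds_ratio, unname(exp(coef(fit)["x"])), tolerance = 1e-6)
  expect_equal(log(r$ci_high / r$ci_low) / (2 * qnorm(0.975)),
               unname(summary(fit)$coefficients["x", "Std. Error"]),
               tolerance = 1e-6)
})

test_that("zero cells get the Haldane-Anscombe correction with a flag", {
  r <- unadjusted_or(10, 0, 5, 5)
  expect_true(r$continuity_corrected)
  expect_equal(r$odds_ratio, (10.5 * 5.5) / (0.5 * 5.5), tolerance = 1e-12)
  expect_false(unadjusted_or(2, 3, 4, 5)$continuity_corrected)
})

test_that("OR confidence bounds bracket the estimate", {
  for (cells in list(c(19, 37, 26, 322), c(3, 133, 42, 226), c(5, 5, 5, 5))) {
    r <- do.call(unadjusted_or, as.list(cells))
    expect_lt(r$ci_low, r$odds_ratio)
    expect_gt(r$ci_high, r$odds_ratio)
  }
})

test_that("compare_groups picks the right test and controls type I error", {
  set.seed(1)
  n <- 50
  labels <- rep(c("A", "B", "C", "D"), each = n)
  null_hits <- 0
  for (rep_i in 1:20) {
    f <- data.frame(x1 = rnorm(4 * n), x2 = rexp(4 * n),
                    b1 = rbinom(4 * n, 1, 0.4))
    out <- compare_groups(f, labels)
    expect_setequal(out$test[out$variable %in% c("x1", "x2")],
                    "kruskal-wallis")
    null_hits <- null_hits + sum(out$significant)
  }
  # 20 replicates x 3 null variables: false discoveries should be rare
  expect_lt(null_hits / 60, 0.1)
  # a 3-SD shift must be detected
  f <- data.frame(x = c(rnorm(n, 3), rnorm(3 * n)))
  out <- compare_groups(f, labels)
  expect_true(out$significant)
  # sparse binary triggers Fisher
  fb <- data.frame(b = c(rbinom(30, 1, 0.05), rbinom(30, 1, 0.2)))
  out <- compare_groups(fb, rep(c("X", "Y"), each = 30))
  expect_equal(out$test, "fisher")
  # constant column is skipped with a reason
  out <- compare_groups(data.frame(k = rep(1, 4 * n)), labels)
  expect_match(out$note, "constant")
})

test_that("BH adjustment is monotone in the raw p-values", {
  set.seed(2)
  f <- as.data.frame(matrix(rnorm(200 * 8), 200))
  out <- compare_groups(f, rep(1:4, each = 50))
  o <- order(out$raw_p)
  expect_true(all(diff(out$adjusted_p[o]) >= -1e-12))
  expect_true(all(out$adjusted_p >= out$raw_p - 1e-12))
})

test_that("adjusted_or agrees with unadjusted under a null covariate", {
  set.seed(3)
  n <- 4000
  x <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, plogis(-2 + 0.8 * x))
  z <- rnorm(n)  # independent of everything
  ua <- unadjusted_or(sum(y & x), sum(!y & x), sum(y & !x), sum(!y & !x))
  ad <- adjusted_or(y, x, data.frame(z = z))
  se <- log(ad$ci_high / ad$ci_low) / (2 * qnorm(0.975))
  expect_lt(abs(log(ad$odds_ratio) - log(ua$odds_ratio)), 3 * se)
})

test_that("adjusted_or CI covers the truth at roughly the nominal rate", {
  set.seed(4)
  cover <- 0
  n <- 600
  for (i in 1:120) {
    x <- rbinom(n, 1, 0.4)
    z <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 0.5 * z))  # exposure truly null
    r <- adjusted_or(y, x, data.frame(z = z))
    cover <- cover + (r$ci_low <= 1 && 1 <= r$ci_high)
  }
  expect_gt(cover / 120, 0.88)
  expect_lt(cover / 120, 0.995)
})

test_that("adjusted_or refuses separated data", {
  y <- c(rep(1, 20), rep(0, 20))
  x <- y  # perfect separation
  expect_error(adjusted_or(y, x), "separation|single class")
})

test_that("organ-failure curves use non-nested daily observation", {
  ofi <- data.frame(
    patient_id = c("a", "a", "a", "b", "b", "c"),
    day = c(1, 2, 3, 1, 2, 1),
    ofi = c(2, 2, 4, 2, 0, 2))
  labels <- c(a = "X", b = "X", c = "X")
  cur <- organ_failure_curves(ofi, labels)
  expect_equal(cur$n_at_risk, c(3, 2, 1))
  expect_equal(cur$mean_ofi, c(2, 1, 4))  # day 3: only patient a remains
  # constant OFI: flat curve with zero-width CI
  flat <- data.frame(patient_id = rep(c("a", "b"), each = 2),
                     day = rep(1:2, 2), ofi = 2)
  cf <- organ_failure_curves(flat, c(a = "X", b = "X"))
  expect_equal(cf$mean_ofi, rep(2, 2))
  expect_equal(cf$lo, cf$hi)
})

test_that("mortality curves are monotone and end at the overall rate", {
  pats <- data.frame(patient_id = paste0("p", 1:10),
                     died = c(rep(TRUE, 3), rep(FALSE, 7)),
                     death_day = c(2, 2, 9, rep(NA, 7)))
  labels <- setNames(rep("X", 10), pats$patient_id)
  mc <- mortality_curves(pats, labels, n_days = 10)
  expect_true(all(diff(mc$cum_mortality) >= 0))
  expect_equal(mc$cum_mortality[mc$day == 1], 0)
  expect_equal(mc$cum_mortality[mc$day == 2], 0.2)
  expect_equal(mc$cum_mortality[mc$day == 10], 0.3)
  none <- mortality_curves(within(pats, died <- FALSE), labels, n_days = 5)
  expect_true(all(none$cum_mortality == 0))
})

test_that("chord links follow the direction rule", {
  set.seed(5)
  n <- 60
  base <- function() data.frame(
    temp_low = rnorm(2 * n, 37, 0.3), temp_high = rnorm(2 * n, 37.5, 0.3),
    crp = rlnorm(2 * n), ferritin = rlnorm(2 * n, 5),
    creatinine = rlnorm(2 * n, -0.7, 0.2), ofi_renal = 0,
    platelets = rnorm(2 * n, 250, 30), ofi_hematologic = 0,
    hemoglobin = rnorm(2 * n, 12), gcs = 15, ofi_cns = 0,
    ofi_total = rbinom(2 * n, 2, 0.3), ofi_pulmonary = 0, intubated = 0,
    heart_rate = rnorm(2 * n, 120, 10), sbp = rnorm(2 * n, 100, 8),
    ofi_cardiovascular = 0, ofi_hepatic = 0)
  labels <- rep(c("G1", "G2"), each = n)
  # identical groups: no links
  expect_equal(nrow(chord_links(base(), labels)), 0)
  # creatinine +2 SD in G2 -> renal link for G2
  f <- base()
  f$creatinine[labels == "G2"] <- f$creatinine[labels == "G2"] * 3
  links <- chord_links(f, labels)
  expect_true(any(links$phenotype == "G2" & links$category == "renal"))
  # platelets lower than cohort mean -> hematologic link (lower-is-link)
  f <- base()
  f$platelets[labels == "G2"] <- f$platelets[labels == "G2"] - 120
  links <- chord_links(f, labels)
  expect_true(any(links$phenotype == "G2" & links$category == "hematologic"))
  expect_false(any(links$phenotype == "G1" & links$category == "hematologic"))
})

test_that("biomarker log-ratios and their ordering match a hand oracle", {
  set.seed(6)
  labels <- rep(c("A", "B"), each = 30)
  bm <- data.frame(m1 = c(rep(2, 30), rep(2 * exp(1), 30)),
                   m2 = rlnorm(60), m3 = rlnorm(60, 2))
  lr <- biomarker_log_ratios(bm, labels)
  expect_equal(lr["m1", "B"], log(median(bm$m1[labels == "B"]) /
                                    median(bm$m1)), tolerance = 1e-12)
  # phenotype median equal to cohort median -> ratio 0; e-fold -> 1
  one <- data.frame(m = rep(5, 60))
  expect_equal(unname(biomarker_log_ratios(one, labels)["m", ]), c(0, 0))
  # 3-marker ordering equals brute-force average-linkage on the profiles
  lr3 <- biomarker_log_ratios(bm, labels)
  prof <- sapply(c("A", "B"), function(g) {
    vapply(bm, function(col) log(median(col[labels == g]) / median(col)),
           numeric(1))
  })
  ord <- hclust(dist(prof), method = "average")$order
  expect_equal(attr(lr3, "row_order"), rownames(prof)[ord])
  # zero-median marker is skipped with a message
  bm$z <- 0
  expect_message(lr <- biomarker_log_ratios(bm, labels), "zero")
  expect_false("z" %in% rownames(lr))
})

test_that("standardized profiles are z-scores of the plotted population", {
  set.seed(7)
  f <- data.frame(x = rnorm(80, 10, 2), y = rexp(80))
  labels <- rep(c("A", "B"), each = 40)
  surv <- rep(c(TRUE, FALSE), 40)
  prof <- standardized_profiles(f, labels, surv)
  # weighted mean over all strata must be 0 for every variable
  for (v in c("x", "y")) {
    rows <- prof[prof$variable == v, ]
    expect_equal(sum(rows$mean_z * rows$n) / sum(rows$n), 0,
                 tolerance = 1e-10)
  }
  # constructed +1 SD shift appears as +1
  f2 <- data.frame(x = c(rnorm(4000), rnorm(4000, 1)))
  l2 <- rep(c("A", "B"), each = 4000)
  p2 <- standardized_profiles(f2, l2, rep(TRUE, 8000))
  zb <- p2$mean_z[p2$phenotype == "B" & p2$survived]
  expect_lt(abs(zb - (0.5 / sd(f2$x))), 0.1)
  # low-count stratum flagged
  expect_true(all(p2$low_n_flag[p2$n == 0]))
})

test_that("picu_free_days gives zero for deaths", {
  pats <- data.frame(died = c(TRUE, FALSE, FALSE),
                     last_day = c(3, 10, 40))
  expect_equal(picu_free_days(pats), c(0, 20, 0))
})
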