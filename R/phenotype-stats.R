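# Phenotype association statistics: omnibus group comparisons with
# Benjamini-Hochberg adjustment, 2x2 and covariate-adjusted odds ratios,
# rate tables, daily organ-failure and mortality curves, chord-plot links,
# biomarker log-ratio heatmap inputs, and survival-stratified standardized
# profiles.

is_binaryish <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 5 && (all(u %in% 0:10) || is.factor(x) || is.character(x))
}

#' Compare every variable across phenotype groups
#'
#' Continuous variables use the Kruskal-Wallis test; categorical variables
#' use the chi-square test unless any expected cell count is below 5, in
#' which case Fisher's exact test is used. Raw p-values are
#' Benjamini-Hochberg adjusted across the variable family; significance is
#' adjusted p < 0.05. Constant variables are skipped with a reason.
#'
#' @param features data.frame of variables (a `patient_id` column is
#'   ignored).
#' @param labels group labels aligned with the rows.
#' @param p_adjust_method multiplicity adjustment (default `"BH"`).
#' @return data.frame: `variable`, `test`, `statistic`, `raw_p`,
#'   `adjusted_p`, `significant`, `note`.
#' @export
compare_groups <- function(features, labels, p_adjust_method = "BH") {
  stopifnot(length(unique(labels)) >= 2)
  x <- as.data.frame(features)
  x <- x[, setdiff(names(x), "patient_id"), drop = FALSE]
  labels <- as.factor(labels)
  if (any(table(labels) == 0)) stop("empty group", call. = FALSE)
  rows <- lapply(names(x), function(v) {
    col <- x[[v]]
    keep <- !is.na(col)
    if (length(unique(col[keep])) < 2) {
      return(data.frame(variable = v, test = NA, statistic = NA,
                        raw_p = NA, note = "constant variable: skipped",
                        stringsAsFactors = FALSE))
    }
    if (is_binaryish(col)) {
      tab <- table(col[keep], labels[keep])
      expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expct < 5)) {
        ft <- stats::fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 10,
                                 B = 1e4)
        data.frame(variable = v, test = "fisher", statistic = NA,
                   raw_p = ft$p.value, note = "", stringsAsFactors = FALSE)
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        data.frame(variable = v, test = "chi-square",
                   statistic = unname(ct$statistic), raw_p = ct$p.value,
                   note = "", stringsAsFactors = FALSE)
      }
    } else {
      kw <- stats::kruskal.test(col[keep], labels[keep])
      data.frame(variable = v, test = "kruskal-wallis",
                 statistic = unname(kw$statistic), raw_p = kw$p.value,
                 note = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  tested <- !is.na(out$raw_p)
  out$adjusted_p[tested] <- stats::p.adjust(out$raw_p[tested],
                                            method = p_adjust_method)
  out$significant <- !is.na(out$adjusted_p) & out$adjusted_p < 0.05
  out[, c("variable", "test", "statistic", "raw_p", "adjusted_p",
          "significant", "note")]
}

#' Percentage rate table
#'
#' @param counts event counts (named by group).
#' @param denominators group sizes, same length.
#' @return data.frame with `count`, `denominator`, `percent` (one decimal).
#' @export
rate_table <- function(counts, denominators) {
  stopifnot(length(counts) == length(denominators))
  if (any(denominators == 0)) stop("zero denominator", call. = FALSE)
  if (any(counts > denominators)) {
    stop("count exceeds denominator", call. = FALSE)
  }
  data.frame(group = names(counts) %||% seq_along(counts),
             count = as.vector(counts), denominator = as.vector(denominators),
             percent = round(100 * as.vector(counts) /
                               as.vector(denominators), 1),
             stringsAsFactors = FALSE)
}

#' Odds ratio from a 2x2 table
#'
#' Cross-product odds ratio with the Woolf log-normal 95% confidence
#' interval and a two-sided p-value from the log-OR z statistic. A zero
#' cell triggers the Haldane-Anscombe +0.5 correction, flagged in the
#' result.
#'
#' @param a,b,c,d cell counts: exposed-event, exposed-nonevent,
#'   unexposed-event, unexposed-nonevent.
#' @return data.frame: `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `adjusted` (FALSE), `continuity_corrected`.
#' @export
unadjusted_or <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(0.975)
  p <- 2 * stats::pnorm(-abs(log(or)) / se)
  data.frame(odds_ratio = or, ci_low = exp(log(or) - z * se),
             ci_high = exp(log(or) + z * se), p_value = p,
             adjusted = FALSE, continuity_corrected = corrected)
}

#' Covariate-adjusted odds ratio
#'
#' Maximum-likelihood logistic regression of a binary outcome on a binary
#' exposure plus adjustment covariates (by default age, sex, ethnicity,
#' race and total PRISM score in the shipped pipeline); the exposure
#' coefficient is exponentiated with a Wald 95% CI. Detected separation
#' aborts with a recommendation rather than returning a degenerate
#' estimate.
#'
#' @param outcome binary 0/1 vector.
#' @param exposure binary 0/1 vector.
#' @param covariates data.frame of adjustment covariates (may be NULL).
#' @return data.frame like [unadjusted_or()] with `adjusted = TRUE` and a
#'   `covariates` attribute.
#' @export
adjusted_or <- function(outcome, exposure, covariates = NULL) {
  df <- data.frame(.y = outcome, .x = as.numeric(exposure))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  if (stats::var(df$.y, na.rm = TRUE) == 0) {
    stop("outcome has a single class", call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  co <- summary(fit)$coefficients
  if (!fit$converged || abs(co[".x", "Estimate"]) > 15 ||
      co[".x", "Std. Error"] > 100) {
    stop("separation detected; consider a penalized (e.g. Firth) fit",
         call. = FALSE)
  }
  est <- co[".x", "Estimate"]
  se <- co[".x", "Std. Error"]
  z <- stats::qnorm(0.975)
  out <- data.frame(odds_ratio = exp(est), ci_low = exp(est - z * se),
                    ci_high = exp(est + z * se),
                    p_value = co[".x", "Pr(>|z|)"], adjusted = TRUE,
                    continuity_corrected = FALSE)
  attr(out, "covariates") <- names(covariates)
  out
}

#' Daily organ-failure curves by phenotype
#'
#' Mean OFI and 95% CI per day and phenotype, by non-nested daily
#' observation: a patient contributes to day d only while still in the
#' PICU on day d — the OFI is not carried forward after death or
#' discharge. Per-day at-risk counts are included.
#'
#' @param ofi_daily data.frame from [mof_labels()]` $ofi_daily` (needs
#'   `patient_id`, `day`, `ofi`).
#' @param labels named vector mapping patient_id to phenotype.
#' @return data.frame: `phenotype`, `day`, `mean_ofi`, `lo`, `hi`,
#'   `n_at_risk`.
#' @export
organ_failure_curves <- function(ofi_daily, labels) {
  ofi_daily$phenotype <- labels[ofi_daily$patient_id]
  grp <- interaction(ofi_daily$phenotype, ofi_daily$day, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ofi_daily, grp), function(g) {
    m <- mean(g$ofi)
    se <- if (nrow(g) > 1) stats::sd(g$ofi) / sqrt(nrow(g)) else 0
    data.frame(phenotype = g$phenotype[1], day = g$day[1], mean_ofi = m,
               lo = m - 1.96 * se, hi = m + 1.96 * se, n_at_risk = nrow(g),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$phenotype, agg$day), ]
  rownames(agg) <- NULL
  agg
}

#' Cumulative mortality curves by phenotype
#'
#' Cumulative deaths by day divided by the phenotype's size; monotone
#' nondecreasing by construction.
#'
#' @param patients data.frame with `patient_id`, `died`, `death_day`.
#' @param labels named vector mapping patient_id to phenotype.
#' @param n_days horizon (default 28).
#' @return data.frame: `phenotype`, `day`, `cum_mortality`.
#' @export
mortality_curves <- function(patients, labels, n_days = 28) {
  patients$phenotype <- labels[patients$patient_id]
  out <- do.call(rbind, lapply(split(patients, patients$phenotype),
                               function(g) {
    dd <- g$death_day[g$died & !is.na(g$death_day)]
    data.frame(phenotype = g$phenotype[1], day = seq_len(n_days),
               cum_mortality = vapply(seq_len(n_days),
                                      function(d) sum(dd <= d), 0) / nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# chord-plot variable categories and, per variable, whether a *lower*
# group mean signals involvement
CHORD_CATEGORIES <- list(
  inflammation = c("temp_low", "temp_high", "crp", "ferritin"),
  organ_failure = "ofi_total",
  pulmonary = c("ofi_pulmonary", "intubated"),
  cardiovascular = c("heart_rate", "sbp", "ofi_cardiovascular"),
  renal = c("creatinine", "ofi_renal"),
  hepatic = "ofi_hepatic",
  hematologic = c("hemoglobin", "platelets", "ofi_hematologic"),
  neurologic = c("gcs", "ofi_cns"))
CHORD_LOWER_IS_LINK <- c("temp_low", "sbp", "hemoglobin", "platelets", "gcs")

#' Chord-plot links between phenotypes and variable categories
#'
#' A phenotype links to a category when any member variable's group mean
#' differs from the overall cohort mean in the involvement direction —
#' lower for low temperature, systolic blood pressure, hemoglobin,
#' platelets and GCS; higher for every other variable — and (by default)
#' the phenotype-vs-rest contrast for that variable is significant after
#' Benjamini-Hochberg adjustment.
#'
#' @param features day-1 feature data.frame.
#' @param labels phenotype labels aligned with rows.
#' @param require_significance demand an adjusted-significant contrast in
#'   addition to the directional difference (default TRUE).
#' @return data.frame: `phenotype`, `category`, `variables` (the members
#'   driving the link).
#' @export
chord_links <- function(features, labels, require_significance = TRUE) {
  x <- as.data.frame(features)
  groups <- sort(unique(labels))
  vars <- intersect(unlist(CHORD_CATEGORIES), names(x))
  # phenotype-vs-rest contrasts per variable, BH-adjusted within variable
  sig <- matrix(TRUE, length(groups), length(vars),
                dimnames = list(groups, vars))
  if (require_significance) {
    for (v in vars) {
      p <- vapply(groups, function(g) {
        col <- x[[v]]
        keep <- !is.na(col)
        grp <- labels == g
        if (length(unique(col[keep])) < 2) return(1)
        if (is_binaryish(col)) {
          tab <- table(col[keep], grp[keep])
          expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
          if (any(expct < 5)) stats::fisher.test(tab)$p.value
          else suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
        } else {
          suppressWarnings(stats::wilcox.test(col[keep & grp],
                                              col[keep & !grp]))$p.value
        }
      }, numeric(1))
      sig[, v] <- stats::p.adjust(p, "BH") < 0.05
    }
  }
  rows <- list()
  for (g in groups) {
    for (cat in names(CHORD_CATEGORIES)) {
      members <- intersect(CHORD_CATEGORIES[[cat]], names(x))
      hit <- character(0)
      for (v in members) {
        gm <- mean(x[[v]][labels == g], na.rm = TRUE)
        om <- mean(x[[v]], na.rm = TRUE)
        dirhit <- if (v %in% CHORD_LOWER_IS_LINK) gm < om else gm > om
        if (isTRUE(dirhit) && sig[g, v]) hit <- c(hit, v)
      }
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          phenotype = g, category = cat,
          variables = paste(hit, collapse = ";"), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(phenotype = character(), category = character(),
                      variables = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Biomarker log-ratio matrix with hierarchical ordering
#'
#' For each biomarker and phenotype, the natural log of the ratio of the
#' phenotype median to the whole-cohort median. Rows (markers) and columns
#' (phenotypes) are ordered by average-linkage hierarchical clustering of
#' their ratio profiles (Euclidean distance). Markers with a zero cohort
#' median are skipped with a message.
#'
#' @param biomarkers data.frame of marker columns (plus optional
#'   `patient_id`).
#' @param labels phenotype labels aligned with rows.
#' @return matrix of log ratios (markers x phenotypes) with attributes
#'   `row_order` and `col_order`.
#' @export
biomarker_log_ratios <- function(biomarkers, labels) {
  x <- as.data.frame(biomarkers)
  x <- x[, setdiff(names(x), "patient_id"), drop = FALSE]
  stopifnot(ncol(x) >= 1)
  groups <- sort(unique(labels))
  keep <- vapply(x, function(col) {
    m <- stats::median(col, na.rm = TRUE)
    ok <- !is.na(m) && m != 0
    ok
  }, logical(1))
  skipped <- names(x)[!keep]
  if (length(skipped)) {
    message("skipping markers with zero cohort median: ",
            paste(skipped, collapse = ", "))
  }
  x <- x[, keep, drop = FALSE]
  ratio <- sapply(groups, function(g) {
    vapply(x, function(col) {
      log(stats::median(col[labels == g], na.rm = TRUE) /
            stats::median(col, na.rm = TRUE))
    }, numeric(1))
  })
  ratio <- matrix(ratio, nrow = ncol(x),
                  dimnames = list(names(x), as.character(groups)))
  row_order <- if (nrow(ratio) > 2) {
    stats::hclust(stats::dist(ratio), method = "average")$order
  } else {
    seq_len(nrow(ratio))
  }
  col_order <- if (ncol(ratio) > 2) {
    stats::hclust(stats::dist(t(ratio)), method = "average")$order
  } else {
    seq_len(ncol(ratio))
  }
  out <- ratio[row_order, col_order, drop = FALSE]
  attr(out, "row_order") <- rownames(ratio)[row_order]
  attr(out, "col_order") <- colnames(ratio)[col_order]
  out
}

#' Standardized variable profiles by phenotype and survival status
#'
#' Each variable is z-scored over the plotted population (mean 0, SD 1);
#' the survivor and non-survivor group means are returned per phenotype.
#' A stratum with fewer than `low_n` patients is flagged.
#'
#' @param features feature data.frame.
#' @param labels phenotype labels.
#' @param survived logical vector (TRUE = survivor).
#' @param low_n low-count flag threshold (default 5).
#' @return data.frame: `phenotype`, `survived`, `variable`, `mean_z`, `n`,
#'   `low_n_flag`.
#' @export
standardized_profiles <- function(features, labels, survived, low_n = 5) {
  x <- as.data.frame(features)
  x <- x[, setdiff(names(x), "patient_id"), drop = FALSE]
  z <- scale(data.matrix(x))
  rows <- list()
  for (g in sort(unique(labels))) {
    for (s in c(TRUE, FALSE)) {
      i <- which(labels == g & survived == s)
      for (v in colnames(z)) {
        rows[[length(rows) + 1L]] <- data.frame(
          phenotype = g, survived = s, variable = v,
          mean_z = if (length(i)) mean(z[i, v], na.rm = TRUE) else NA_real_,
          n = length(i), low_n_flag = length(i) < low_n,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' PICU-free days
#'
#' Days alive and out of the PICU within the horizon; deaths are assigned
#' 0 days.
#'
#' @param patients data.frame with `died` and `last_day`.
#' @param horizon follow-up horizon in days (default 30).
#' @return numeric vector.
#' @export
picu_free_days <- function(patients, horizon = 30) {
  ifelse(patients$died, 0, pmax(0, horizon - patients$last_day))
}
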