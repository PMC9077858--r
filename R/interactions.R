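# Heterogeneous treatment-interaction screening: univariable therapy
# selection, an elastic-net logistic model over all therapy main effects
# and pairwise interactions (the heatmap grid: T diagonal cells + C(T,2)
# off-diagonal cells), and logistic-regression confirmation of interactions
# flagged below an odds-ratio threshold.

#' Exposure indicator matrix from a cohort's therapy table
#'
#' One 0/1 column per therapy, rows aligned with `patients`; the
#' mechanical-ventilation indicator is derived from the day series.
#'
#' @param cohort a `pedsep_cohort`.
#' @return data.frame of 0/1 indicators with a `patient_id` column.
#' @export
therapy_exposures <- function(cohort) {
  ids <- cohort$patients$patient_id
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  out$mech_vent <- as.numeric(ids %in%
    cohort$days$patient_id[cohort$days$mech_vent %in% TRUE])
  for (tn in sort(unique(cohort$therapies$therapy))) {
    out[[tn]] <- as.numeric(ids %in%
      cohort$therapies$patient_id[cohort$therapies$therapy == tn])
  }
  out
}

#' Select therapies associated with outcome in univariable analysis
#'
#' A therapy is selected iff its unadjusted association with the outcome
#' has p < `alpha` in the population as a whole or within any phenotype
#' (chi-square, or Fisher's exact test when any expected cell count is
#' below 5). Therapies with zero exposed patients are excluded and listed
#' in the `excluded` attribute.
#'
#' @param exposures 0/1 indicator data.frame (plus optional `patient_id`).
#' @param outcome binary 0/1 vector.
#' @param labels optional phenotype labels for the within-phenotype tests.
#' @param alpha selection threshold (default 0.05).
#' @return character vector of selected therapy names, with attributes
#'   `p_values` (therapy x stratum matrix) and `excluded`.
#' @export
select_therapies <- function(exposures, outcome, labels = NULL,
                             alpha = 0.05) {
  x <- as.data.frame(exposures)
  x <- x[, setdiff(names(x), "patient_id"), drop = FALSE]
  excluded <- names(x)[colSums(x) == 0]
  x <- x[, setdiff(names(x), excluded), drop = FALSE]
  strata <- list(overall = rep(TRUE, length(outcome)))
  for (g in sort(unique(labels))) strata[[as.character(g)]] <- labels == g
  pmat <- matrix(NA_real_, ncol(x), length(strata),
                 dimnames = list(names(x), names(strata)))
  for (tn in names(x)) {
    for (sn in names(strata)) {
      i <- strata[[sn]]
      tab <- table(factor(x[[tn]][i], 0:1), factor(outcome[i], 0:1))
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      pmat[tn, sn] <- if (any(expct < 5)) {
        stats::fisher.test(tab)$p.value
      } else {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
      }
    }
  }
  selected <- rownames(pmat)[apply(pmat, 1, function(p) {
    any(!is.na(p) & p < alpha)
  })]
  structure(selected, p_values = pmat, excluded = excluded)
}

#' Design matrix of therapy main effects and pairwise interactions
#'
#' T main-effect columns plus all C(T, 2) pairwise product columns; column
#' names are deterministic (therapies in alphabetical order, products named
#' `a:b`).
#'
#' @param exposures 0/1 indicator data.frame of the selected therapies.
#' @return numeric matrix with `T + T(T-1)/2` columns.
#' @export
build_design <- function(exposures) {
  x <- as.data.frame(exposures)
  x <- x[, setdiff(names(x), "patient_id"), drop = FALSE]
  stopifnot(ncol(x) >= 1)
  nms <- sort(names(x))
  x <- data.matrix(x[nms])
  cols <- list()
  for (tn in nms) cols[[tn]] <- x[, tn]
  if (length(nms) > 1) {
    for (i in seq_len(length(nms) - 1)) {
      for (j in seq(i + 1, length(nms))) {
        cols[[paste0(nms[i], ":", nms[j])]] <- x[, i] * x[, j]
      }
    }
  }
  do.call(cbind, cols)
}

#' Penalized fit specification
#'
#' @param alpha elastic-net mixing parameter in (0, 1] (default 0.5).
#' @param nfolds cross-validation folds (default 10, minimum 3).
#' @param seed fold-assignment seed.
#' @param lambda optional lambda grid (default: glmnet's path).
#' @return list of class `pedsep_penalized_spec`.
#' @export
penalized_spec <- function(alpha = 0.5, nfolds = 10, seed = 1L,
                           lambda = NULL) {
  stopifnot(alpha > 0, alpha <= 1, nfolds >= 3)
  structure(list(alpha = alpha, nfolds = nfolds, seed = seed,
                 lambda = lambda), class = "pedsep_penalized_spec")
}

#' Elastic-net mortality grid over therapies and their interactions
#'
#' Fits a penalized logistic model of the outcome on all therapy main
#' effects and pairwise interactions within one phenotype stratum; lambda
#' is chosen at the minimum cross-validated deviance. Each grid cell holds
#' the unadjusted mortality odds ratio `exp(coefficient)` — diagonal cells
#' for single therapies, off-diagonal for combinations. Combinations with
#' no exposed patients are blank (NA). The penalized-path method yields no
#' confidence intervals by design. Strata with fewer than `min_deaths`
#' deaths are refused.
#'
#' @param exposures 0/1 indicator data.frame of the selected therapies.
#' @param outcome binary 0/1 vector.
#' @param spec a [penalized_spec()].
#' @param min_deaths minimum deaths required to fit (default 5).
#' @return object of class `pedsep_interaction_grid`: list with `grid`
#'   (T x T OR matrix), `cell_n` (patient counts), `therapies`, `fit`
#'   metadata.
#' @export
elastic_net_grid <- function(exposures, outcome, spec = penalized_spec(),
                             min_deaths = 5) {
  x <- build_design(exposures)
  y <- as.numeric(outcome)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class", call. = FALSE)
  }
  if (sum(y) < min_deaths) {
    stop(sprintf(
      "stratum not fitted: only %d deaths (< %d); too few events, as for the lowest-mortality phenotype",
      sum(y), min_deaths), call. = FALSE)
  }
  set.seed(spec$seed)
  foldid <- sample(rep_len(seq_len(spec$nfolds), length(y)))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = spec$alpha,
                          foldid = foldid, lambda = spec$lambda,
                          standardize = FALSE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  names(beta) <- colnames(x)

  nms <- sort(setdiff(names(as.data.frame(exposures)), "patient_id"))
  T_ <- length(nms)
  grid <- matrix(NA_real_, T_, T_, dimnames = list(nms, nms))
  cell_n <- matrix(0L, T_, T_, dimnames = list(nms, nms))
  for (i in seq_len(T_)) {
    cell_n[i, i] <- sum(x[, nms[i]])
    grid[i, i] <- exp(beta[nms[i]])
    if (i < T_) {
      for (j in seq(i + 1, T_)) {
        cn <- paste0(nms[i], ":", nms[j])
        cell_n[i, j] <- cell_n[j, i] <- sum(x[, cn])
        if (cell_n[i, j] > 0) {
          grid[i, j] <- grid[j, i] <- exp(beta[cn])
        }
      }
    }
  }
  structure(list(grid = grid, cell_n = cell_n, therapies = nms,
                 lambda_min = cv$lambda.min, alpha = spec$alpha,
                 n = length(y), deaths = sum(y)),
            class = "pedsep_interaction_grid")
}

#' @export
print.pedsep_interaction_grid <- function(x, ...) {
  cat(sprintf(
    "Elastic-net interaction grid: %d therapies, %d cells (%d blank), %d patients, %d deaths\n",
    length(x$therapies),
    length(x$therapies) * (length(x$therapies) + 1) / 2,
    sum(is.na(x$grid[upper.tri(x$grid, diag = TRUE)])), x$n, x$deaths))
  invisible(x)
}

#' Flag grid cells below an odds-ratio threshold
#'
#' @param grid a `pedsep_interaction_grid`.
#' @param threshold odds-ratio cutoff (default 0.1).
#' @return data.frame of flagged terms sorted by ascending OR: `term`,
#'   `therapy1`, `therapy2` (NA for single therapies), `odds_ratio`, `n`.
#' @export
flag_candidates <- function(grid, threshold = 0.1) {
  g <- grid$grid
  nms <- grid$therapies
  rows <- list()
  for (i in seq_along(nms)) {
    for (j in seq(i, length(nms))) {
      or <- g[i, j]
      if (!is.na(or) && or < threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          term = if (i == j) nms[i] else paste0(nms[i], ":", nms[j]),
          therapy1 = nms[i], therapy2 = if (i == j) NA else nms[j],
          odds_ratio = or, n = grid$cell_n[i, j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(term = character(), therapy1 = character(),
                      therapy2 = character(), odds_ratio = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$odds_ratio), , drop = FALSE]
}

#' Confirm a flagged interaction by logistic regression
#'
#' Maximum-likelihood logistic model of the outcome on both therapy main
#' effects, their product term and adjustment covariates (optionally plus
#' a phenotype-membership x combination term via `membership`). Reports
#' the product-term odds ratio with a Wald 95% CI and p-value.
#' Quasi-separation aborts with a recommendation — no silent fallback.
#'
#' @param outcome binary 0/1 vector.
#' @param therapy1,therapy2 0/1 exposure vectors (must be distinct
#'   therapies).
#' @param covariates data.frame of adjustment covariates (or NULL).
#' @param membership optional 0/1 phenotype-membership vector; when given,
#'   the reported term is membership x (therapy1 & therapy2).
#' @return data.frame like [adjusted_or()] for the interaction term.
#' @export
confirm_interaction <- function(outcome, therapy1, therapy2,
                                covariates = NULL, membership = NULL) {
  if (identical(as.numeric(therapy1), as.numeric(therapy2))) {
    stop("therapy interacted with itself is not a valid product term",
         call. = FALSE)
  }
  df <- data.frame(.y = as.numeric(outcome), .t1 = as.numeric(therapy1),
                   .t2 = as.numeric(therapy2))
  if (!is.null(membership)) {
    df$.combo <- df$.t1 * df$.t2
    df$.m <- as.numeric(membership)
    form <- .y ~ .t1 + .t2 + .combo + .m + .m:.combo
    term <- ".combo:.m"
  } else {
    form <- .y ~ .t1 * .t2
    term <- ".t1:.t2"
  }
  if (!is.null(covariates)) {
    df <- cbind(df, covariates)
    form <- stats::update(form, stats::as.formula(
      paste(". ~ . +", paste(names(covariates), collapse = " + "))))
  }
  fit <- suppressWarnings(stats::glm(form, data = df,
                                     family = stats::binomial()))
  co <- summary(fit)$coefficients
  if (!term %in% rownames(co)) term <- ".m:.combo"
  if (!fit$converged || abs(co[term, "Estimate"]) > 15 ||
      co[term, "Std. Error"] > 100) {
    stop("quasi-separation in the confirmation model; use exact or penalized inference",
         call. = FALSE)
  }
  est <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  z <- stats::qnorm(0.975)
  out <- data.frame(odds_ratio = exp(est), ci_low = exp(est - z * se),
                    ci_high = exp(est + z * se),
                    p_value = co[term, "Pr(>|z|)"], adjusted = !is.null(covariates),
                    continuity_corrected = FALSE)
  attr(out, "term") <- term
  out
}
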