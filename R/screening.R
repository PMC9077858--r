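#' Default day-1 variable schema
#'
#' The 25 clustering inputs: demographics (age, sex, ethnicity, previous
#' health, post-operative status), severity-window vitals and labs (most
#' abnormal in the first 6 h: systolic blood pressure, heart rate, GCS,
#' hemoglobin, creatinine, platelets, intubation), inflammation markers
#' (most abnormal within 24 h: low/high temperature, SIRS count, absolute
#' lymphocyte count, C-reactive protein, ferritin), the total organ failure
#' index and the six per-organ failure flags.
#'
#' @return data.frame with columns `name`, `kind`
#'   (continuous/binary/ordinal), `abnormal_direction`, `window`
#'   (`6h`/`24h`), `log_transform`, `cluster_input`.
#' @export
default_schema <- function() {
  s <- function(name, kind, dir, window, log) {
    data.frame(name = name, kind = kind, abnormal_direction = dir,
               window = window, log_transform = log, cluster_input = TRUE,
               stringsAsFactors = FALSE)
  }
  rbind(
    s("age", "continuous", "both", "24h", TRUE),
    s("male", "binary", "both", "24h", FALSE),
    s("hispanic", "binary", "both", "24h", FALSE),
    s("prev_healthy", "binary", "both", "24h", FALSE),
    s("post_op", "binary", "both", "24h", FALSE),
    s("sbp", "continuous", "low", "6h", TRUE),
    s("heart_rate", "continuous", "high", "6h", TRUE),
    s("gcs", "ordinal", "low", "6h", TRUE),
    s("hemoglobin", "continuous", "low", "6h", TRUE),
    s("creatinine", "continuous", "high", "6h", TRUE),
    s("platelets", "continuous", "low", "6h", TRUE),
    s("intubated", "binary", "high", "6h", FALSE),
    s("temp_low", "continuous", "low", "24h", TRUE),
    s("temp_high", "continuous", "high", "24h", TRUE),
    s("sirs", "ordinal", "high", "24h", TRUE),
    s("alc", "continuous", "low", "24h", TRUE),
    s("crp", "continuous", "high", "24h", TRUE),
    s("ferritin", "continuous", "high", "24h", TRUE),
    s("ofi_total", "ordinal", "high", "24h", TRUE),
    s("ofi_cardiovascular", "binary", "high", "24h", FALSE),
    s("ofi_pulmonary", "binary", "high", "24h", FALSE),
    s("ofi_renal", "binary", "high", "24h", FALSE),
    s("ofi_hepatic", "binary", "high", "24h", FALSE),
    s("ofi_hematologic", "binary", "high", "24h", FALSE),
    s("ofi_cns", "binary", "high", "24h", FALSE))
}

worst_value <- function(x, direction, anchor = NA) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  switch(direction,
         low = min(x),
         high = max(x),
         both = if (is.na(anchor)) x[1] else x[which.max(abs(x - anchor))])
}

#' Extract the day-1 feature vector for every patient
#'
#' For each schema variable, takes the most abnormal value inside its window
#' (the first 6 h for severity-score variables, the full first 24 h for
#' inflammation and organ-failure variables); the abnormal direction decides
#' whether minimum or maximum is "worst" (temperature contributes both its
#' low and high extreme). The SIRS count and the organ failure flags are
#' computed from the 24-h data with [sirs_count()] and [ofi_score()]. An
#' empty window yields a missing value, not an error.
#'
#' @param cohort a `pedsep_cohort`, or a list with `days` and `patients`.
#' @param schema variable schema, defaulting to [default_schema()].
#' @param rules a [rule_set()] for the organ-failure flags.
#' @return data.frame `patient_id` + the 25 schema variables (class
#'   `pedsep_day1_features`).
#' @export
extract_day1_features <- function(cohort, schema = default_schema(),
                                  rules = rule_set()) {
  days <- cohort$days
  patients <- cohort$patients
  d1 <- days[days$day == 1, , drop = FALSE]
  if (!nrow(d1)) stop("no day-1 rows in cohort", call. = FALSE)
  has_window <- "window" %in% names(d1)
  ids <- patients$patient_id
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)

  demo <- c("age", "male", "hispanic", "prev_healthy", "post_op")
  for (v in demo) out[[v]] <- patients[[v]][match(ids, patients$patient_id)]

  window_rows <- function(pid_rows, window) {
    if (window == "6h" && has_window) {
      r <- pid_rows[pid_rows$window == "0-6h", , drop = FALSE]
      if (nrow(r)) r else pid_rows
    } else {
      pid_rows
    }
  }
  split_d1 <- split(d1, d1$patient_id)
  measured <- setdiff(schema$name[schema$name %in% names(d1)], demo)
  for (v in measured) {
    dir <- schema$abnormal_direction[schema$name == v]
    win <- schema$window[schema$name == v]
    out[[v]] <- vapply(ids, function(pid) {
      rows <- split_d1[[pid]]
      if (is.null(rows)) return(NA_real_)
      as.numeric(worst_value(window_rows(rows, win)[[v]], dir,
                             VAR_ANCHORS[v]))
    }, numeric(1))
  }

  daily1 <- collapse_days(d1)
  flags <- organ_flags(daily1, rules)
  rowid <- match(ids, daily1$patient_id)
  out$ofi_total <- rowSums(flags)[rowid]
  for (org in colnames(flags)) {
    out[[paste0("ofi_", org)]] <- as.numeric(flags[rowid, org])
  }
  out$sirs <- vapply(seq_along(ids), function(i) {
    j <- rowid[i]
    if (is.na(j) || is.na(out$age[i])) return(NA_real_)
    as.numeric(sirs_count(daily1[j, ], age = out$age[i]))
  }, numeric(1))

  for (v in c("male", "hispanic", "prev_healthy", "post_op")) {
    out[[v]] <- as.numeric(out[[v]])
  }
  out <- out[, c("patient_id", schema$name), drop = FALSE]
  class(out) <- c("pedsep_day1_features", "data.frame")
  out
}

# pairwise association magnitude for mixed-type columns: Spearman rank
# correlation throughout (equivalent to the phi coefficient up to sign for
# two binaries and to a rank-biserial for mixed pairs)
mixed_cor <- function(x) {
  suppressWarnings(stats::cor(x, method = "spearman",
                              use = "pairwise.complete.obs"))
}

#' Screen candidate variables by missingness and correlation
#'
#' A variable is retained iff its missing fraction is below `miss_thresh`
#' and its absolute pairwise correlation with every other retained variable
#' is below `corr_thresh`. Columns failing the missingness rule are dropped
#' first; correlated pairs among the survivors are then eliminated greedily
#' in descending `|r|`, dropping the member with more missingness (ties:
#' the column later in table order).
#'
#' @param table data.frame of candidate columns (a `patient_id` column is
#'   ignored).
#' @param miss_thresh missingness threshold (default 0.20).
#' @param corr_thresh absolute-correlation threshold (default 0.60).
#' @return a `pedsep_screening_report`: data.frame with `variable`,
#'   `missing_fraction`, `max_abs_correlation`, `correlation_partner`,
#'   `retained`, `drop_reason`.
#' @export
screen_variables <- function(table, miss_thresh = 0.20, corr_thresh = 0.60) {
  stopifnot(miss_thresh > 0, miss_thresh < 1, corr_thresh > 0, corr_thresh < 1)
  x <- table[, setdiff(names(table), "patient_id"), drop = FALSE]
  if (ncol(x) < 2) stop("need at least two candidate columns", call. = FALSE)
  vars <- names(x)
  miss <- vapply(x, function(col) mean(is.na(col)), numeric(1))
  retained <- miss < miss_thresh
  reason <- ifelse(retained, "none", "missingness")

  xm <- data.matrix(x)
  cm <- mixed_cor(xm)
  diag(cm) <- 0
  cm[is.na(cm)] <- 0

  # greedy elimination among missingness survivors, descending |r|
  repeat {
    live <- which(retained)
    if (length(live) < 2) break
    sub <- abs(cm[live, live, drop = FALSE])
    mx <- max(sub)
    if (mx < corr_thresh) break
    ij <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- live[ij[1]]; b <- live[ij[2]]
    drop <- if (miss[a] > miss[b]) a else if (miss[b] > miss[a]) b else max(a, b)
    retained[drop] <- FALSE
    reason[drop] <- "correlation"
  }
  if (!any(retained)) {
    stop("screening eliminated every candidate column", call. = FALSE)
  }
  max_abs <- partner <- rep(NA, length(vars))
  for (i in seq_along(vars)) {
    others <- setdiff(which(retained), i)
    if (!length(others)) next
    j <- others[which.max(abs(cm[i, others]))]
    max_abs[i] <- abs(cm[i, j])
    partner[i] <- vars[j]
  }
  out <- data.frame(variable = vars, missing_fraction = unname(miss),
                    max_abs_correlation = max_abs,
                    correlation_partner = partner,
                    retained = unname(retained), drop_reason = reason,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("pedsep_screening_report", "data.frame")
  out
}

#' Impute remaining missing values
#'
#' Continuous columns get the column median; binary columns (values in
#' \{0, 1\}) get the column mode. The imputation mask is attached as the
#' `imputed` attribute.
#'
#' @param table data.frame of screened columns (plus optional `patient_id`).
#' @return completed data.frame.
#' @export
impute_features <- function(table) {
  vars <- setdiff(names(table), "patient_id")
  mask <- sapply(table[vars], is.na)
  for (v in vars) {
    col <- table[[v]]
    if (!any(is.na(col))) next
    if (all(is.na(col))) {
      stop("column entirely missing: ", v, call. = FALSE)
    }
    obs <- col[!is.na(col)]
    fill <- if (all(obs %in% c(0, 1))) {
      as.numeric(names(which.max(table(obs))))
    } else {
      stats::median(obs)
    }
    col[is.na(col)] <- fill
    table[[v]] <- col
  }
  attr(table, "imputed") <- mask
  table
}

#' Transform and standardize the feature table for clustering
#'
#' Applies `log(x + 1)` to log-flagged columns, then z-scores every column.
#' The per-column transform (log flag, mean, SD) is stored so that a new
#' raw patient can be mapped into the same standardized space (see
#' [apply_transform()]), and inverted exactly (see [invert_transform()]).
#'
#' @param table complete feature data.frame (plus optional `patient_id`).
#' @param schema variable schema giving the `log_transform` flags; columns
#'   absent from the schema are not log transformed.
#' @return a `pedsep_cohort_matrix`: list with the standardized matrix `x`,
#'   per-column `log_flag`, `center`, `scale`, and `patient_id`.
#' @export
transform_standardize <- function(table, schema = default_schema()) {
  ids <- table$patient_id
  vars <- setdiff(names(table), "patient_id")
  x <- data.matrix(table[vars])
  if (anyNA(x)) stop("table must be complete; run impute_features() first",
                     call. = FALSE)
  log_flag <- stats::setNames(vars %in% schema$name[schema$log_transform],
                              vars)
  x[, log_flag] <- log1p(x[, log_flag, drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance column(s): ",
         paste(vars[scl == 0], collapse = ", "), call. = FALSE)
  }
  xs <- scale(x, center = ctr, scale = scl)
  attr(xs, "scaled:center") <- attr(xs, "scaled:scale") <- NULL
  structure(list(x = xs, log_flag = log_flag, center = ctr, scale = scl,
                 patient_id = ids),
            class = "pedsep_cohort_matrix")
}

#' Map raw feature rows into (or back out of) a stored standardized space
#'
#' @param features data.frame of raw feature values (columns matching the
#'   stored transform; extra columns ignored; missing columns become NA).
#' @param cm a `pedsep_cohort_matrix` (or a phenotype model containing
#'   `log_flag`, `center`, `scale`).
#' @return `apply_transform`: numeric matrix in standardized space (NAs
#'   preserved). `invert_transform`: data.frame of raw values.
#' @export
apply_transform <- function(features, cm) {
  vars <- names(cm$center)
  x <- matrix(NA_real_, nrow(as.data.frame(features)), length(vars),
              dimnames = list(NULL, vars))
  features <- as.data.frame(features)
  for (v in intersect(vars, names(features))) x[, v] <- features[[v]]
  x[, cm$log_flag] <- log1p(x[, cm$log_flag, drop = FALSE])
  sweep(sweep(x, 2, cm$center), 2, cm$scale, "/")
}

#' @rdname apply_transform
#' @param z matrix of standardized values.
#' @export
invert_transform <- function(z, cm) {
  x <- sweep(sweep(z, 2, cm$scale, "*"), 2, cm$center, "+")
  x[, cm$log_flag] <- expm1(x[, cm$log_flag, drop = FALSE])
  as.data.frame(x)
}

#' @export
print.pedsep_cohort_matrix <- function(x, ...) {
  cat(sprintf("Standardized cohort matrix: %d patients x %d variables\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' @export
print.pedsep_screening_report <- function(x, ...) {
  cat(sprintf("Variable screening: %d of %d candidates retained\n",
              sum(x$retained), nrow(x)))
  NextMethod()
}
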