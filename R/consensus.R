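# Consensus k-means phenotype derivation: resampled k-means runs are
# summarized in a consensus matrix M(k) whose entry (i, j) is the fraction
# of runs co-clustering patients i and j among runs subsampling both; the
# number of clusters is chosen from the relative change in area under the
# CDF of consensus values.

#' Consensus matrix from recorded clustering runs
#'
#' The workhorse shared by [consensus_cluster()] and its tests: given the
#' subsample index sets and cluster labels of a series of runs, returns the
#' connectivity/co-sampling ratio matrix.
#'
#' @param idx_list list of integer vectors (patients sampled in each run).
#' @param label_list list of integer vectors (cluster labels, aligned with
#'   `idx_list`).
#' @param n total number of patients.
#' @return list with `M` (n x n consensus matrix, diagonal 1; pairs never
#'   co-sampled get 0), `cosampled` (count matrix) and `never_cosampled`
#'   (logical matrix marking pairs excluded from the CDF).
#' @export
consensus_matrix_from_runs <- function(idx_list, label_list, n) {
  conn <- matrix(0, n, n)
  cos <- matrix(0, n, n)
  for (r in seq_along(idx_list)) {
    idx <- idx_list[[r]]
    lab <- label_list[[r]]
    Z <- outer(lab, sort(unique(lab)), `==`) * 1
    conn[idx, idx] <- conn[idx, idx] + tcrossprod(Z)
    cos[idx, idx] <- cos[idx, idx] + 1
  }
  never <- cos == 0
  M <- ifelse(never, 0, conn / pmax(cos, 1))
  diag(M) <- 1
  list(M = M, cosampled = cos, never_cosampled = never & !diag(n))
}

#' Empirical CDF and area for a consensus matrix
#'
#' The CDF is over the upper-triangle consensus values (pairs never
#' co-sampled are excluded); the area is the integral of the CDF over
#' `[0, 1]` by the histogram (step) rule. All-zero entries give area 1,
#' all-one entries give area 0.
#'
#' @param M consensus matrix, or the list returned by
#'   [consensus_matrix_from_runs()].
#' @return list with `cdf` (a function) and `area`.
#' @export
cdf_area <- function(M) {
  excl <- NULL
  if (is.list(M) && !is.null(M$M)) {
    excl <- M$never_cosampled
    M <- M$M
  }
  up <- upper.tri(M)
  if (!is.null(excl)) up <- up & !excl
  v <- M[up]
  if (!length(v)) stop("no consensus values to summarize", call. = FALSE)
  cdf <- stats::ecdf(v)
  # integral of the right-continuous step CDF over [0, 1]
  xs <- sort(unique(v))
  xs_lo <- c(0, xs[xs < 1])
  xs_hi <- c(xs[xs < 1], 1)
  area <- sum(cdf(xs_lo) * (xs_hi - xs_lo))
  list(cdf = cdf, area = area)
}

#' Relative change in CDF area across k
#'
#' `delta(k_min)` is `A(k_min)` by convention; for larger k,
#' `delta(k) = (A(k) - A(k-1)) / A(k-1)`.
#'
#' @param areas named numeric vector of areas, names = consecutive k values.
#' @return named numeric vector of delta values (NA, flagged with a
#'   warning, where the previous area is 0).
#' @export
delta_area <- function(areas) {
  k <- as.integer(names(areas))
  stopifnot(!is.null(k), all(diff(k) == 1))
  d <- numeric(length(areas))
  d[1] <- areas[1]
  for (i in seq_along(areas)[-1]) {
    if (areas[i - 1] == 0) {
      warning("area at k=", k[i - 1], " is 0; delta undefined", call. = FALSE)
      d[i] <- NA_real_
    } else {
      d[i] <- (areas[i] - areas[i - 1]) / areas[i - 1]
    }
  }
  stats::setNames(d, names(areas))
}

#' Choose the number of clusters from the delta-area curve
#'
#' The chosen k is the largest k whose relative area gain is at least
#' `threshold` (adding clusters beyond it yields little statistical gain,
#' at a cost of overfitting). The choice is flagged ambiguous when the
#' curve is flat beyond the smallest k (every later delta below
#' `threshold / 2`) or when the chosen consensus matrix is diffuse — a
#' large share of its entries sit away from 0 and 1 (the proportion of
#' ambiguously clustered pairs, `pac`, exceeds `pac_limit`), as happens
#' for data without cluster structure.
#'
#' @param delta vector from [delta_area()].
#' @param threshold minimum relative gain (default 0.1).
#' @param pac proportion of consensus entries in (0.1, 0.9) at the chosen
#'   k (optional; supplied by [consensus_cluster()]).
#' @param pac_limit diffuseness bound (default 0.18: clearly above the
#'   0.05-0.12 range seen on structured cohorts, clearly below the 0.2+
#'   range seen when the phenotype separation is removed).
#' @return list with `k`, `ambiguous` and `pac`.
#' @export
select_k <- function(delta, threshold = 0.1, pac = NULL, pac_limit = 0.18) {
  k <- as.integer(names(delta))
  ok <- !is.na(delta) & delta >= threshold
  chosen <- if (any(ok)) max(k[ok]) else k[1]
  later <- delta[-1]
  flat <- length(later) > 0 && all(is.na(later) | later < threshold / 2)
  diffuse <- !is.null(pac) && !is.na(pac) && pac > pac_limit
  list(k = chosen, ambiguous = flat || diffuse, pac = pac)
}

#' Consensus k-means clustering with delta-area model selection
#'
#' For each k in `k_range`, runs `n_iterations` k-means fits on random
#' subsamples of `subsample_fraction` of the patients (all features
#' retained), accumulates the consensus matrix, computes the CDF area and
#' its relative change, selects k, and derives final labels and centroids
#' (see [final_labels()]). Reproducible from `seed`.
#'
#' @param cm a `pedsep_cohort_matrix` (or a bare numeric matrix).
#' @param k_range candidate cluster counts (default 2:6).
#' @param n_iterations resampling iterations per k (default 1000).
#' @param subsample_fraction fraction of patients per iteration (default 0.8).
#' @param threshold delta-area selection threshold (default 0.1).
#' @param seed master seed; per-(k, iteration) seeds derive from it.
#' @param nstart,iter_max k-means restarts and iteration cap per fit.
#' @param keep_runs record every subsample and label vector (for oracle
#'   checks on small problems).
#' @return object of class `pedsep_consensus`: list with `M` (per-k
#'   consensus matrices), `areas`, `delta`, `k`, `ambiguous`, `labels`,
#'   `centroids`, `phenotype_names`, the transform of `cm`, and `seed`.
#' @export
consensus_cluster <- function(cm, k_range = 2:6, n_iterations = 1000,
                              subsample_fraction = 0.8, threshold = 0.1,
                              seed = 1L, nstart = 10, iter_max = 300,
                              keep_runs = FALSE) {
  x <- if (inherits(cm, "pedsep_cohort_matrix")) cm$x else as.matrix(cm)
  if (anyNA(x)) stop("clustering input contains missing values", call. = FALSE)
  n <- nrow(x)
  if (min(k_range) < 2 || max(k_range) > n / 2) {
    stop("k_range must lie in [2, n/2]", call. = FALSE)
  }
  ns <- max(2L, floor(subsample_fraction * n))

  Ms <- list()
  runs <- list()
  areas <- numeric(length(k_range))
  names(areas) <- k_range
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    set.seed(seed + ki)
    conn <- matrix(0, n, n)
    cos <- matrix(0, n, n)
    if (keep_runs) runs[[as.character(k)]] <- list(idx = list(), lab = list())
    for (it in seq_len(n_iterations)) {
      idx <- sample.int(n, ns)
      km <- tryCatch(
        stats::kmeans(x[idx, , drop = FALSE], centers = k, nstart = nstart,
                      iter.max = iter_max),
        error = function(e) NULL)
      if (is.null(km)) next
      Z <- outer(km$cluster, seq_len(k), `==`) * 1
      conn[idx, idx] <- conn[idx, idx] + tcrossprod(Z)
      cos[idx, idx] <- cos[idx, idx] + 1
      if (keep_runs) {
        runs[[as.character(k)]]$idx[[it]] <- idx
        runs[[as.character(k)]]$lab[[it]] <- km$cluster
      }
    }
    never <- cos == 0
    if (any(never & !diag(n))) {
      warning("some pairs were never co-sampled at k=", k,
              "; their consensus entries are set to 0 and excluded from the CDF",
              call. = FALSE)
    }
    M <- ifelse(never, 0, conn / pmax(cos, 1))
    diag(M) <- 1
    Ms[[as.character(k)]] <- M
    areas[ki] <- cdf_area(list(M = M, never_cosampled = never & !diag(n)))$area
  }
  delta <- delta_area(areas)
  sel <- select_k(delta, threshold)
  Mk <- Ms[[as.character(sel$k)]]
  up <- Mk[upper.tri(Mk)]
  sel <- select_k(delta, threshold, pac = mean(up > 0.1 & up < 0.9))
  fl <- final_labels(Ms[[as.character(sel$k)]], x, sel$k)
  cn <- canonical_phenotype_names(fl$centroids, k = sel$k)

  structure(list(
    M = Ms, areas = areas, delta = delta, k = sel$k,
    ambiguous = sel$ambiguous, pac = sel$pac, labels = fl$labels,
    centroids = fl$centroids, phenotype_names = cn$map,
    name_scores = cn$scores,
    transform = if (inherits(cm, "pedsep_cohort_matrix")) {
      cm[c("log_flag", "center", "scale")]
    },
    patient_id = if (inherits(cm, "pedsep_cohort_matrix")) cm$patient_id,
    k_range = k_range, n_iterations = n_iterations,
    subsample_fraction = subsample_fraction, threshold = threshold,
    seed = seed, runs = if (keep_runs) runs),
    class = "pedsep_consensus")
}

#' @export
print.pedsep_consensus <- function(x, ...) {
  cat("Consensus k-means model\n")
  cat(sprintf("  k range %d-%d, %d iterations, subsample %.2f\n",
              min(x$k_range), max(x$k_range), x$n_iterations,
              x$subsample_fraction))
  cat(sprintf("  chosen k = %d%s\n", x$k,
              if (x$ambiguous) " (ambiguous: flat delta-area curve)" else ""))
  cat("  delta area:",
      paste(sprintf("k=%s %.3f", names(x$delta), x$delta), collapse = ", "),
      "\n")
  if (!is.null(x$phenotype_names)) {
    cat("  cluster sizes:\n")
    print(table(x$phenotype_names[x$labels]))
  }
  invisible(x)
}

#' Final labels and centroids from a consensus matrix
#'
#' Cuts an average-linkage hierarchical tree on distance `1 - M` at the
#' chosen k — the final partition uses the consensus evidence itself —
#' and computes per-cluster centroids in the standardized feature space.
#'
#' @param M consensus matrix at the chosen k.
#' @param x standardized feature matrix (rows aligned with `M`).
#' @param k number of clusters.
#' @return list with integer `labels` (1..k) and `centroids` (k x p).
#' @export
final_labels <- function(M, x, k) {
  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  labels <- stats::cutree(hc, k = k)
  if (length(unique(labels)) < k) {
    stop("consensus cut produced an empty cluster; consider a lower k",
         call. = FALSE)
  }
  centroids <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(x[labels == g, , drop = FALSE])
  }))
  rownames(centroids) <- seq_len(k)
  list(labels = labels, centroids = centroids)
}

# standardized-sign signatures of the four phenotypes: A young, previously
# healthy, low inflammation, high lymphocytes/platelets, high heart rate,
# low creatinine; B intubated with low GCS and pulmonary failure; C febrile
# with high GCS, lymphopenia, little pulmonary failure; D renal / hepatic /
# hematologic failure with thrombocytopenia and hyperferritinemia
PHENOTYPE_TEMPLATES <- list(
  A = c(age = -1, prev_healthy = 1, crp = -1, ferritin = -1, alc = 1,
        platelets = 1, heart_rate = 1, creatinine = -1, ofi_total = -1),
  B = c(intubated = 1, gcs = -1, ofi_pulmonary = 1, ofi_cns = 1,
        ofi_total = 1, alc = 0, temp_high = -1),
  C = c(temp_high = 1, gcs = 1, alc = -1, ofi_pulmonary = -1,
        intubated = -1, ferritin = 1),
  D = c(creatinine = 1, ofi_total = 1, ofi_renal = 1, ofi_hematologic = 1,
        ofi_hepatic = 1, platelets = -1, ferritin = 1))

#' Map clusters to canonical phenotype letters
#'
#' With k = 4, each cluster centroid is matched to the reference phenotype
#' signatures (standardized signs on age, platelets, lymphocytes,
#' intubation, GCS, temperature, creatinine, organ-failure pattern); the
#' bijection maximizing total signed agreement wins, with ties broken by
#' total agreement across all signature variables. For other k the clusters
#' are named `Cluster-1..k`.
#'
#' @param centroids k x p matrix in standardized space (columns named).
#' @param k number of clusters.
#' @return list with `map` (cluster index -> name) and `scores` (k x 4
#'   agreement matrix for k = 4, else NULL).
#' @export
canonical_phenotype_names <- function(centroids, k = nrow(centroids)) {
  if (k != 4) {
    return(list(map = stats::setNames(paste0("Cluster-", seq_len(k)),
                                      seq_len(k)),
                scores = NULL))
  }
  score <- matrix(0, 4, 4, dimnames = list(seq_len(4), names(PHENOTYPE_TEMPLATES)))
  for (ci in seq_len(4)) {
    for (tn in names(PHENOTYPE_TEMPLATES)) {
      tmpl <- PHENOTYPE_TEMPLATES[[tn]]
      vars <- intersect(names(tmpl), colnames(centroids))
      score[ci, tn] <- sum(tmpl[vars] * centroids[ci, vars])
    }
  }
  perms <- all_permutations(4)
  totals <- vapply(perms, function(p) sum(score[cbind(seq_len(4), p)]),
                   numeric(1))
  best <- perms[[which.max(totals)]]
  map <- stats::setNames(paste0("PedSep-", colnames(score)[best]), seq_len(4))
  list(map = map, scores = score)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Two-dimensional embedding for cluster visualization
#'
#' A deterministic principal-component embedding of the standardized
#' feature matrix, used only for plotting — never by any inference step.
#'
#' @param x standardized feature matrix (or `pedsep_cohort_matrix`).
#' @param labels optional cluster labels attached to the output.
#' @param seed accepted for interface symmetry; the embedding is
#'   deterministic.
#' @return data.frame with `dim1`, `dim2` and optional `label`.
#' @export
embed_2d <- function(x, labels = NULL, seed = 1L) {
  if (inherits(x, "pedsep_cohort_matrix")) x <- x$x
  if (nrow(x) < 5) stop("need at least 5 rows to embed", call. = FALSE)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  out <- data.frame(dim1 = pc$x[, 1], dim2 = pc$x[, 2])
  if (!is.null(labels)) out$label <- labels
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#'
#' @param a,b label vectors of equal length.
#' @return numeric in `[-1, 1]`; 1 iff the partitions coincide.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  nn <- comb2(length(a))
  expected <- sum_a * sum_b / nn
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
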