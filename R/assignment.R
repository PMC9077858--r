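# Bedside phenotype assignment: nearest centroid in the standardized
# training space, the simplest rule consistent with a k-means-derived model.

#' Assign individual patients to a derived phenotype
#'
#' Raw day-1 feature values are mapped into the model's standardized space
#' with the stored log/z transforms; missing inputs are imputed at the
#' training median (0 in standardized space) and counted. The nearest
#' centroid (Euclidean distance) wins; exact ties go to the lowest
#' canonical letter with `tie_flag` set. Membership weights are a softmax
#' of negative distances (descriptive only, not probabilities of class
#' membership).
#'
#' @param features data.frame of raw day-1 feature values (one or more
#'   rows; columns as in [extract_day1_features()]).
#' @param model a `pedsep_consensus` model (or one read by [read_model()])
#'   containing centroids and transforms.
#' @param max_missing maximum tolerated fraction of missing inputs
#'   (default 0.4); beyond it the patient is refused with the missing list.
#' @return data.frame of class `pedsep_assignment`: `label`, one
#'   `dist_<name>` column per phenotype, `weight_<name>` columns,
#'   `n_missing_inputs`, `tie_flag`.
#' @export
assign_phenotype <- function(features, model, max_missing = 0.4) {
  tr <- model$transform
  if (is.null(tr)) stop("model carries no stored transform", call. = FALSE)
  cent <- model$centroids
  nms <- model$phenotype_names %||%
    stats::setNames(paste0("Cluster-", seq_len(nrow(cent))),
                    seq_len(nrow(cent)))
  ord <- order(nms)
  features <- as.data.frame(features)
  z <- apply_transform(features, tr)
  p <- ncol(z)
  out <- NULL
  for (i in seq_len(nrow(z))) {
    zi <- z[i, ]
    miss <- is.na(zi)
    if (mean(miss) > max_missing) {
      stop(sprintf(
        "patient %d: %d of %d inputs missing (> %d%% allowed): %s",
        i, sum(miss), p, round(100 * max_missing),
        paste(names(zi)[miss], collapse = ", ")), call. = FALSE)
    }
    zi[miss] <- 0  # training median in standardized space
    d <- sqrt(colSums((t(cent[, colnames(z), drop = FALSE]) - zi)^2))
    names(d) <- nms
    d <- d[ord]
    w <- exp(-d)
    w <- w / sum(w)
    dmin <- min(d)
    tie <- sum(d - dmin < 1e-12) > 1
    label <- names(d)[d - dmin < 1e-12][1]  # lowest letter on ties
    row <- data.frame(label = label, t(d), t(w),
                      n_missing_inputs = sum(miss), tie_flag = tie,
                      stringsAsFactors = FALSE)
    names(row) <- c("label", paste0("dist_", names(d)),
                    paste0("weight_", names(d)), "n_missing_inputs",
                    "tie_flag")
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  class(out) <- c("pedsep_assignment", "data.frame")
  out
}

#' Outcome risk profile for a canonical phenotype
#'
#' Returns the phenotype's reference outcome rates (mortality and the
#' subsequent MOF phenotypes TAMOF, MAS, IPMOF, SMOF, NPMOF) from the
#' shipped reference table
#' (`inst/extdata/phenotype_outcome_rates.csv`). An unnamed cluster gets an
#' empty annotation.
#'
#' @param label `"A".."D"`, or `"PedSep-A".."PedSep-D"`; anything else
#'   (e.g. `"Cluster-2"`) returns an empty annotation.
#' @return one-row data.frame of percentage rates, or a zero-row frame for
#'   unnamed clusters.
#' @export
risk_annotation <- function(label) {
  tab <- utils::read.csv(system.file("extdata", "phenotype_outcome_rates.csv",
                                     package = "pedsep", mustWork = TRUE),
                         stringsAsFactors = FALSE)
  key <- ifelse(grepl("^PedSep-", label), label, paste0("PedSep-", label))
  out <- tab[tab$phenotype == key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a phenotype model file
#'
#' Serializes the parts of a consensus model needed for bedside assignment
#' (centroids, transforms, canonical names, selection summary) as
#' schema-versioned JSON.
#'
#' @param model a `pedsep_consensus`.
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns a
#'   list usable by [assign_phenotype()].
#' @export
write_model <- function(model, path) {
  obj <- list(
    schema = "pedsep-model/1",
    k = model$k,
    ambiguous = model$ambiguous,
    delta = as.list(model$delta),
    areas = as.list(model$areas),
    centroids = list(values = unname(model$centroids),
                     columns = colnames(model$centroids)),
    phenotype_names = as.list(model$phenotype_names),
    transform = list(log_flag = as.list(model$transform$log_flag),
                     center = as.list(model$transform$center),
                     scale = as.list(model$transform$scale)),
    seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "pedsep-model/1")) {
    stop("unrecognized model schema: ", obj$schema, call. = FALSE)
  }
  cent <- obj$centroids$values
  colnames(cent) <- obj$centroids$columns
  rownames(cent) <- seq_len(nrow(cent))
  structure(list(
    k = obj$k, ambiguous = obj$ambiguous,
    delta = unlist(obj$delta), areas = unlist(obj$areas),
    centroids = cent,
    phenotype_names = unlist(obj$phenotype_names),
    transform = list(log_flag = unlist(obj$transform$log_flag),
                     center = unlist(obj$transform$center),
                     scale = unlist(obj$transform$scale)),
    seed = obj$seed), class = "pedsep_consensus")
}
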