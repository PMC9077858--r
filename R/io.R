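# CSV readers/writers binding the pipeline stages. All tabular artifacts
# are plain UTF-8 CSV ("." decimal separator, empty cell = missing); the
# phenotype model file is schema-versioned JSON (see write_model()).

PATIENT_LEVEL_COLS <- c("phenotype", "age", "male", "hispanic", "white",
                        "prev_healthy", "post_op", "prism", "died",
                        "death_day", "discharge_day", "last_day")

#' Write / read a cohort as a long patient-day CSV
#'
#' One row per patient-day window; patient-level columns are repeated on
#' each row and split back out on read. Unknown columns survive a
#' round-trip untouched. Duplicate (patient, day, window) rows on read are
#' an error.
#'
#' @param cohort a `pedsep_cohort` (or any list with `days` and `patients`).
#' @param path CSV path.
#' @return `write_patient_days` returns `path` invisibly;
#'   `read_patient_days` returns a list of class `pedsep_cohort` with
#'   `days` and `patients` (truth/therapies are not part of the exchange
#'   format).
#' @export
write_patient_days <- function(cohort, path) {
  days <- cohort$days
  pat <- cohort$patients
  keep <- intersect(PATIENT_LEVEL_COLS, names(pat))
  merged <- cbind(days,
                  pat[match(days$patient_id, pat$patient_id), keep,
                      drop = FALSE])
  rownames(merged) <- NULL
  utils::write.csv(merged, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_patient_days
#' @export
read_patient_days <- function(path) {
  if (!file.size(path) > 0) stop("empty file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  required <- c("patient_id", "day")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$patient_id, df$day,
               if ("window" %in% names(df)) df$window else "")
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, day) rows: ",
         key[anyDuplicated(key)], call. = FALSE)
  }
  for (v in intersect(c("on_vasoactive", "mech_vent", "intubated", "sedated",
                        "male", "hispanic", "white", "prev_healthy",
                        "post_op", "died"), names(df))) {
    df[[v]] <- as.logical(df[[v]])
  }
  patient_cols <- intersect(PATIENT_LEVEL_COLS, names(df))
  pat <- df[!duplicated(df$patient_id), c("patient_id", patient_cols),
            drop = FALSE]
  rownames(pat) <- NULL
  days <- df[, setdiff(names(df), patient_cols), drop = FALSE]
  structure(list(days = days, patients = pat), class = "pedsep_cohort")
}

#' Write the MOF rule labels as CSV
#'
#' @param labels the `labels` element of [mof_labels()].
#' @param path CSV path.
#' @export
write_mof_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full derivation pipeline
#'
#' Simulate (or load) a cohort, label MOF phenotypes, build and screen the
#' candidate table, impute and standardize, run consensus clustering, name
#' the clusters, and write every artifact (cohort CSV, rule labels,
#' screening report, features, model JSON, group-comparison and outcome
#' summaries, organ-failure and mortality curves, interaction grid) into
#' `outdir`.
#'
#' @param config a [sim_config()]; ignored when `input` is given.
#' @param outdir output directory (created if needed).
#' @param seed global seed.
#' @param input optional path to an existing patient-day CSV.
#' @param n_iterations consensus resampling iterations (default 200).
#' @return (invisibly) a list with the cohort, screening report, matrix,
#'   model, labels and output paths.
#' @export
run_pipeline <- function(config = sim_config(), outdir, seed = 1L,
                         input = NULL, n_iterations = 200) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(outdir, f)

  cohort <- if (is.null(input)) {
    generate_cohort(config, seed = seed)
  } else {
    read_patient_days(input)
  }
  if (is.null(input)) write_patient_days(cohort, out("patient_days.csv"))

  rules <- rule_set()
  mof <- mof_labels(cohort, rules)
  write_mof_labels(mof$labels, out("mof_labels.csv"))

  cand <- make_candidate_table(cohort, seed = seed + 2L)
  report <- screen_variables(cand)
  utils::write.csv(report, out("screening_report.csv"), row.names = FALSE)
  retained <- report$variable[report$retained]
  feats <- impute_features(cand[, c("patient_id", retained)])
  utils::write.csv(feats, out("day1_features.csv"), row.names = FALSE)

  cmx <- transform_standardize(feats)
  model <- consensus_cluster(cmx, n_iterations = n_iterations, seed = seed)
  write_model(model, out("phenotype_model.json"))
  labs <- stats::setNames(model$phenotype_names[model$labels],
                          cmx$patient_id)
  utils::write.csv(
    data.frame(patient_id = cmx$patient_id, phenotype = unname(labs)),
    out("phenotype_labels.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(k = names(model$areas), area = model$areas,
               delta = model$delta),
    out("consensus_selection.csv"), row.names = FALSE)

  comp <- compare_groups(feats, labs[feats$patient_id])
  utils::write.csv(comp, out("group_comparisons.csv"), row.names = FALSE)

  # outcome summary by assigned phenotype (mortality and MOF rates)
  groups <- sort(unique(labs))
  mrow <- mof$labels[match(names(labs), mof$labels$patient_id), ]
  died <- cohort$patients$died[match(names(labs),
                                     cohort$patients$patient_id)]
  outcome_rows <- lapply(groups, function(g) {
    i <- labs == g
    data.frame(phenotype = g, n = sum(i),
               mortality_pct = round(100 * mean(died[i]), 1),
               tamof_pct = round(100 * mean(mrow$tamof[i]), 1),
               mas_pct = round(100 * mean(mrow$mas[i]), 1),
               ipmof_pct = round(100 * mean(mrow$ipmof[i]), 1),
               smof_pct = round(100 * mean(mrow$smof[i]), 1),
               npmof_pct = round(100 * mean(mrow$npmof[i]), 1),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, outcome_rows), out("outcome_summary.csv"),
                   row.names = FALSE)

  # resolved configuration and versions, for full regenerability
  if (is.null(input)) write_sim_config(config, out("resolved_config.yaml"))
  writeLines(c(sprintf("pedsep: %s",
                       as.character(utils::packageVersion("pedsep"))),
               sprintf("R: %s", getRversion()),
               sprintf("seed: %d", seed)),
             out("versions.txt"))

  ofc <- organ_failure_curves(mof$ofi_daily, labs)
  utils::write.csv(ofc, out("organ_failure_curves.csv"), row.names = FALSE)
  mc <- mortality_curves(cohort$patients, labs,
                         n_days = if (is.null(input)) config$n_days else 28)
  utils::write.csv(mc, out("mortality_curves.csv"), row.names = FALSE)

  expo <- therapy_exposures(cohort)
  died <- as.numeric(cohort$patients$died)
  sel <- select_therapies(expo, died, labs[expo$patient_id])
  grid_paths <- character(0)
  for (g in sort(unique(labs))) {
    i <- labs[expo$patient_id] == g
    gr <- tryCatch(
      elastic_net_grid(expo[i, , drop = FALSE], died[i],
                       penalized_spec(seed = seed)),
      error = function(e) {
        message(g, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(gr)) next
    f <- out(sprintf("interaction_grid_%s.csv", gsub("[^A-Za-z0-9]", "_", g)))
    utils::write.csv(grid_to_long(gr), f, row.names = FALSE)
    grid_paths <- c(grid_paths, f)
  }
  invisible(list(cohort = cohort, report = report, matrix = cmx,
                 model = model, labels = labs, selected_therapies = sel,
                 outdir = outdir))
}

grid_to_long <- function(gr) {
  nms <- gr$therapies
  rows <- list()
  for (i in seq_along(nms)) {
    for (j in seq(i, length(nms))) {
      rows[[length(rows) + 1L]] <- data.frame(
        therapy_i = nms[i], therapy_j = nms[j],
        odds_ratio = gr$grid[i, j], n = gr$cell_n[i, j],
        blank = is.na(gr$grid[i, j]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions, used by the shipped
#' `inst/scripts/pedsep.R` front end. Subcommands: `simulate` (write a
#' cohort CSV), `rules` (MOF labels for a cohort CSV), `screen`,
#' `cluster`, `assign` (batch nearest-centroid assignment from a model
#' JSON), `all` (the full pipeline via [run_pipeline()]).
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit code (0 on success, 2 on usage error).
#' @export
pedsep_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pedsep <subcommand> [--seed N] [--outdir DIR] [--config FILE]",
    "              [--input FILE] [--model FILE]",
    "subcommands: simulate | rules | screen | cluster | assign | all",
    sep = "\n")
  if (!length(args)) {
    message(usage)
    return(2L)
  }
  sub <- args[1]
  opt <- list(seed = 1L, outdir = ".", config = NULL, input = NULL,
              model = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      message("unknown or incomplete flag: ", args[i], "\n", usage)
      return(2L)
    }
    opt[[key]] <- if (key == "seed") as.integer(args[i + 1]) else args[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) read_sim_config(opt$config) else sim_config()
  dir.create(opt$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- tryCatch({
    switch(sub,
      simulate = {
        cohort <- generate_cohort(cfg, seed = opt$seed)
        write_patient_days(cohort, file.path(opt$outdir, "patient_days.csv"))
      },
      rules = {
        cohort <- read_patient_days(opt$input)
        write_mof_labels(mof_labels(cohort)$labels,
                         file.path(opt$outdir, "mof_labels.csv"))
      },
      screen = {
        cohort <- if (is.null(opt$input)) generate_cohort(cfg, opt$seed) else
          read_patient_days(opt$input)
        feats <- extract_day1_features(cohort)
        rep <- screen_variables(feats)
        utils::write.csv(rep, file.path(opt$outdir, "screening_report.csv"),
                         row.names = FALSE)
      },
      cluster = ,
      all = {
        run_pipeline(cfg, opt$outdir, seed = opt$seed, input = opt$input)
      },
      assign = {
        model <- read_model(opt$model)
        feats <- utils::read.csv(opt$input, stringsAsFactors = FALSE,
                                 na.strings = "")
        res <- assign_phenotype(feats, model)
        utils::write.csv(res, file.path(opt$outdir, "assignments.csv"),
                         row.names = FALSE)
      },
      {
        message("unknown subcommand: ", sub, "\n", usage)
        return(2L)
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  res
}
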