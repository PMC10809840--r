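#' Pipeline configuration
#'
#' Assembles (and optionally reads from a YAML file) the configuration for
#' the end-to-end pipeline: synthesis, feature extraction and reporting.
#' Any field may be overridden; unspecified fields keep their defaults.
#'
#' @param path optional YAML file; its entries override the defaults.
#' @param ... named overrides applied after the file (e.g.
#'   `seed = 7`, `synth = list(n_subjects = 4)`).
#' @return Nested list of class `nw_pipeline_config` with blocks `paths`
#'   (`out_dir`, `edf_dir`, `annotation_dir`), `synth` (`n_subjects` plus
#'   [synth_config()] arguments), `preprocess` ([preprocess_config()]
#'   arguments), `features` (`features`, `epoch_len`), `classify`
#'   (`schemes`, `fusion`, `contact`, `classifiers`) and `seed`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    paths = list(out_dir = "neowave_out", edf_dir = NULL,
                 annotation_dir = NULL),
    synth = list(n_subjects = 4),
    preprocess = list(),
    features = list(features = c("envelope", "sharpness", "don"),
                    epoch_len = 1),
    classify = list(schemes = 1:3, fusion = 3, contact = "C4-P4",
                    classifiers = c("svm", "knn", "lr", "nb")),
    seed = 1)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_rec(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_rec(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_rec(cfg, list(...))
  if (is.null(cfg$paths$edf_dir))
    cfg$paths$edf_dir <- file.path(cfg$paths$out_dir, "edf")
  if (is.null(cfg$paths$annotation_dir))
    cfg$paths$annotation_dir <- file.path(cfg$paths$out_dir, "annotations")
  structure(cfg, class = "nw_pipeline_config")
}

.subject_ids <- function(n) sprintf("subj%02d", seq_len(n))

#' Synthesize a cohort and write EDF + annotation fixtures
#'
#' One EDF recording and one rater-mask CSV per subject, seeded
#' deterministically from the pipeline seed (subject i uses
#' `seed * 1000 + i`), so a fixed configuration is idempotent.
#'
#' @param cfg an [pipeline_config()].
#' @param force overwrite a non-empty output directory.
#' @return Invisibly, the subject ids written.
#' @export
run_synth <- function(cfg, force = FALSE) {
  stopifnot(inherits(cfg, "nw_pipeline_config"))
  for (d in c(cfg$paths$edf_dir, cfg$paths$annotation_dir)) {
    if (dir.exists(d) && length(list.files(d)) && !force)
      stop("output directory not empty (use force = TRUE): ", d)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  sargs <- cfg$synth
  n_subj <- sargs$n_subjects
  sargs$n_subjects <- NULL
  ids <- .subject_ids(n_subj)
  for (i in seq_along(ids)) {
    sargs$seed <- cfg$seed * 1000 + i
    sc <- do.call(synth_config, sargs)
    out <- generate_recording(sc)
    write_edf(out$recording, file.path(cfg$paths$edf_dir,
                                       paste0(ids[i], ".edf")))
    write_annotations(out$annotations,
                      file.path(cfg$paths$annotation_dir,
                                paste0(ids[i], ".csv")))
  }
  invisible(ids)
}

#' Extract the labelled feature table for every subject
#'
#' Reads each EDF in the configured directory with its annotation CSV,
#' derives the bipolar montage when the channels are referential (labels
#' without `"-"`), runs the preprocessing chain, and extracts per-epoch
#' features at every fusion level. The combined table is written to
#' `features.csv` under the output directory.
#'
#' @param cfg an [pipeline_config()].
#' @return The feature table, invisibly.
#' @export
run_extract <- function(cfg) {
  stopifnot(inherits(cfg, "nw_pipeline_config"))
  edfs <- sort(list.files(cfg$paths$edf_dir, "\\.edf$", full.names = TRUE))
  if (!length(edfs)) stop("no EDF files in ", cfg$paths$edf_dir)
  pp <- do.call(preprocess_config, cfg$preprocess)
  tabs <- lapply(edfs, function(f) {
    id <- sub("\\.edf$", "", basename(f))
    annf <- file.path(cfg$paths$annotation_dir, paste0(id, ".csv"))
    if (!file.exists(annf))
      stop("missing annotation file for subject ", id, ": ", annf)
    rec <- read_edf(f)
    if (!any(grepl("-", rec$channel_labels, fixed = TRUE)))
      rec <- to_bipolar(rec)
    rec <- preprocess(rec, pp)
    feature_table(rec, read_annotations(annf), subject_id = id,
                  features = cfg$features$features,
                  epoch_len = cfg$features$epoch_len)
  })
  tab <- do.call(rbind, tabs)
  dir.create(cfg$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tab, file.path(cfg$paths$out_dir, "features.csv"),
                   row.names = FALSE)
  invisible(tab)
}

#' Group statistics and classification report
#'
#' From the extracted feature table: a repeated ANOVA per feature (period
#' x contact, consensus fusion), topography tables per feature and stage,
#' and classifier evaluations per feature x scheme. Writes `anova.csv`,
#' `topography.csv` and `classifier_report.json` under the output
#' directory. Schemes with an empty class are skipped with a message.
#'
#' @param cfg an [pipeline_config()].
#' @param table optionally, an in-memory feature table (otherwise
#'   `features.csv` is read).
#' @return List with `anova`, `topography`, `reports`, invisibly.
#' @export
run_report <- function(cfg, table = NULL) {
  stopifnot(inherits(cfg, "nw_pipeline_config"))
  if (is.null(table)) {
    f <- file.path(cfg$paths$out_dir, "features.csv")
    if (!file.exists(f)) stop("no feature table; run run_extract() first")
    table <- utils::read.csv(f)
  }
  feats <- intersect(cfg$features$features,
                     c("envelope", "sharpness", "don"))
  fusion <- cfg$classify$fusion
  anovas <- lapply(stats::setNames(feats, feats), function(f)
    repeated_anova(table, f, c("period", "contact"), fusion = fusion))
  an_tab <- do.call(rbind, lapply(feats, function(f)
    cbind(feature = f, anovas[[f]]$anova)))
  topo <- do.call(rbind, lapply(feats, function(f) {
    do.call(rbind, lapply(list(NULL, "S1", "S2", "S3"), function(st)
      cbind(feature = f, stage = if (is.null(st)) "S" else st,
            fusion = fusion, topography(table, f, fusion, st))))
  }))
  reports <- list()
  for (f in feats) for (sch in cfg$classify$schemes) {
    key <- paste0(f, "_scheme", sch)
    obs <- try(suppressMessages(
      make_observations(table, f, sch, fusion, cfg$classify$contact)),
      silent = TRUE)
    if (inherits(obs, "try-error")) {
      message("skipping ", key, ": ", attr(obs, "condition")$message)
      next
    }
    rep <- try(evaluate_classifiers(obs, cfg$classify$classifiers,
                                    seed = cfg$seed), silent = TRUE)
    if (inherits(rep, "try-error")) {
      message("skipping ", key, ": ", attr(rep, "condition")$message)
      next
    }
    reports[[key]] <- rep
  }
  dir.create(cfg$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(an_tab, file.path(cfg$paths$out_dir, "anova.csv"),
                   row.names = FALSE)
  utils::write.csv(topo, file.path(cfg$paths$out_dir, "topography.csv"),
                   row.names = FALSE)
  json <- lapply(reports, function(r) {
    lapply(r$results, function(x)
      list(accuracy = x$accuracy, sensitivity = x$sensitivity,
           specificity = x$specificity, auc = x$auc,
           roc = x$roc, calibration = x$calibration,
           params = as.list(x$params), seed = r$seed))
  })
  jsonlite::write_json(json, file.path(cfg$paths$out_dir,
                                       "classifier_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(anova = anovas, topography = topo, reports = reports))
}

#' Run the full pipeline
#'
#' [run_synth()] (unless EDF input already exists), [run_extract()],
#' then [run_report()].
#'
#' @param cfg an [pipeline_config()].
#' @param force passed to [run_synth()].
#' @return The [run_report()] result, invisibly.
#' @export
run_pipeline <- function(cfg, force = FALSE) {
  if (!dir.exists(cfg$paths$edf_dir) ||
      !length(list.files(cfg$paths$edf_dir, "\\.edf$")))
    run_synth(cfg, force)
  tab <- run_extract(cfg)
  run_report(cfg, tab)
}
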