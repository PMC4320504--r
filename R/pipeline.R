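#' Preprocess and fit every curve of a cohort
#'
#' For each record: smooth the full recording (span from the config of the
#' caller), split baseline/recovery at the protocol boundary, measure the
#' reference quantities, move to deviation coordinates, and run the
#' three-stage fit.
#'
#' @param cohort List of `cohort_record`s (from [generate_cohort()] or
#'   assembled from [read_roi_csv()] output).
#' @param protocol A [thermo_protocol()].
#' @param span Smoothing span (odd), default 5.
#' @param space A [search_space()].
#' @return The cohort with each record's `fit` slot filled.
#' @export
fit_cohort <- function(cohort, protocol = thermo_protocol(), span = 5L,
                       space = search_space()) {
  lapply(cohort, function(rec) {
    sm <- smooth_series(rec$series, span)
    ph <- segment_phases(sm, protocol)
    ref <- compute_reference(ph$baseline, ph$recovery)
    dev <- deviation_transform(ph$recovery, ref)
    rec$fit <- fit_curve(dev, ref, space)
    rec
  })
}

#' Default pipeline configuration
#'
#' The defaults reproduce the study's stated settings: 0.1 Hz sampling with
#' 1.5 min baseline / 2 min exercise / 5 min recovery, smoothing span 5,
#' exclusion threshold 1, the standard parameter search space, and a
#' synthetic cohort of 11 PsA and 9 HC subjects.
#'
#' @return A named list (class `pipeline_config`).
#' @export
default_config <- function() {
  structure(list(
    protocol = list(baseline_samples = 9L, exercise_samples = 12L,
                    recovery_samples = 30L, sampling_rate = 0.1),
    search_space = list(lt = c(0, 22), a = c(0.01, 30),
                        k = c(-5, 100), d = c(-5, 10)),
    smoothing_span = 5L,
    exclusion_threshold = 1,
    cohort = list(n_psa = 11L, n_hc = 9L, noise_sd = 0.04,
                  param_table = NULL),
    input_dir = NULL,
    seed = 20140101L,
    out_dir = NULL
  ), class = "pipeline_config")
}

#' Load and validate a pipeline configuration
#'
#' Reads a JSON configuration file, checks it strictly against the known
#' keys (unknown keys are rejected), fills defaults for anything omitted,
#' and validates types and value constraints (e.g. the smoothing span must
#' be odd).
#'
#' @param path Path to a JSON file; an empty file yields all defaults.
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nchar(trimws(txt)) == 0) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  cfg <- unclass(default_config())
  merge_strict <- function(base, upd, where) {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown))
      stop("unknown config key", if (length(unknown) > 1) "s", " ",
           if (nzchar(where)) paste0("in '", where, "'"), ": ",
           paste(unknown, collapse = ", "))
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
        if (!is.list(upd[[nm]])) stop("config key '", nm, "' must be an object")
        base[[nm]] <- merge_strict(base[[nm]], upd[[nm]], nm)
      } else base[[nm]] <- upd[[nm]]
    }
    base
  }
  cfg <- merge_strict(cfg, user, "")
  cfg$smoothing_span <- as.integer(cfg$smoothing_span)
  if (cfg$smoothing_span < 1L || cfg$smoothing_span %% 2L == 0L)
    stop("config error: smoothing_span must be odd and >= 1")
  if (!is.finite(cfg$exclusion_threshold) || cfg$exclusion_threshold < 0)
    stop("config error: exclusion_threshold must be non-negative")
  # these constructors own the detailed validation
  do.call(thermo_protocol, cfg$protocol)
  do.call(search_space, cfg$search_space)
  if (!is.null(cfg$cohort$n_psa) && (cfg$cohort$n_psa < 1 || cfg$cohort$n_hc < 1))
    stop("config error: cohort sizes must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Synthesize (or load) a cohort, preprocess and fit every curve, exclude
#' poor fits, run the per-ROI and pooled group comparisons, fit the
#' logistic region classifiers on the ROIs with at least one significant
#' parameter, select the ROC cutoff, and build the confusion matrices. All
#' intermediate artifacts and a machine-readable run report are written to
#' `config$out_dir` when set.
#'
#' @param config A `pipeline_config` (see [default_config()],
#'   [validate_config()]).
#' @return The run report (named list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  protocol <- do.call(thermo_protocol, config$protocol)
  space <- do.call(search_space, config$search_space)
  out_dir <- config$out_dir
  save_artifact <- function(obj, name, writer) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writer(obj, file.path(out_dir, name))
    }
  }

  # stage 1: cohort
  if (!is.null(config$input_dir)) {
    cohort <- load_cohort_dir(config$input_dir, protocol)
  } else {
    tbl <- if (is.null(config$cohort$param_table)) group_param_table() else
      group_param_table(config$cohort$param_table)
    cohort <- generate_cohort(tbl, config$cohort$n_psa, config$cohort$n_hc,
                              protocol, config$cohort$noise_sd, config$seed,
                              space)
    if (!is.null(out_dir)) write_cohort(cohort, file.path(out_dir, "cohort"), protocol)
  }
  n_in <- length(cohort)

  # stage 2: preprocess + fit
  cohort <- fit_cohort(cohort, protocol, config$smoothing_span, space)

  # stage 3: exclusion
  fits <- lapply(cohort, function(x) x$fit)
  costs <- vapply(fits, function(f) f$cost, numeric(1))
  keep <- costs <= config$exclusion_threshold
  excluded_by_group <- table(factor(
    vapply(cohort, function(x) x$group_label, character(1))[!keep],
    levels = c("PsA", "HC")))
  retained <- cohort[keep]
  fits_df <- fits_to_df(retained)
  save_artifact(fits_df, "fits.csv",
                function(o, p) utils::write.csv(o, p, row.names = FALSE))

  report <- list(
    n_curves_in = n_in,
    n_psa_in = sum(vapply(cohort, function(x) x$group_label, character(1)) == "PsA"),
    n_hc_in = n_in - sum(vapply(cohort, function(x) x$group_label, character(1)) == "PsA"),
    n_excluded = as.integer(sum(!keep)),
    excluded_by_group = as.list(excluded_by_group),
    n_retained = as.integer(sum(keep)),
    seed = config$seed)

  if (sum(keep) == 0) {
    warning("all curves excluded at threshold ", config$exclusion_threshold,
            "; statistical stages skipped")
    report$stats <- NULL
    save_artifact(report, "report.json",
                  function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA))
    return(invisible(report))
  }

  # stage 4: group comparisons
  stats_df <- region_stats(fits_df)
  save_artifact(stats_df, "region_stats.csv",
                function(o, p) utils::write.csv(o, p, row.names = FALSE))
  sig <- stats_df[stats_df$significant & stats_df$roi != "all", ]
  sig_rois <- unique(sig$roi)
  pooled <- stats_df[stats_df$roi == "all", ]
  report$significant_rois <- sig_rois
  report$pooled_significant <- pooled$parameter[pooled$significant]

  # stage 5: per-ROI classification on the candidate ROIs
  classification <- list()
  for (roi in sig_rois) {
    sub <- fits_df[fits_df$roi == roi, ]
    if (length(unique(sub$group)) < 2L || any(table(sub$group) < 2L)) next
    model <- tryCatch(fit_region_classifier(sub), error = function(e) NULL)
    if (is.null(model)) next
    roc <- roc_cutoff(model)
    cm <- classify_regions(model, roc$cutoff)
    classification[[roi]] <- list(
      coefficients = model$coefficients, separation = model$separation,
      cutoff = roc$cutoff, auc = roc$auc,
      confusion_percent = cm$percent, correct = cm$correct)
  }
  if (length(classification)) {
    overall <- vapply(classification, function(x) mean(x$correct), numeric(1))
    best_roi <- names(classification)[which.max(overall)]
    report$best_roi <- best_roi
    report$chosen_cutoff <- classification[[best_roi]]$cutoff
    report$confusion_matrix <- classification[[best_roi]]$confusion_percent
    report$correct_percent <- as.list(classification[[best_roi]]$correct)
    save_artifact(classification, "classification.json",
                  function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                                      digits = NA, force = TRUE))
  }
  report$classified_rois <- names(classification)
  save_artifact(report, "report.json",
                function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                                    digits = NA, force = TRUE))
  invisible(report)
}

#' Load a cohort written in the export dialect
#'
#' Reads every `*.csv` recording in a directory (file name = subject id;
#' subjects whose id starts with `PsA`/`HC` are labelled accordingly) and,
#' when present, attaches generating parameters from a
#' `ground_truth.json` sidecar.
#'
#' @param dir Directory of per-subject CSVs.
#' @param protocol A [thermo_protocol()].
#' @return A list of `cohort_record`s (fits unfilled).
#' @export
load_cohort_dir <- function(dir, protocol = thermo_protocol()) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no CSV recordings found in ", dir)
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::fromJSON(truth_path, simplifyVector = FALSE) else NULL
  truth_key <- if (!is.null(truth))
    vapply(truth, function(x) paste(x$subject_id, x$roi), character(1)) else character(0)
  records <- list()
  for (f in files) {
    sid <- sub("\\.csv$", "", basename(f))
    grp <- if (startsWith(sid, "PsA")) "PsA" else if (startsWith(sid, "HC")) "HC" else "unknown"
    series_list <- read_roi_csv(f, protocol, subject_id = sid, group_label = grp)
    for (s in series_list) {
      tp <- NULL; ref <- NULL
      hit <- match(paste(sid, s$roi), truth_key)
      if (!is.na(hit)) {
        tr <- truth[[hit]]
        tp <- model_params(tr$params$lt, tr$params$a, tr$params$d, tr$params$k)
        ref <- structure(list(T = tr$ref$T, y0 = tr$ref$y0, r = tr$ref$r),
                         class = "reference_signal")
      }
      records[[length(records) + 1L]] <- structure(
        list(subject_id = sid, group_label = grp, roi = s$roi,
             true_params = tp, ref = ref, series = s, fit = NULL),
        class = "cohort_record")
    }
  }
  records
}
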