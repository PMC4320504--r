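# Deterministic seed splitting: one master seed fans out into independent
# per-task stream seeds. All stochastic operations take an explicit seed and
# restore the caller's RNG state on exit.
split_seeds <- function(seed, n) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Default group-level parameter table
#'
#' Per-ROI means and standard deviations of the four model parameters for
#' the psoriatic-arthritis (PsA) and healthy-control (HC) populations, as
#' reported for 14 hand regions in the study this package models. Used as
#' the generative population of the synthetic cohort generator.
#'
#' @param path Optional path to a CSV with columns `roi_index, roi, group,
#'   lt_mean, lt_sd, a_mean, a_sd, d_mean, d_sd, k_mean, k_sd`; defaults to
#'   the packaged table.
#' @return A data.frame, one row per (ROI, group).
#' @export
group_param_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "group_params.csv", package = "thermofit",
                        mustWork = TRUE)
  df <- utils::read.csv(path)
  need <- c("roi_index", "roi", "group", "lt_mean", "lt_sd", "a_mean", "a_sd",
            "d_mean", "d_sd", "k_mean", "k_sd")
  if (!all(need %in% names(df)))
    stop("parameter table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df[, grep("_sd$", names(df))] < 0)) stop("parameter SDs must be >= 0")
  df
}

# One truncated-normal draw: resample until inside [lo, up] (max 100
# attempts), then clip. Degenerate sd = 0 returns the mean (clipped).
.rtruncnorm1 <- function(mean, sd, lo, up) {
  if (sd == 0) return(min(max(mean, lo), up))
  for (i in seq_len(100L)) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= up) return(x)
  }
  min(max(x, lo), up)
}

#' Draw one parameter set from a group population
#'
#' Each parameter is drawn from a normal distribution with the tabulated
#' mean and SD for the requested (group, ROI), truncated to the search
#' space by resampling (up to 100 attempts, then clipped). Reproducible
#' under the seed; the caller's RNG state is untouched.
#'
#' @param table A [group_param_table()].
#' @param group `"PsA"` or `"HC"`.
#' @param roi ROI label (see [roi_labels()]).
#' @param seed Integer seed.
#' @param space A [search_space()].
#' @return A `thermo_params`.
#' @export
draw_params <- function(table, group, roi, seed, space = search_space()) {
  row <- table[table$group == group & table$roi == roi, ]
  if (nrow(row) != 1L)
    stop(sprintf("no parameter-table entry for group '%s', ROI '%s'", group, roi))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  lo <- .space_lower(space); up <- .space_upper(space)
  model_params(
    lt = .rtruncnorm1(row$lt_mean, row$lt_sd, lo[["lt"]], up[["lt"]]),
    a  = .rtruncnorm1(row$a_mean,  row$a_sd,  lo[["a"]],  up[["a"]]),
    d  = .rtruncnorm1(row$d_mean,  row$d_sd,  lo[["d"]],  up[["d"]]),
    k  = .rtruncnorm1(row$k_mean,  row$k_sd,  lo[["k"]],  up[["k"]]))
}

#' Generate one synthetic recording
#'
#' Baseline phase: the basal temperature plus measurement noise. Recovery
#' phase: the switched feedback-model response in deviation coordinates,
#' shifted to absolute temperature by `y0`, plus noise. Noise is iid
#' Gaussian; the default SD mirrors the thermal resolution of research
#' infrared cameras (0.04 degC).
#'
#' @param params A `thermo_params` (the generating truth).
#' @param ref A `reference_signal` (basal `T`, post-exercise `y0`).
#' @param protocol A [thermo_protocol()].
#' @param noise_sd Measurement noise SD, degC, `>= 0`.
#' @param seed Integer seed.
#' @param roi,subject_id,group_label Metadata for the series.
#' @return A `temperature_series` of baseline + recovery samples.
#' @export
generate_curve <- function(params, ref, protocol = thermo_protocol(),
                           noise_sd = 0.04, seed = 1L,
                           roi = NA_character_, subject_id = NA_character_,
                           group_label = "unknown") {
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  nb <- protocol$baseline_samples
  nr <- protocol$recovery_samples
  rec_grid <- time_grid(nr, dt = 1, t0 = 0)
  dev <- simulate_response(params, ref$r, rec_grid)
  clean <- c(rep(ref$T, nb), dev$values + ref$y0)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  noisy <- clean + stats::rnorm(length(clean), 0, noise_sd)
  g <- structure(list(n_samples = nb + nr, dt = 1, t0 = 0), class = "time_grid")
  temperature_series(g, noisy, roi = roi, subject_id = subject_id,
                     group_label = group_label, check_window = FALSE)
}

#' Generate a labelled synthetic cohort
#'
#' One recording per subject x ROI with group-specific parameters drawn
#' from the population table. Per-subject basal temperature is drawn from
#' N(30, 1) degC and the deviation reference from N(0.8, 0.3) truncated
#' positive, with `y0 = T - r`. Defaults (11 PsA, 9 HC subjects, 14 ROIs)
#' give 154 + 126 = 280 curves.
#'
#' @param table A [group_param_table()].
#' @param n_psa,n_hc Subjects per group, `>= 1`.
#' @param protocol A [thermo_protocol()].
#' @param noise_sd Measurement noise SD, degC.
#' @param seed Master seed; all randomness derives from it.
#' @param space A [search_space()] used to truncate parameter draws.
#' @return A list of `cohort_record`s, each with `subject_id`,
#'   `group_label`, `roi`, `true_params`, `ref`, and `series`.
#' @export
generate_cohort <- function(table = group_param_table(), n_psa = 11L,
                            n_hc = 9L, protocol = thermo_protocol(),
                            noise_sd = 0.04, seed = 1L,
                            space = search_space()) {
  if (n_psa < 1L || n_hc < 1L) stop("need at least one subject per group")
  rois <- roi_labels()
  groups <- c(rep("PsA", n_psa), rep("HC", n_hc))
  subj_ids <- c(sprintf("PsA%02d", seq_len(n_psa)), sprintf("HC%02d", seq_len(n_hc)))
  n_sub <- length(groups)
  seeds <- split_seeds(seed, 2L * n_sub + n_sub * length(rois))
  subj_seeds <- seeds[seq_len(2L * n_sub)]
  curve_seeds <- matrix(seeds[-seq_len(2L * n_sub)], nrow = n_sub)
  records <- vector("list", n_sub * length(rois))
  idx <- 0L
  for (i in seq_len(n_sub)) {
    old <- .save_rng()
    set.seed(subj_seeds[2L * i - 1L])
    T_basal <- stats::rnorm(1L, 30, 1)
    set.seed(subj_seeds[2L * i])
    r_sub <- .rtruncnorm1(0.8, 0.3, lo = 1e-6, up = Inf)
    .restore_rng(old)
    ref <- structure(list(T = T_basal, y0 = T_basal - r_sub, r = r_sub),
                     class = "reference_signal")
    for (j in seq_along(rois)) {
      idx <- idx + 1L
      sd_pair <- split_seeds(curve_seeds[i, j], 2L)
      truth <- draw_params(table, groups[i], rois[[j]], sd_pair[1], space)
      series <- generate_curve(truth, ref, protocol, noise_sd, sd_pair[2],
                               roi = rois[[j]], subject_id = subj_ids[i],
                               group_label = groups[i])
      records[[idx]] <- structure(
        list(subject_id = subj_ids[i], group_label = groups[i],
             roi = rois[[j]], true_params = truth, ref = ref,
             series = series, fit = NULL),
        class = "cohort_record")
    }
  }
  records
}

#' Write a cohort to disk in the thermal-export dialect
#'
#' One CSV per subject (columns `time_s` then the 14 ROI labels), plus a
#' ground-truth JSON sidecar with every record's generating parameters and
#' reference quantities.
#'
#' @param cohort List of `cohort_record`s from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param protocol A [thermo_protocol()].
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir, protocol = thermo_protocol()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- split(cohort, vapply(cohort, function(x) x$subject_id, character(1)))
  paths <- character(0)
  for (sid in names(subjects)) {
    recs <- subjects[[sid]]
    p <- file.path(dir, paste0(sid, ".csv"))
    write_roi_csv(lapply(recs, function(x) x$series), p, protocol)
    paths <- c(paths, p)
  }
  truth <- lapply(cohort, function(x) {
    list(subject_id = x$subject_id, group = x$group_label, roi = x$roi,
         params = as.list(params_vector(x$true_params)),
         ref = list(T = x$ref$T, y0 = x$ref$y0, r = x$ref$r))
  })
  tp <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tp))
}
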