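#' Canonical region-of-interest labels
#'
#' The 14 hand-dorsum regions tracked over the finger joints, in their
#' conventional order: metacarpophalangeal joints (MCP), the thumb
#' interphalangeal joint (IP), and the proximal/distal interphalangeal
#' joints (IPP/IPD).
#'
#' @return Character vector of 14 labels, named `ROI1` ... `ROI14`.
#' @export
roi_labels <- function() {
  c(ROI1  = "I_MCP",   ROI2  = "thumb_IP", ROI3  = "II_MCP",  ROI4  = "I_IPP",
    ROI5  = "I_IPD",   ROI6  = "III_MCP",  ROI7  = "II_IPP",  ROI8  = "II_IPD",
    ROI9  = "IV_MCP",  ROI10 = "III_IPP",  ROI11 = "III_IPD", ROI12 = "V_MCP",
    ROI13 = "IV_IPP",  ROI14 = "IV_IPD")
}

#' Recording protocol
#'
#' Describes the acquisition protocol: a baseline recording, an unrecorded
#' isometric-exercise gap, and a recovery recording, all at a fixed sampling
#' rate. Defaults: 1.5 min baseline (9 samples), 2 min exercise (12 samples,
#' not recorded), 5 min recovery (30 samples), at 0.1 Hz.
#'
#' @param baseline_samples,exercise_samples,recovery_samples Phase durations
#'   in samples.
#' @param sampling_rate Sampling rate, Hz.
#' @return Object of class `thermo_protocol`.
#' @export
thermo_protocol <- function(baseline_samples = 9L, exercise_samples = 12L,
                            recovery_samples = 30L, sampling_rate = 0.1) {
  p <- list(baseline_samples = as.integer(baseline_samples),
            exercise_samples = as.integer(exercise_samples),
            recovery_samples = as.integer(recovery_samples),
            sampling_rate = sampling_rate)
  if (any(vapply(p, function(x) !is.finite(x) || x < 0, logical(1))))
    stop("protocol fields must be finite and non-negative")
  if (p$recovery_samples < 2L) stop("recovery must have at least 2 samples")
  if (p$sampling_rate <= 0) stop("sampling rate must be positive")
  structure(p, class = "thermo_protocol")
}

#' One region's temperature trace
#'
#' @param grid A `time_grid` (sample units).
#' @param values Temperatures, degrees C.
#' @param roi ROI label (one of [roi_labels()], or `NA`).
#' @param subject_id,group_label Cohort metadata; `group_label` is one of
#'   `"PsA"`, `"HC"`, `"unknown"`.
#' @param check_window Validate values against the plausibility window
#'   15-42 degrees C (out-of-window samples are masked to `NA` with a
#'   warning).
#' @return Object of class `temperature_series`.
#' @export
temperature_series <- function(grid, values, roi = NA_character_,
                               subject_id = NA_character_,
                               group_label = "unknown",
                               check_window = TRUE) {
  stopifnot(inherits(grid, "time_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_samples)
    stop("length of `values` must equal grid$n_samples")
  if (!group_label %in% c("PsA", "HC", "unknown"))
    stop("`group_label` must be 'PsA', 'HC' or 'unknown'")
  if (check_window) {
    bad <- which(is.finite(values) & (values < 15 | values > 42))
    if (length(bad)) {
      warning(sprintf("%d sample(s) outside the 15-42 degC window masked", length(bad)))
      values[bad] <- NA_real_
    }
  }
  structure(list(grid = grid, values = values, roi = roi,
                 subject_id = subject_id, group_label = group_label),
            class = "temperature_series")
}

# Linear interpolation of masked samples; refuses if more than 10% missing.
.impute_masked <- function(values) {
  miss <- !is.finite(values)
  if (!any(miss)) return(values)
  if (mean(miss) > 0.10)
    stop("more than 10% of samples missing/masked; series rejected")
  idx <- seq_along(values)
  stats::approx(idx[!miss], values[!miss], xout = idx, rule = 2)$y
}

#' Read a per-ROI thermal export
#'
#' Parses the CSV dialect written by thermal-camera ROI export software (and
#' by [write_cohort()]): a `time_s` column followed by one temperature column
#' per ROI, comma-separated, `.` decimal. Rows must be uniformly sampled at
#' the protocol rate and the row count must equal baseline + recovery
#' samples. Out-of-window temperatures are masked and linearly interpolated
#' (at most 10% per series).
#'
#' @param path CSV file path.
#' @param protocol A [thermo_protocol()].
#' @param subject_id,group_label Metadata attached to every series.
#' @return Named list of `temperature_series`, one per ROI column, keyed by
#'   ROI label (order-independent of the file's column order).
#' @export
read_roi_csv <- function(path, protocol = thermo_protocol(),
                         subject_id = NA_character_, group_label = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("format error: missing 'time_s' column")
  tt <- df$time_s
  step <- 1 / protocol$sampling_rate
  if (nrow(df) >= 2) {
    dtt <- diff(tt)
    if (max(abs(dtt - step)) > 1e-6 * step)
      stop("format error: time column is not uniformly sampled at the protocol rate")
  }
  n_expect <- protocol$baseline_samples + protocol$recovery_samples
  if (nrow(df) != n_expect)
    stop(sprintf("protocol error: expected %d rows (baseline + recovery), got %d",
                 n_expect, nrow(df)))
  rois <- setdiff(names(df), "time_s")
  known <- roi_labels()
  if (!all(rois %in% known))
    stop("labeling error: unknown ROI column(s): ",
         paste(setdiff(rois, known), collapse = ", "))
  grid <- time_grid(n_expect, dt = 1, t0 = 0)
  out <- lapply(rois, function(lab) {
    s <- temperature_series(grid, df[[lab]], roi = lab,
                            subject_id = subject_id, group_label = group_label)
    # series breaching the 10% missing-sample cap are rejected, not repaired
    tryCatch({
      s$values <- .impute_masked(s$values)
      s
    }, error = function(e) {
      warning(sprintf("ROI '%s' rejected: %s", lab, conditionMessage(e)))
      NULL
    })
  })
  names(out) <- rois
  out <- Filter(Negate(is.null), out)
  out[known[known %in% names(out)]]
}

#' Write one subject's recording in the export dialect
#'
#' @param series_list Named list of `temperature_series` (one per ROI).
#' @param path Output CSV path.
#' @param protocol A [thermo_protocol()] (sets the time column).
#' @return `path`, invisibly.
#' @export
write_roi_csv <- function(series_list, path, protocol = thermo_protocol()) {
  n <- series_list[[1]]$grid$n_samples
  df <- data.frame(time_s = (seq_len(n) - 1) / protocol$sampling_rate)
  for (s in series_list) df[[s$roi]] <- s$values
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Moving-average smoothing with shrinking edge windows
#'
#' Centred moving average of odd width `span`; near the edges the window
#' shrinks symmetrically (widths 1, 3, 5, ... at positions 1, 2, 3, ...),
#' so affine signals pass through unchanged and the output range never
#' exceeds the input range.
#'
#' @param series A `temperature_series` (or bare numeric vector).
#' @param span Window width in samples; odd, default 5.
#' @return Same type as the input, smoothed.
#' @export
smooth_series <- function(series, span = 5L) {
  span <- as.integer(span)
  if (span < 1L || span %% 2L == 0L) stop("`span` must be odd and >= 1")
  x <- if (inherits(series, "temperature_series")) series$values else as.numeric(series)
  n <- length(x)
  if (span > n) stop("`span` must not exceed the series length")
  hmax <- (span - 1L) %/% 2L
  out <- vapply(seq_len(n), function(i) {
    h <- min(hmax, i - 1L, n - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
  if (inherits(series, "temperature_series")) {
    series$values <- out
    series
  } else out
}

#' Split a recording into baseline and recovery phases
#'
#' The exercise gap is absent from the recording, so the series splits at
#' the protocol's baseline length. The recovery grid is re-origined to
#' `t0 = 0` (end of exercise).
#'
#' @param series A `temperature_series` of length baseline + recovery.
#' @param protocol A [thermo_protocol()].
#' @return List with elements `baseline` and `recovery`.
#' @export
segment_phases <- function(series, protocol = thermo_protocol()) {
  stopifnot(inherits(series, "temperature_series"))
  nb <- protocol$baseline_samples
  nr <- protocol$recovery_samples
  if (series$grid$n_samples != nb + nr)
    stop(sprintf("protocol error: series has %d samples, protocol implies %d",
                 series$grid$n_samples, nb + nr))
  baseline <- if (nb > 0L) {
    g <- structure(list(n_samples = nb, dt = series$grid$dt, t0 = 0),
                   class = "time_grid")
    temperature_series(g, series$values[seq_len(nb)], roi = series$roi,
                       subject_id = series$subject_id,
                       group_label = series$group_label, check_window = FALSE)
  } else NULL
  g <- structure(list(n_samples = nr, dt = series$grid$dt, t0 = 0),
                 class = "time_grid")
  recovery <- temperature_series(g, series$values[nb + seq_len(nr)],
                                 roi = series$roi,
                                 subject_id = series$subject_id,
                                 group_label = series$group_label,
                                 check_window = FALSE)
  list(baseline = baseline, recovery = recovery)
}

#' Measured reference quantities of one recording
#'
#' The basal temperature `T` is the time average of the baseline phase; the
#' post-exercise temperature `y0` is the first recovery sample; the
#' deviation reference is `r = T - y0`.
#'
#' @param baseline Baseline `temperature_series` (non-empty), or `NULL` if
#'   `T` is supplied explicitly.
#' @param recovery Recovery `temperature_series`.
#' @param T_basal Optional explicit basal temperature, degrees C.
#' @return Object of class `reference_signal` with fields `T`, `y0`, `r`.
#' @export
compute_reference <- function(baseline, recovery, T_basal = NULL) {
  stopifnot(inherits(recovery, "temperature_series"))
  if (is.null(T_basal)) {
    if (is.null(baseline) || baseline$grid$n_samples < 1L)
      stop("empty baseline: supply `T_basal` explicitly")
    T_basal <- mean(baseline$values)
  }
  y0 <- recovery$values[1]
  if (!is.finite(T_basal) || !is.finite(y0))
    stop("reference quantities must be finite")
  structure(list(T = T_basal, y0 = y0, r = T_basal - y0),
            class = "reference_signal")
}

#' Express a recovery trace in deviation coordinates
#'
#' Subtracts the post-exercise temperature `y0`, so the first sample of the
#' result is 0 by construction. Inverse of [to_absolute()].
#'
#' @param recovery Recovery `temperature_series`.
#' @param ref A `reference_signal` from [compute_reference()].
#' @return A `deviation_series`.
#' @export
deviation_transform <- function(recovery, ref) {
  stopifnot(inherits(recovery, "temperature_series"),
            inherits(ref, "reference_signal"))
  deviation_series(recovery$grid, recovery$values - ref$y0)
}
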