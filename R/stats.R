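#' Shapiro-Wilk normality test
#'
#' Thin wrapper used to screen each parameter's group distribution before
#' the rank-based comparisons.
#'
#' @param values Numeric vector, `3 <= n <= 5000`, not all equal.
#' @return List with elements `W` and `p`.
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("normality test requires between 3 and 5000 values")
  if (diff(range(values)) == 0)
    stop("degenerate input: all values identical")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

# Exact null distribution of the rank sum of a group of size n1 drawn from
# the pooled (midrank, tie-aware) ranks: a count dynamic programme over
# subsets, on doubled ranks so midranks stay integral.
.ranksum_exact_counts <- function(ranks2, n1) {
  smax <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n1)])
  # counts[k + 1, s + 1] = number of size-k subsets with doubled-rank sum s
  counts <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  counts[1L, 1L] <- 1
  for (r in ranks2) {
    kmax <- n1
    for (k in kmax:1) {
      shifted <- c(rep(0, r), counts[k, seq_len(smax + 1L - r)])
      counts[k + 1L, ] <- counts[k + 1L, ] + shifted
    }
  }
  counts[n1 + 1L, ]
}

#' Wilcoxon-Mann-Whitney comparison of two groups
#'
#' Reports the rank sum of the first group (midranks under ties), a z
#' statistic when the normal approximation is used, and a two-sided p
#' value. Small samples (`min(n1, n2) < 10`) use the exact permutation
#' distribution of the rank sum (tie-aware) and report no z; larger samples
#' use the normal approximation with tie-corrected variance.
#'
#' @param x,y Numeric vectors (first group = `x`, e.g. PsA).
#' @return List with `ranksum`, `z` (`NA` under the exact path), `p`, and
#'   `method`.
#' @export
group_compare <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  rk <- rank(c(x, y))
  w <- sum(rk[seq_len(n1)])
  e_w <- n1 * (n + 1) / 2
  ties <- table(rk)
  if (all(ties == n)) {
    warning("all observations tied; comparison is uninformative")
    return(list(ranksum = w, z = NA_real_, p = 1, method = "degenerate"))
  }
  exact_feasible <- min(n1, n2) < 10L && n <= 60L
  if (exact_feasible) {
    cnt <- .ranksum_exact_counts(as.integer(round(2 * rk)), n1)
    s <- (seq_along(cnt) - 1) / 2               # back to rank-sum units
    dev <- abs(w - e_w)
    p <- sum(cnt[abs(s - e_w) >= dev - 1e-9]) / sum(cnt)
    list(ranksum = w, z = NA_real_, p = min(1, p), method = "exact")
  } else {
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v_w <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (w - e_w) / sqrt(v_w)
    list(ranksum = w, z = z, p = 2 * stats::pnorm(-abs(z)),
         method = "normal-approximation")
  }
}

#' Per-ROI and pooled group comparisons of fitted parameters
#'
#' For each ROI (and pooled over all ROIs) and each model parameter,
#' reports group means/SDs, the rank-sum statistic of the PsA group, the z
#' statistic when available, the two-sided p value, and a significance flag
#' at alpha = 0.05.
#'
#' @param fits_df Data frame with columns `roi`, `group` and the parameter
#'   columns `lt`, `a`, `d`, `k` (see [fits_to_df()]).
#' @param alpha Significance level, default 0.05.
#' @return Data frame, one row per (ROI, parameter), with the pooled rows
#'   labelled `"all"`.
#' @export
region_stats <- function(fits_df, alpha = 0.05) {
  pars <- c("lt", "a", "d", "k")
  rois <- c(unique(fits_df$roi), "all")
  rows <- list()
  for (roi in rois) {
    sub <- if (roi == "all") fits_df else fits_df[fits_df$roi == roi, ]
    for (p in pars) {
      xa <- sub[[p]][sub$group == "PsA"]
      xh <- sub[[p]][sub$group == "HC"]
      if (!length(xa) || !length(xh)) {
        rows[[length(rows) + 1L]] <- data.frame(
          roi = roi, parameter = p,
          mean_psa = if (length(xa)) mean(xa) else NA_real_,
          sd_psa = NA_real_, mean_hc = if (length(xh)) mean(xh) else NA_real_,
          sd_hc = NA_real_, ranksum = NA_real_, z = NA_real_, p = NA_real_,
          significant = FALSE)
        next
      }
      gc <- group_compare(xa, xh)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi, parameter = p,
        mean_psa = mean(xa), sd_psa = stats::sd(xa),
        mean_hc = mean(xh), sd_hc = stats::sd(xh),
        ranksum = gc$ranksum, z = gc$z, p = gc$p,
        significant = gc$p < alpha)
    }
  }
  do.call(rbind, rows)
}

#' Logistic-regression region classifier
#'
#' Binary logistic regression of group membership (PsA vs HC, HC as the
#' reference class) on the four fitted model parameters, with intercept,
#' fitted by maximum likelihood. Reports coefficients, standard errors,
#' Wald statistics (`beta / SE`), two-sided p values, and odds ratios
#' `exp(beta)`. Perfect separation is detected and flagged rather than
#' silently diverging.
#'
#' @param records Data frame with columns `group` (`"PsA"`/`"HC"`) and
#'   `lt`, `a`, `d`, `k`; at least 2 records per class.
#' @return Object of class `logistic_model`: `coefficients` (data frame),
#'   `fitted` (per-record PsA probabilities), `labels`, `separation` flag,
#'   and the underlying `glm`.
#' @export
fit_region_classifier <- function(records) {
  need <- c("group", "lt", "a", "d", "k")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  y <- factor(records$group, levels = c("HC", "PsA"))
  if (any(table(y) < 2L)) stop("need at least 2 records per class")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ lt + a + d + k, data = records, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!sep && any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8))
    sep <- TRUE
  if (sep) warning("perfect or quasi-perfect separation detected; coefficients unstable")
  cf <- summary(fit)$coefficients
  coef_df <- data.frame(term = rownames(cf), beta = cf[, 1], se = cf[, 2],
                        wald = cf[, 1] / cf[, 2],
                        p = 2 * stats::pnorm(-abs(cf[, 1] / cf[, 2])),
                        exp_beta = exp(cf[, 1]), row.names = NULL)
  structure(list(coefficients = coef_df,
                 fitted = unname(fit$fitted.values),
                 labels = as.character(y), separation = sep, glm = fit),
            class = "logistic_model")
}

.model_probs <- function(model) {
  if (inherits(model, "logistic_model")) model$fitted else as.numeric(model)
}

#' ROC analysis and optimal cutoff
#'
#' Sweeps every distinct predicted probability as a candidate cutoff
#' (predict PsA iff probability >= cutoff), computes sensitivity and false
#' positive rate at each, and selects the cutoff maximising Youden's
#' J = sensitivity + specificity - 1. Ties on J are broken toward higher
#' sensitivity, then toward the higher cutoff. The AUC is the area under
#' the empirical ROC polygon (trapezoidal rule), which equals the
#' Mann-Whitney probability that a random PsA record scores above a random
#' HC record (ties counted half).
#'
#' @param model A `logistic_model`, or a numeric vector of PsA
#'   probabilities.
#' @param labels Character vector of true groups (`"PsA"`/`"HC"`); taken
#'   from the model if omitted.
#' @return Object of class `roc_result`: `curve` (data frame of threshold,
#'   sensitivity, fpr), `cutoff`, `youden`, `auc`.
#' @export
roc_cutoff <- function(model, labels = NULL) {
  probs <- .model_probs(model)
  if (is.null(labels) && inherits(model, "logistic_model"))
    labels <- model$labels
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  pos <- labels == "PsA"
  if (all(pos) || !any(pos)) stop("ROC undefined: labels contain one class only")
  th <- sort(unique(probs))
  sens <- vapply(th, function(c) mean(probs[pos] >= c), numeric(1))
  fpr <- vapply(th, function(c) mean(probs[!pos] >= c), numeric(1))
  j <- sens - fpr
  best <- order(-j, -sens, -th)[1]
  # empirical ROC polygon from (0,0) to (1,1), thresholds descending
  ox <- c(0, rev(fpr), 1)
  oy <- c(0, rev(sens), 1)
  auc <- sum(diff(ox) * (utils::head(oy, -1) + utils::tail(oy, -1)) / 2)
  structure(list(curve = data.frame(threshold = th, sensitivity = sens, fpr = fpr),
                 cutoff = th[best], youden = j[best], auc = auc),
            class = "roc_result")
}

#' Confusion matrix at a probability cutoff
#'
#' Predicts PsA for every record with probability at or above the cutoff
#' and cross-tabulates against the true groups as row-normalised
#' percentages (each true group's row sums to 100), plus the per-group
#' correct-classification percentage.
#'
#' @param model A `logistic_model` or numeric PsA probabilities.
#' @param cutoff Probability cutoff in (0, 1) (boundary values allowed for
#'   degenerate sweeps).
#' @param labels True groups; taken from the model if omitted.
#' @return Object of class `confusion_matrix`: `percent` (2x2 matrix, rows
#'   = original group, columns = predicted group) and `correct` (named
#'   vector of per-group correct percentages).
#' @export
classify_regions <- function(model, cutoff, labels = NULL) {
  probs <- .model_probs(model)
  if (is.null(labels) && inherits(model, "logistic_model"))
    labels <- model$labels
  pred <- ifelse(probs >= cutoff, "PsA", "HC")
  groups <- c("PsA", "HC")
  pct <- matrix(0, 2, 2, dimnames = list(original = groups, predicted = groups))
  for (g in groups) {
    in_g <- labels == g
    if (any(in_g))
      pct[g, ] <- 100 * c(mean(pred[in_g] == "PsA"), mean(pred[in_g] == "HC"))
  }
  structure(list(percent = pct,
                 correct = c(PsA = pct["PsA", "PsA"], HC = pct["HC", "HC"])),
            class = "confusion_matrix")
}

#' Collect fit results into a tidy data frame
#'
#' @param cohort List of `cohort_record`s whose `fit` slots are filled (see
#'   [fit_cohort()]), or a list of `fit_result`s with `meta` attributes.
#' @return Data frame with one row per fitted curve: `subject_id`, `group`,
#'   `roi`, the fitted `lt`, `a`, `d`, `k`, `cost`, `converged`, and the
#'   generating truth (`true_lt`, ...) when present.
#' @export
fits_to_df <- function(cohort) {
  rows <- lapply(cohort, function(rec) {
    f <- rec$fit
    if (is.null(f)) return(NULL)
    th <- params_vector(f$params)
    row <- data.frame(subject_id = rec$subject_id, group = rec$group_label,
                      roi = rec$roi, lt = th[["lt"]], a = th[["a"]],
                      d = th[["d"]], k = th[["k"]], cost = f$cost,
                      converged = f$converged)
    if (!is.null(rec$true_params)) {
      tt <- params_vector(rec$true_params)
      row$true_lt <- tt[["lt"]]; row$true_a <- tt[["a"]]
      row$true_d <- tt[["d"]]; row$true_k <- tt[["k"]]
    }
    row
  })
  do.call(rbind, rows)
}
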