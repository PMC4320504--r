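test_that("normality screen behaves under null and skewed alternatives", {
  seeds <- thermofit:::split_seeds(31, 100)
  null_p <- vapply(seeds, function(s) {
    set.seed(s); normality_test(rnorm(50))$p
  }, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.9)
  skew_p <- vapply(seeds, function(s) {
    set.seed(s); normality_test(abs(rnorm(50)))$p
  }, numeric(1))
  expect_gte(mean(skew_p < 0.05), 0.9)
  expect_error(normality_test(rep(1, 10)), "identical")
  expect_error(normality_test(rnorm(2)), "between 3 and 5000")
})

test_that("rank-sum comparison reproduces hand-enumerable exact cases", {
  # identical groups: no detectable shift
  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_true(is.na(same$z))
  # fully separated 3 vs 3: rank sum at its minimum 6, exact p = 2/20
  sep <- group_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$ranksum, 6)
  expect_equal(sep$p, 0.1)
  expect_equal(sep$method, "exact")
  # all tied: degenerate, p = 1 with a warning
  expect_warning(tied <- group_compare(rep(2, 4), rep(2, 5)), "tied")
  expect_equal(tied$p, 1)
})

test_that("exact p agrees with full enumeration and with wilcox.test when tie-free", {
  set.seed(17)
  for (i in 1:10) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- round(rnorm(n1), 1); y <- round(rnorm(n2, 0.5), 1)  # rounding creates ties
    gc <- group_compare(x, y)
    expect_equal(gc$p, enum_ranksum_p(x, y), tolerance = 1e-12)
  }
  # tie-free data: also matches the classical exact distribution
  set.seed(18)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(7, 1)
    expect_equal(group_compare(x, y)$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large samples use the tie-corrected normal approximation with a z statistic", {
  set.seed(21)
  x <- rnorm(60, 1); y <- rnorm(55)
  gc <- group_compare(x, y)
  expect_equal(gc$method, "normal-approximation")
  expect_false(is.na(gc$z))
  expect_lt(gc$p, 0.05)
  # z matches the direct formula on tie-free data
  n1 <- 60; n2 <- 55; n <- n1 + n2
  w <- sum(rank(c(x, y))[1:n1])
  z_direct <- (w - n1 * (n + 1) / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  expect_equal(gc$z, z_direct, tolerance = 1e-12)
})

test_that("per-region statistics table flags group differences at alpha 0.05", {
  set.seed(5)
  df <- data.frame(
    roi = rep(c("thumb_IP", "I_MCP"), each = 24),
    group = rep(rep(c("PsA", "HC"), each = 12), 2),
    lt = rnorm(48, 4), a = rnorm(48, 0.5, 0.1),
    d = c(rnorm(12, 0.5, 0.2), rnorm(12, -0.5, 0.2), rnorm(24, 0, 0.2)),
    k = rnorm(48, 0.3, 0.1))
  rs <- region_stats(df)
  expect_equal(nrow(rs), 12)                 # (2 ROIs + pooled) x 4 parameters
  d_thumb <- rs[rs$roi == "thumb_IP" & rs$parameter == "d", ]
  expect_true(d_thumb$significant)
  expect_lt(d_thumb$p, 1e-3)
  # the 10 null cells can throw the occasional 5% false positive, but most
  # must stay non-significant
  null_cells <- rs[!(rs$roi %in% c("thumb_IP", "all") & rs$parameter == "d"), ]
  expect_lte(sum(null_cells$significant), 2)
  expect_true(all(rs$p >= 0 & rs$p <= 1))
})

test_that("logistic classifier is calibrated under the null and flags separation", {
  seeds <- thermofit:::split_seeds(77, 60)
  null_rej <- vapply(seeds, function(s) {
    set.seed(s)
    df <- data.frame(group = rep(c("PsA", "HC"), each = 30),
                     lt = rnorm(60), a = rnorm(60), d = rnorm(60), k = rnorm(60))
    m <- fit_region_classifier(df)
    any(m$coefficients$p[-1] < 0.05)
  }, logical(1))
  # with 4 independent null features, all-p>0.05 should hold in >= 90% minus
  # multiplicity (~0.95^4); allow the binomial fluctuation
  expect_lte(mean(null_rej), 0.35)
  # a feature equal to the label separates perfectly and is flagged
  df_sep <- data.frame(group = rep(c("PsA", "HC"), each = 10),
                       lt = rep(c(1, 0), each = 10),
                       a = rnorm(20), d = rnorm(20), k = rnorm(20))
  expect_warning(m_sep <- fit_region_classifier(df_sep), "separation")
  expect_true(m_sep$separation)
})

test_that("logistic slope recovers the analytic log-odds of two equal-variance Gaussians", {
  # for classes N(+delta/2, s^2) vs N(-delta/2, s^2), the true slope is delta/s^2
  set.seed(404)
  delta <- 1.2; s <- 0.8
  n <- 500
  df <- data.frame(group = rep(c("PsA", "HC"), each = n),
                   lt = c(rnorm(n, delta / 2, s), rnorm(n, -delta / 2, s)),
                   a = rnorm(2 * n), d = rnorm(2 * n), k = rnorm(2 * n))
  m <- fit_region_classifier(df)
  row <- m$coefficients[m$coefficients$term == "lt", ]
  expect_lt(abs(row$beta - delta / s^2), 3 * row$se)
  # odds ratios are exactly exp(beta) for every coefficient
  expect_equal(m$coefficients$exp_beta, exp(m$coefficients$beta))
  # Wald statistic is beta / SE
  expect_equal(m$coefficients$wald, m$coefficients$beta / m$coefficients$se)
})

test_that("ROC cutoff maximises Youden's J with the highest-sensitivity tie-break", {
  # perfectly separated: AUC 1; the returned cutoff keeps every positive
  probs <- c(rep(0.1, 5), rep(0.9, 5))
  labels <- rep(c("HC", "PsA"), each = 5)
  roc <- roc_cutoff(probs, labels)
  expect_equal(roc$auc, 1)
  expect_equal(roc$cutoff, 0.9)
  expect_equal(roc$youden, 1)
  cm <- classify_regions(probs, roc$cutoff, labels)
  expect_equal(unname(cm$correct), c(100, 100))
  # constant probabilities: AUC exactly 1/2
  expect_equal(roc_cutoff(rep(0.4, 10), labels)$auc, 0.5)
  # random probabilities: AUC near 1/2
  set.seed(12)
  pr <- runif(2000)
  lb <- sample(rep(c("PsA", "HC"), 1000))
  expect_lt(abs(roc_cutoff(pr, lb)$auc - 0.5), 0.05)
  expect_error(roc_cutoff(rep(0.5, 4), rep("PsA", 4)), "one class")
})

test_that("AUC equals the rank-based Mann-Whitney probability and the pROC value", {
  set.seed(66)
  probs <- round(runif(80), 2)               # duplicates force tie handling
  labels <- sample(rep(c("PsA", "HC"), 40))
  roc <- roc_cutoff(probs, labels)
  pos <- probs[labels == "PsA"]; neg <- probs[labels == "HC"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(roc$auc, mean(cmp), tolerance = 1e-12)
  skip_if_not_installed("pROC")
  proc_auc <- as.numeric(pROC::auc(pROC::roc(labels, probs, levels = c("HC", "PsA"),
                                             direction = "<", quiet = TRUE)))
  expect_equal(roc$auc, proc_auc, tolerance = 1e-12)
})

test_that("confusion matrix is row-normalised with the >= cutoff convention", {
  probs <- c(0.95, 0.8, 0.7, 0.6, 0.45, 0.41, 0.39, 0.2, 0.35, 0.3,
             0.25, 0.15, 0.1, 0.05, 0.55, 0.02, 0.03, 0.04, 0.06)
  labels <- c(rep("PsA", 8), rep("HC", 11))
  cm <- classify_regions(probs, 0.4, labels)
  expect_equal(rowSums(cm$percent), c(PsA = 100, HC = 100))
  # 1 of 11 HC records sits at/above the cutoff (0.55): 90.91% correct
  expect_equal(unname(cm$correct[["HC"]]), 100 * 10 / 11, tolerance = 1e-9)
  # cutoff 0 predicts PsA for everyone
  cm0 <- classify_regions(probs, 0, labels)
  expect_equal(unname(cm0$percent["HC", ]), c(100, 0))
  # 9 HC with 1 misclassified: 88.89%
  cm9 <- classify_regions(c(rep(0.9, 3), rep(0.1, 8), 0.9), 0.4,
                          c(rep("PsA", 3), rep("HC", 8), "HC"))
  expect_equal(unname(cm9$correct[["HC"]]), 88.89, tolerance = 1e-3)
})
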