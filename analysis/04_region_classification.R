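#!/usr/bin/env Rscript
# Step 4 — region-based classification of PsA vs HC.
#
# For every region showing at least one significant parameter difference in
# step 3, fits a logistic regression of group on (LT, a, d, K), selects the
# probability cutoff by ROC analysis (Youden's J, ties broken toward
# sensitivity), and reports the in-sample confusion matrix. The region with
# the best balanced accuracy is highlighted.

suppressPackageStartupMessages(library(thermofit))

fits <- utils::read.csv("results/fits.csv")
stats <- utils::read.csv("results/region_stats.csv")

cand <- unique(stats$roi[stats$significant & stats$roi != "all"])
cat("candidate regions:", if (length(cand)) paste(cand, collapse = ", ") else "none", "\n\n")

classification <- list()
for (roi in cand) {
  sub <- fits[fits$roi == roi, ]
  if (any(table(sub$group) < 2)) next
  model <- tryCatch(suppressWarnings(fit_region_classifier(sub)),
                    error = function(e) NULL)
  if (is.null(model)) next
  roc <- roc_cutoff(model)
  cm <- classify_regions(model, roc$cutoff)
  classification[[roi]] <- list(coefficients = model$coefficients,
                                separation = model$separation,
                                cutoff = roc$cutoff, auc = roc$auc,
                                confusion_percent = cm$percent,
                                correct = as.list(cm$correct))
  cat(sprintf("%-8s AUC = %.3f, cutoff = %.3f, correct: PsA %.1f%%, HC %.1f%%%s\n",
              roi, roc$auc, roc$cutoff, cm$correct[["PsA"]], cm$correct[["HC"]],
              if (model$separation) "  [separation flagged]" else ""))
}

if (length(classification)) {
  jsonlite::write_json(classification, "results/classification.json",
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  balanced <- vapply(classification, function(x) mean(unlist(x$correct)), numeric(1))
  best <- names(classification)[which.max(balanced)]
  cat(sprintf("\nbest-discriminating region: %s (balanced accuracy %.1f%%)\n",
              best, max(balanced)))
  cat("details written to results/classification.json\n")
} else {
  cat("no region qualified for classification\n")
}
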