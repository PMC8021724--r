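#!/usr/bin/env Rscript
# Stage 2: apply the 14-item SIMPLE score to every infant at each of the
# six scheduled hours. Reads the cohort CSVs written by 01_simulate.R,
# writes results/scores.csv, and prints the per-hour score distributions
# by group (median and range), the shape in which such cohorts are
# usually reported.

library(simplepda)

cohort <- read_cohort("results/cohort")
scores <- score_cohort(cohort$infants, cohort$observations)
utils::write.csv(scores, "results/scores.csv", row.names = FALSE)

grp <- setNames(cohort$labels$group, cohort$labels$infant_id)
cat("SIMPLE totals by group, median (min-max):\n")
cat(sprintf("%6s  %-16s %-16s\n", "hour", "hsPDA cases", "controls"))
for (h in simple_schedule()) {
  sh <- scores[scores$hour == h, ]
  f <- function(v) sprintf("%g (%g-%g)", median(v), min(v), max(v))
  cat(sprintf("%5dh  %-16s %-16s\n", h,
              f(sh$total[grp[sh$infant_id] == "case"]),
              f(sh$total[grp[sh$infant_id] == "control"])))
}
cat(sprintf("\nMaximum attainable total: %d\n", sum(simple_item_maxima())))
cat("Written: results/scores.csv\n")
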