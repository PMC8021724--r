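#!/usr/bin/env Rscript
# Stage 1: generate the synthetic ELBW cohort.
#
# Emulates the study design: 48 infants (30 symptomatic hsPDA cases, 18
# controls), bedside observations at 6-72 h, echo at 24/48/72 h. Writes
# the four cohort CSVs under results/cohort/.

library(simplepda)

seed <- 1L
cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort")

cat(sprintf("Cohort: %d infants, %d cases (%.1f%%), %d controls; seed %d\n",
            nrow(cohort$infants), sum(cohort$labels$group == "case"),
            100 * mean(cohort$labels$group == "case"),
            sum(cohort$labels$group == "control"), seed))
cat(sprintf("Rejection-sampling acceptance rate: %.2f\n\n", cohort$acceptance_rate))

grp <- cohort$labels$group == "case"
cat("Item prevalences (cases vs controls):\n")
for (v in c("chorioamnionitis", "antenatal_steroid_complete")) {
  cat(sprintf("  %-28s %2d/30 vs %2d/18\n", v,
              sum(cohort$infants[[v]][grp]), sum(cohort$infants[[v]][!grp])))
}
hypo <- tapply(cohort$observations$hypotension_inotropes,
               cohort$observations$infant_id, max)[cohort$infants$infant_id]
cat(sprintf("  %-28s %2d/30 vs %2d/18\n", "hypotension (ever)",
            sum(hypo[grp]), sum(hypo[!grp])))
cat("\nWritten: results/cohort/{infants,observations,echo,labels}.csv\n")
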