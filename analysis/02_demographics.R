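#!/usr/bin/env Rscript
# Demographic comparison table: per-group summaries with uncorrected
# chi-square / pooled-t p-values against the reference group, mirroring a
# standard cohort table.
suppressPackageStartupMessages(library(taucovnet))

cohort <- read_cohort("results/cohort/values.csv",
                      "results/cohort/metadata.csv")
tab <- demographics_table(cohort, reference_group = "A4-T-")
write.csv(tab, "results/demographics.csv", row.names = FALSE)
print(tab, right = FALSE)
cat("\nWrote results/demographics.csv\n")
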