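#!/usr/bin/env Rscript
# Clinical correlations: Pearson r between regional uptake (within the
# ANOVA-significant mask) and FAQ score per group, and between CSF
# total-tau and regional/global uptake.
suppressPackageStartupMessages(library(taucovnet))

cohort <- read_cohort("results/cohort/values.csv",
                      "results/cohort/metadata.csv")
aov_res <- anova_regions(cohort, adjust_covariates = TRUE, fdr_q = 0.05)
mask <- aov_res$region[aov_res$significant]

faq_out <- NULL
for (grp in c("A4+T+", "A4+T-", "A4-T+")) {
  res <- correlate_with_score(cohort, mask, "faq", grp)
  nsig <- sum(res$p < 0.05 & res$r > 0)
  cat(sprintf("%-6s: %d/%d masked regions positively FAQ-correlated ",
              grp, nsig, nrow(res)))
  cat(sprintf("(mean r = %.2f)\n", mean(res$r)))
  faq_out <- rbind(faq_out, cbind(comparison = grp, res))
}
write.csv(faq_out, "results/faq_correlations.csv", row.names = FALSE)

csf <- correlate_csf_pet(cohort, "A4+T+")
regional <- csf[csf$region != "global_mean", ]
top <- regional[order(-abs(regional$r)), ][1:5, ]
cat("\nTop CSF T-Tau / uptake correlations in A4+T+:\n")
print(top, row.names = FALSE, digits = 3)
cat(sprintf("Global-mean correlation: r = %.3f (p = %.3g)\n",
            csf$r[csf$region == "global_mean"],
            csf$p[csf$region == "global_mean"]))
write.csv(csf, "results/csf_pet_correlations.csv", row.names = FALSE)
cat("\nWrote results/faq_correlations.csv and results/csf_pet_correlations.csv\n")
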