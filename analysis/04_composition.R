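#!/usr/bin/env Rscript
# Composite immune groups and their association with recurrence and stage:
# the cohort correlation table and Dunn's pairwise group comparisons.

library(immuneRecur)

fr <- read_matrix_tsv("results/fractions_percent.tsv")
clin <- read_clinical_tsv("results/cohort/clinical.tsv")
clin <- clin[clin$sample_id %in% colnames(fr), ]

comp <- build_composites(fr)
all_vals <- rbind(fr, comp)[, clin$sample_id]
tab <- correlation_table(all_vals, clin)
write.table(tab, "results/correlation_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

show <- c("T regs", "Plasma cells", "Monocyte-macrophage system",
          "Total nonTreg CD4", "Tregs/NonTreg", "Lymphocytes")
cat("correlation with recurrence (r, p):\n")
for (ct in show) {
  row <- tab[tab$cell_type == ct, ]
  cat(sprintf("  %-28s %+.2f  %.4f\n", ct, row$r_recurrence, row$p_recurrence))
}

grp <- ifelse(clin$recurrence == 1, "recurrent", "non-recurrent")
gc <- group_compare(fr["T regs", clin$sample_id], grp)
cat("Treg fraction, recurrent vs non-recurrent: z =",
    round(gc$pairs$z, 2), ", adjusted p =", signif(gc$pairs$p_adjusted, 3), "\n")
cat("written: results/correlation_table.tsv\n")
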