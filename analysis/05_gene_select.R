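#!/usr/bin/env Rscript
# Candidate prognostic genes: Welch tests and a univariate Cox screen over
# the filtered genes, correlation-network modules by Markov clustering
# (inflation 2.5, |r| > 0.30), and the GSEA-style ranked list with its
# bottom-5% tail.

library(immuneRecur)

expr <- read_matrix_tsv("results/expression_log2_preprocessed.tsv", scale = "log2")
clin <- read_clinical_tsv("results/cohort/clinical.tsv")
clin <- drop_missing_followup(clin)
clin <- clin[clin$sample_id %in% colnames(expr), ]
ex <- expr[, clin$sample_id]
grp <- factor(ifelse(clin$recurrence == 1, "recurrent", "non-recurrent"),
              levels = c("non-recurrent", "recurrent"))

welch <- welch_test(ex, grp)
cox <- cox_screen(ex, clin$time_months, clin$event)
cat("genes at nominal p < 0.05: Welch", sum(welch$p < 0.05, na.rm = TRUE),
    "| Cox", sum(cox$p < 0.05, na.rm = TRUE), "\n")

mods <- find_modules(ex, r_threshold = 0.30, inflation = 2.5)
cat("modules:", length(mods$modules), "covering",
    length(unlist(mods$modules)), "genes\n")

ranked <- gsea_rank(ex, grp)
cand <- prioritize(mods, setNames(welch$p, welch$gene), setNames(cox$p, cox$gene))
cat("candidate genes (module AND (Welch OR Cox)):", length(cand), "\n")
if (length(cand)) {
  tail_flags <- bottom5pct(ranked, cand)
  cat("candidates in the bottom 5% of the ranked list:", sum(tail_flags), "\n")
}

write.table(merge(welch, cox, by = "gene", suffixes = c("_welch", "_cox")),
            "results/gene_screens.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ranked, "results/gsea_ranked.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(cand, "results/candidate_genes.txt")
cat("written: results/gene_screens.tsv, results/gsea_ranked.tsv,",
    "results/candidate_genes.txt\n")
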