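#!/usr/bin/env Rscript
# Resolve the 22 leukocyte types per tumor by nu-SVR deconvolution against
# the reference signature, with 1000-permutation significance.

library(immuneRecur)

expr <- read_matrix_tsv("results/expression_linear_adjusted.tsv", scale = "linear")
sig <- read_matrix_tsv("results/cohort/signature.tsv")

dec <- deconvolve(expr, sig, permutations = 1000, seed = 1)
print(dec)
cat("samples with permutation p < 0.05:",
    sum(dec$perm_p < 0.05), "/", length(dec$perm_p), "\n")

write_matrix_tsv(fractions_percent(dec), "results/fractions_percent.tsv",
                 id_col = "cell_type")
diag <- data.frame(sample_id = colnames(dec$fractions), rmse = dec$rmse,
                   pearson_r = dec$pearson_r, perm_p = dec$perm_p,
                   chosen_nu = dec$chosen_nu)
write.table(diag, "results/deconvolution_diagnostics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("written: results/fractions_percent.tsv\n")
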