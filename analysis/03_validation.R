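#!/usr/bin/env Rscript
# Validation arm: CD45-normalized 40-Ct scores, per-marker two-tailed
# Mann-Whitney tests with BH-FDR, single-marker AUCs, and the combined
# logistic panel ROC.
library(ctcsig)

wells <- read.delim("results/qpcr_wells.tsv")
d <- structure(wells, ref_gene = "CD45", ct_floor = 40,
               class = c("qpcr_dataset", "data.frame"))
res <- suppressWarnings(run_validation(d, out_dir = "results/validation"))

print(res$marker_table, digits = 3)
cat(sprintf("\n%d of %d markers significant at FDR 0.05\n",
            sum(res$marker_table$q < 0.05), nrow(res$marker_table)))
cat(sprintf("combined panel AUC %.3f (95%% CI %.2f-%.2f)\n",
            res$panel$auc, res$panel$auc_ci[1], res$panel$auc_ci[2]))
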