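#!/usr/bin/env Rscript
# Generates the synthetic study data used by the downstream analysis steps:
# a discovery array cohort (9 patients, 6 healthy donors) written as
# Agilent-style spot tables, and a qPCR validation cohort (28 patients,
# 15 controls) with linked survival follow-up.
library(ctcsig)

seed <- 1L
out <- "results"
dir.create(file.path(out, "arrays"), showWarnings = FALSE, recursive = TRUE)

## discovery arrays -----------------------------------------------------------
cfg <- array_sim_config(seed = seed)  # 2000 genes, 40 spiked CTC genes
sim <- simulate_array_cohort(cfg)
for (nm in names(sim$tables))
  write_spot_table(sim$tables[[nm]], file.path(out, "arrays",
                                               paste0(nm, ".txt")))
truth <- data.frame(gene = names(sim$truth$occupancy),
                    patient_occupancy = as.integer(sim$truth$occupancy))
write.table(truth, file.path(out, "arrays_ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("wrote %d spot tables (%d spiked CTC genes, %d with occupancy >= 5)\n",
            length(sim$tables), nrow(truth), sum(truth$patient_occupancy >= 5)))

## qPCR validation cohort -----------------------------------------------------
vcfg <- qpcr_sim_config(seed = seed)
d <- simulate_qpcr_cohort(vcfg)
write.table(d, file.path(out, "qpcr_wells.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

sm <- score_matrix(normalize_ct(d))
pat <- rownames(sm)[grepl("^P", rownames(sm))]
sv <- simulate_survival(vcfg, sm[pat, ])
write.table(sv, file.path(out, "survival.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("wrote qPCR wells for %d samples and survival for %d patients (%d events)\n",
            length(unique(d$sample_id)), nrow(sv), sum(sv$event)))
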