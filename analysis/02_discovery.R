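#!/usr/bin/env Rscript
# Discovery arm: spot QC filtering, detection calls, quantile normalization,
# probe collapse, and background-subtraction signature selection
# (detected in >= 5 of 9 patients, 0 of 6 healthy donors).
library(ctcsig)

paths <- sort(list.files("results/arrays", pattern = "\\.txt$",
                         full.names = TRUE))
stopifnot(length(paths) > 0)
res <- run_discovery(paths, out_dir = "results/discovery")

fr <- res$filter_report
cat(sprintf("filtered %.0f spots per array on average (%.2f%% of %d)\n",
            mean(fr$filtered_spots), 100 * mean(fr$filtered_fraction),
            fr$total_spots[1]))
cat(sprintf("signature: %d genes selected\n", length(res$signature$genes)))

truth <- read.delim("results/arrays_ground_truth.tsv")
oracle <- truth$gene[truth$patient_occupancy >= 5]
cat(sprintf("ground-truth check: %d/%d recoverable spiked genes selected, %d false positives\n",
            length(intersect(res$signature$genes, oracle)), length(oracle),
            length(setdiff(res$signature$genes, oracle))))
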