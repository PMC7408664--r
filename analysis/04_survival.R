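#!/usr/bin/env Rscript
# Survival arm: marker-dichotomized Kaplan-Meier restricted means and
# log-rank tests, using the published fixed cut-offs for the six-marker
# panel, plus a median-cut sensitivity run.
library(ctcsig)

wells <- read.delim("results/qpcr_wells.tsv")
d <- structure(wells, ref_gene = "CD45", ct_floor = 40,
               class = c("qpcr_dataset", "data.frame"))
sc <- normalize_ct(d)
sv <- read.delim("results/survival.tsv")

cuts <- c(HOXB13 = -3.8, MAOA = -4.1, FGD4 = 0.4, MOSPD1 = -4.0,
          QKI = 0.5, SDK1 = -2.0)
pat <- sc[sc$group == "patient", ]

fixed <- marker_survival_report(pat, cuts, sv, endpoint = "PFS")
write.table(fixed, "results/validation/survival_fixed_cuts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
median_cut <- marker_survival_report(pat, "median", sv, endpoint = "PFS")
write.table(median_cut, "results/validation/survival_median_cuts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

print(fixed, digits = 3)
sig <- unique(fixed$marker[fixed$logrank_p <= 0.05])
cat(sprintf("\nmarkers with log-rank p <= 0.05 at fixed cuts: %s\n",
            if (length(sig)) paste(sig, collapse = ", ") else "none"))
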