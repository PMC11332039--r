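#!/usr/bin/env Rscript
# Synthesis: join the temperature outlier SNPs, the genomic islands of
# differentiation, and the divergent-selection calls into the enrichment
# report.

library(reefpopgen)

div <- readRDS("scratch/divergence.rds")
gea <- readRDS("scratch/gea.rds")

report <- build_report(gea$outliers, div$gids, gea$selection)
print(report)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write_report(report, "results/tables/enrichment_report.tsv")
cat("wrote results/tables/enrichment_report.tsv\n")
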