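#!/usr/bin/env Rscript
# Genomic divergence among species: per-site and 500 bp windowed
# Weir-Cockerham FST, genomic islands of differentiation (top 1% of bins),
# pairwise group FST matrices, and f2/f4 statistics with block-jackknife
# errors.

library(reefpopgen)

sim <- readRDS("scratch/sim.rds")
cl <- readRDS("scratch/clones.rds")
gm <- cl$gm_ramets
meta <- sim$meta[match(gm$sample_ids, sim$meta$sample_id), ]
lineage <- setNames(meta$lineage, meta$sample_id)

track <- lineage_window_fst(gm, lineage, window_bp = 500)
gids <- call_gids(track, quantile = 0.01)
cat(sprintf("windows with SNPs: %d; GIDs called: %d\n",
            nrow(track), nrow(gids)))
cat(sprintf("mean among-species window FST: %.4f; GID minimum: %.4f\n",
            mean(track$mean_fst), min(gids$mean_fst)))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
bed <- track
bed$is_gid <- paste(bed$contig, bed$start) %in% paste(gids$contig, gids$start)
write.table(bed[, c("contig", "start", "end", "mean_fst", "is_gid")],
            "results/tables/window_fst.bed", sep = "\t", quote = FALSE,
            row.names = FALSE)

# group FST at the species x island level (the grouping used for the
# distance-based correlation analyses)
grp <- setNames(paste(meta$lineage, meta$island, sep = "_"), meta$sample_id)
fst_groups <- suppressWarnings(pairwise_group_fst(gm, grp))
write.table(round(fst_groups, 5), "results/tables/group_fst.tsv",
            sep = "\t", quote = FALSE)
cat(sprintf("group FST matrix: %d x %d (species x island groups)\n",
            nrow(fst_groups), ncol(fst_groups)))

# f-statistics over the species
f2_12 <- f2_stat(gm, lineage, "SP1", "SP2")
f4_t <- f4_stat(gm, lineage, "SP1", "SP2", "SP2", "SP3")
cat(sprintf("f2(SP1,SP2) = %.5f (SE %.5f)\n", f2_12$stat, f2_12$se))
cat(sprintf("f4(SP1,SP2;SP2,SP3) = %.5f, Z = %.2f (%ssignificant)\n",
            f4_t$stat, f4_t$z, if (f4_t$significant) "" else "not "))

saveRDS(list(track = track, gids = gids, fst_groups = fst_groups),
        "scratch/divergence.rds")
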