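#!/usr/bin/env Rscript
# Site filtering (MAF >= 0.05, QUAL >= 30, no missing data) and LD pruning
# (r2 >= 0.2 within a 1000-site window), mirroring the "linked" ->
# "unlinked" dataset reduction.

library(reefpopgen)

sim <- readRDS("scratch/sim.rds")
gm <- read_vcf("results/data/genotypes.vcf")
stopifnot(identical(unname(gm$dosages), unname(sim$gm$dosages)))

spec <- filter_spec(min_maf = 0.05, min_qual = 30, max_missing_fraction = 0,
                    ld_r2_max = 0.2, ld_window_sites = 1000)
gm_f <- apply_site_filters(gm, spec)
cat(sprintf("site filters: %d -> %d sites\n", n_sites(gm), n_sites(gm_f)))

gm_p <- ld_prune(gm_f, spec)
cat(sprintf("LD pruning:  %d -> %d sites (unlinked set)\n",
            n_sites(gm_f), n_sites(gm_p)))

saveRDS(list(gm_filtered = gm_f, gm_pruned = gm_p, spec = spec),
        "scratch/filtered.rds")
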