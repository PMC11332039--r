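#!/usr/bin/env Rscript
# Population structure: genotype PCA, ancestry coefficients with the
# cross-entropy choice of K, and second-round subclustering.

library(reefpopgen)

sim <- readRDS("scratch/sim.rds")
cl <- readRDS("scratch/clones.rds")
gm <- cl$gm_ramets

pca <- gt_pca(gm, n_components = 4)
cat(sprintf("PC1/PC2 variance: %.1f%% / %.1f%%\n",
            100 * pca$prop_var[1], 100 * pca$prop_var[2]))

ck <- choose_K(gm, K_range = 1:5, seed = 106, n_restarts = 5, max_iter = 150)
cat("cross-entropy by K:\n")
print(round(ck$cross_entropy, 4))
cat(sprintf("best K = %d (simulated number of species: 3)\n", ck$best_K))

fit <- ck$fits[[which(names(ck$cross_entropy) == as.character(ck$best_K))]]
assign <- cluster_assignment(fit)
truth <- sim$truth$species_assignment[names(assign)]
cat("cluster x species table:\n")
print(table(assign, truth))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(
  data.frame(sample_id = rownames(fit$Q), round(fit$Q, 4)),
  "results/tables/ancestry_Q.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE
)
write.table(
  data.frame(sample_id = rownames(pca$scores), round(pca$scores, 4)),
  "results/tables/pca_scores.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE
)
write.table(
  data.frame(K = as.integer(names(ck$cross_entropy)),
             cross_entropy = unname(ck$cross_entropy)),
  "results/tables/cross_entropy.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE
)

sub <- subcluster(gm, fit, K_range = 1:3, seed = 7, n_restarts = 3,
                  max_iter = 100)
for (k in names(sub)) {
  if (!is.null(sub[[k]])) {
    cat(sprintf("cluster %s subcluster K = %d\n", k, sub[[k]]$best_K))
  }
}
saveRDS(list(pca = pca, choice = ck, ancestry = fit), "scratch/structure.rds")
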