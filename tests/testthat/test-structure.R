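two_species_gm <- function(n_sites = 400, seed = 11) {
  sim <- simulate_dataset(sim_config(
    n_species = 2, n_islands = 4, sites_per_island = 2, samples_per_site = 3,
    n_sites_genomic = n_sites, seed = seed
  ))
  list(gm = apply_site_filters(sim$gm, filter_spec()),
       species = sim$truth$species_assignment)
}

test_that("PCA separates diverged populations on PC1 and conserves variance", {
  fx <- two_species_gm()
  pca <- gt_pca(fx$gm, n_components = 4)
  sp <- fx$species[rownames(pca$scores)]
  s1 <- pca$scores[sp == "SP1", 1]
  s2 <- pca$scores[sp == "SP2", 1]
  expect_true(max(min(s1), min(s2)) > min(max(s1), max(s2)) ||
              all(s1 > max(s2)) || all(s2 > max(s1)))
  # linear separation on PC1: ranges do not overlap
  expect_true(min(s1) > max(s2) || min(s2) > max(s1))
  # eigenvalues: non-increasing, sum equals total variance
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
  centered <- scale(fx$gm$dosages, center = TRUE, scale = FALSE)
  expect_equal(sum(pca$eigenvalues), sum(centered^2) / (nrow(centered) - 1))
})

test_that("duplicated samples get identical PCA scores", {
  fx <- two_species_gm(n_sites = 150, seed = 13)
  d <- fx$gm$dosages
  d2 <- rbind(d, d[3, ])
  gm2 <- genotype_matrix(d2, fx$gm$sites,
                         c(fx$gm$sample_ids, "dup"))
  pca <- gt_pca(gm2, 3)
  expect_equal(unname(pca$scores[3, ]), unname(pca$scores[nrow(d2), ]))
  expect_error(gt_pca(gm2, n_components = 1000), "n_components")
})

test_that("ancestry coefficients recover two well-separated species", {
  fx <- two_species_gm()
  fit <- estimate_ancestry(fx$gm, K = 2, seed = 1, n_restarts = 4,
                           max_iter = 150)
  expect_equal(unname(rowSums(fit$Q)), rep(1, nrow(fit$Q)), tolerance = 1e-6)
  expect_true(all(fit$Q >= -1e-9))
  expect_true(all(fit$G >= 0 & fit$G <= 1))
  expect_gte(mean(apply(fit$Q, 1, max) >= 0.95), 0.95)
  cl <- apply(fit$Q, 1, which.max)
  sp <- fx$species[rownames(fit$Q)]
  agree <- max(mean((cl == 1) == (sp == "SP1")),
               mean((cl == 2) == (sp == "SP1")))
  expect_gte(agree, 0.95)
})

test_that("K = 1 gives a trivial all-ones Q", {
  fx <- two_species_gm(n_sites = 100, seed = 17)
  fit <- estimate_ancestry(fx$gm, K = 1)
  expect_equal(dim(fit$Q), c(n_samples(fx$gm), 1L))
  expect_equal(unname(fit$Q[, 1]), rep(1, n_samples(fx$gm)))
})

test_that("a 50/50 hybrid receives intermediate ancestry", {
  # a single admixed genotype is weakly informative; the fixture needs
  # enough sites and parental samples for its coefficient to be resolved
  sim <- simulate_dataset(sim_config(
    n_species = 2, n_islands = 5, sites_per_island = 2, samples_per_site = 4,
    n_sites_genomic = 2000, seed = 19
  ))
  gm <- apply_site_filters(sim$gm, filter_spec())
  sp <- sim$truth$species_assignment[gm$sample_ids]
  p1 <- colMeans(gm$dosages[sp == "SP1", ]) / 2
  p2 <- colMeans(gm$dosages[sp == "SP2", ]) / 2
  set.seed(101)
  hyb <- rbinom(n_sites(gm), 2, (p1 + p2) / 2)
  gm2 <- genotype_matrix(rbind(gm$dosages, hyb), gm$sites,
                         c(gm$sample_ids, "hybrid"))
  fit <- estimate_ancestry(gm2, K = 2, seed = 1, n_restarts = 4,
                           max_iter = 300)
  q_h <- fit$Q["hybrid", ]
  expect_true(all(q_h >= 0.3 & q_h <= 0.7))
})

test_that("cross-entropy K selection returns a full curve and sane argmin", {
  fx <- two_species_gm()
  ck <- choose_K(fx$gm, K_range = 1:4, seed = 2, n_restarts = 3,
                 max_iter = 100)
  expect_length(ck$cross_entropy, 4)
  expect_equal(ck$best_K, 2)
  expect_error(choose_K(gm_subset(fx$gm, samples = 1:4, sites = 1:10),
                        K_range = 1:2, holdout_fraction = 0.01),
               "holdout")
})

test_that("subclustering finds island demes within a species and none in a homogeneous one", {
  # one species, two strongly diverged islands -> subcluster K = 2
  sim <- simulate_dataset(sim_config(
    n_species = 1, n_islands = 2, sites_per_island = 3, samples_per_site = 4,
    n_sites_genomic = 500, f_island = 0.15, seed = 23
  ))
  gm <- apply_site_filters(sim$gm, filter_spec())
  first <- estimate_ancestry(gm, K = 1)
  sub <- subcluster(gm, first, K_range = 1:3, seed = 1, n_restarts = 3,
                    max_iter = 100)
  expect_equal(sub[["1"]]$best_K, 2)
  # homogeneous cluster -> subcluster K = 1
  sim_h <- simulate_dataset(sim_config(
    n_species = 1, n_islands = 2, sites_per_island = 3, samples_per_site = 4,
    n_sites_genomic = 500, f_island = 0.01, seed = 29
  ))
  gm_h <- apply_site_filters(sim_h$gm, filter_spec())
  sub_h <- subcluster(gm_h, estimate_ancestry(gm_h, K = 1),
                      K_range = 1:3, seed = 1, n_restarts = 3,
                      max_iter = 100)
  expect_equal(sub_h[["1"]]$best_K, 1)
  # assignment by max Q covers every sample
  expect_length(cluster_assignment(first), n_samples(gm))
})
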