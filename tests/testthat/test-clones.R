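test_that("allele-sharing distance has its definitional values", {
  a <- c(0L, 0L, 2L, 2L, 0L, 0L, 2L, 0L, 0L, 2L)
  gm <- make_gm(rbind(a, a, 2L - a, replace(a, 3, 1L)))
  d <- pairwise_distance(gm)
  expect_equal(unname(d["s01", "s02"]), 0)           # identical
  expect_equal(unname(d["s01", "s03"]), 1)           # opposite homozygotes
  expect_equal(unname(d["s01", "s04"]), 0.05)        # one het step over 10 sites
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 4))
})

test_that("pairwise-complete distance agrees with a direct computation", {
  sim <- simulate_dataset(sim_config(n_islands = 3, sites_per_island = 2,
                                     samples_per_site = 2,
                                     n_sites_genomic = 200, seed = 21))
  gm <- inject_missingness(sim$gm, 0.1, seed = 3)
  d <- pairwise_distance(gm)
  i <- 2; j <- 7
  x <- gm$dosages[i, ]; y <- gm$dosages[j, ]
  cc <- complete.cases(x, y)
  expect_equal(unname(d[i, j]), mean(abs(x[cc] - y[cc]) / 2))
})

test_that("clone threshold separates planted clones from distinct genotypes", {
  sim <- fixture_sim()
  d <- pairwise_distance(sim$gm)
  thr <- detect_clone_threshold(d)
  expect_gt(thr, 0)
  clone_d <- vapply(sim$truth$clone_pairs,
                    function(cp) d[cp[1], cp[2]], numeric(1))
  expect_true(all(clone_d <= thr))
  non_clone <- d[lower.tri(d)]
  non_clone <- non_clone[non_clone > 0]
  expect_true(all(non_clone > thr))
})

test_that("threshold is 0 with no clonal mode and degenerate inputs warn", {
  sim <- simulate_dataset(sim_config(n_islands = 3, sites_per_island = 2,
                                     samples_per_site = 2,
                                     n_sites_genomic = 300, seed = 31))
  d <- pairwise_distance(sim$gm)
  expect_equal(detect_clone_threshold(d), 0)
  gm_same <- make_gm(matrix(rep(c(0L, 1L, 2L, 1L), 3), 3, byrow = TRUE))
  d_same <- pairwise_distance(gm_same)
  expect_warning(thr <- detect_clone_threshold(d_same), "degenerate")
  expect_equal(thr, 0)
})

test_that("MLL assignment is single linkage with deterministic representatives", {
  # chain: A-B and B-C within threshold, A-C beyond -> one MLL
  d <- matrix(c(0, 1, 1.9, 1, 0, 1, 1.9, 1, 0), 3,
              dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  part <- assign_mll(d, threshold = 1)
  expect_equal(length(part$representatives), 1)
  expect_equal(part$representatives, "a") # lexicographically smallest
  # three mutual clones
  d3 <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  p3 <- assign_mll(d3, threshold = 0)
  expect_equal(length(unique(p3$mll_assignment)), 1)
  expect_equal(p3$representatives, "x")
})

test_that("partitions nest monotonically as the threshold decreases", {
  sim <- fixture_sim()
  d <- pairwise_distance(gm_subset(sim$gm, samples = 1:30))
  thrs <- quantile(d[lower.tri(d)], c(0.1, 0.3, 0.5))
  parts <- lapply(thrs, function(t) assign_mll(d, t)$mll_assignment)
  for (i in 1:2) {
    # every MLL at the smaller threshold lies within one MLL at the larger
    tab <- table(parts[[i]], parts[[i + 1]])
    expect_true(all(rowSums(tab > 0) == 1))
  }
})

test_that("planted clone groups are recovered with perfect precision and recall", {
  sim <- fixture_sim()
  d <- pairwise_distance(sim$gm)
  thr <- detect_clone_threshold(d)
  part <- assign_mll(d, thr)
  mll <- part$mll_assignment
  truth_pairs <- lapply(sim$truth$clone_pairs, sort)
  called_pairs <- list()
  for (g in split(names(mll), mll)) {
    if (length(g) >= 2) {
      for (cmb in combn(sort(g), 2, simplify = FALSE)) {
        called_pairs[[length(called_pairs) + 1]] <- cmb
      }
    }
  }
  expect_setequal(
    vapply(called_pairs, paste, "", collapse = "|"),
    vapply(truth_pairs, paste, "", collapse = "|")
  )
})
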