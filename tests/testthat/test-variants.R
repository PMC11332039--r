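test_that("a toy VCF round-trips through write and read", {
  gm <- make_gm(rbind(c(0L, 2L), c(1L, NA), c(2L, 0L)), pos = c(5L, 12L))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  gm2 <- read_vcf(path)
  expect_equal(unname(gm2$dosages), unname(gm$dosages))
  expect_equal(gm2$sites$pos, gm$sites$pos)
  expect_equal(gm2$sample_ids, gm$sample_ids)
})

test_that("multi-allelic and non-SNP records are excluded with a count", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "c1\t10\t.\tA\tT\t40\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "c1\t20\t.\tA\tT,G\t40\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "c1\t30\t.\tAC\tA\t40\tPASS\t.\tGT\t0/0\t0/0\t0/1"
  ), path)
  expect_warning(gm <- read_vcf(path), "2 multi-allelic or non-SNP")
  expect_equal(n_sites(gm), 1)
  expect_equal(attr(gm, "n_excluded"), 2)
  expect_equal(unname(gm$dosages[, 1]), c(0L, 1L, 2L))
})

test_that("site filters apply inclusive boundaries and preserve order", {
  # MAF boundary: ALT count 1 over 20 alleles in 10 diploids = 0.05 -> kept
  d_boundary <- matrix(0L, 10, 1); d_boundary[1, 1] <- 1L
  gm <- make_gm(d_boundary)
  expect_equal(n_sites(apply_site_filters(gm, filter_spec())), 1)
  # below the boundary (1/22) -> removed
  d_below <- matrix(0L, 11, 1); d_below[1, 1] <- 1L
  expect_warning(out <- apply_site_filters(make_gm(d_below), filter_spec()))
  expect_equal(n_sites(out), 0)
  # QUAL boundary
  d <- rbind(c(0L, 0L), c(1L, 1L), c(2L, 2L), c(1L, 1L))
  gm_q <- genotype_matrix(d, data.frame(contig = "c1", pos = c(1L, 2L),
                                        qual = c(29.9, 30)), paste0("s", 1:4))
  kept <- apply_site_filters(gm_q, filter_spec())
  expect_equal(kept$sites$pos, 2L)
  # one missing call under max_missing_fraction = 0 -> removed
  d_m <- rbind(c(0L, 0L), c(1L, NA), c(2L, 2L), c(1L, 1L))
  gm_m <- make_gm(d_m)
  expect_equal(apply_site_filters(gm_m, filter_spec())$sites$pos, 10L)
})

test_that("filtering is idempotent and criterion-order-insensitive", {
  sim <- fixture_sim()
  gm <- inject_missingness(sim$gm, 0.02, seed = 8)
  spec <- filter_spec(max_missing_fraction = 0.05)
  once <- apply_site_filters(gm, spec)
  twice <- apply_site_filters(once, spec)
  expect_identical(twice$sites, once$sites)
  # independent criteria compose in any order
  maf_first <- apply_site_filters(
    apply_site_filters(gm, filter_spec(min_qual = 0, max_missing_fraction = 1)),
    filter_spec(min_maf = 0, max_missing_fraction = 0.05))
  expect_identical(maf_first$sites, once$sites)
})

test_that("LD pruning removes later duplicated columns and keeps orthogonal ones", {
  v <- c(0L, 1L, 2L, 0L, 1L, 2L)
  gm_dup <- make_gm(cbind(v, v))
  pruned <- ld_prune(gm_dup, filter_spec())
  expect_equal(pruned$sites$pos, 10L)
  x <- c(0L, 0L, 1L, 1L, 2L, 2L)
  y <- c(0L, 2L, 1L, 1L, 2L, 0L) # cor(x, y) = 0
  gm_orth <- make_gm(cbind(x, y))
  expect_equal(n_sites(ld_prune(gm_orth, filter_spec())), 2)
})

test_that("LD pruning matches the brute-force oracle and is idempotent", {
  for (s in 1:3) {
    sim <- simulate_dataset(sim_config(
      n_islands = 4, sites_per_island = 2, samples_per_site = 3,
      n_sites_genomic = 400, contig_length_bp = 4000, seed = 300 + s
    ))
    gm <- apply_site_filters(sim$gm, filter_spec())
    spec <- filter_spec(ld_r2_max = 0.2, ld_window_sites = 50)
    pruned <- ld_prune(gm, spec)
    oracle_kept <- ld_prune_oracle(gm, r2_max = 0.2, window = 50)
    expect_equal(pruned$sites$pos, gm$sites$pos[oracle_kept])
    again <- ld_prune(pruned, spec)
    expect_identical(again$sites, pruned$sites)
  }
})

test_that("pruning with missing data falls back to pairwise-complete r2", {
  sim <- simulate_dataset(sim_config(n_islands = 3, sites_per_island = 2,
                                     samples_per_site = 3,
                                     n_sites_genomic = 120, seed = 5))
  gm <- inject_missingness(sim$gm, 0.05, seed = 2)
  spec <- filter_spec(ld_r2_max = 0.25, ld_window_sites = 30)
  pruned <- ld_prune(gm, spec)
  oracle_kept <- ld_prune_oracle(gm, r2_max = 0.25, window = 30)
  expect_equal(pruned$sites$pos, gm$sites$pos[oracle_kept])
})
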