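# shared fixtures, built once per test run

.fx <- new.env()

# default-design dataset with planted clones and selected loci
fixture_sim <- function() {
  if (is.null(.fx$sim)) {
    .fx$sim <- simulate_dataset(sim_config(
      n_sites_genomic = 1500, n_selected = 30, n_clone_pairs = 2, seed = 42
    ))
  }
  .fx$sim
}

# small genotype matrix from explicit dosages on one contig
make_gm <- function(dosages, pos = NULL, qual = 50) {
  dosages <- as.matrix(dosages)
  L <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(L) * 10L
  genotype_matrix(
    dosages,
    data.frame(contig = "c1", pos = as.integer(pos),
               qual = rep_len(qual, L)),
    sprintf("s%02d", seq_len(nrow(dosages)))
  )
}

# two-population fixture with exact allele frequencies at single site
freq_pair_gm <- function(pA, pB, n = 10) {
  make_gm(cbind(c(exact_freq_dosages(pA, n), exact_freq_dosages(pB, n))))
}
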