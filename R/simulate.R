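#' Simulation configuration
#'
#' Parameters of the two-level Balding-Nichols generator that emulates a
#' multi-island, multi-species reef sampling design: `n_species` latent
#' species whose allele frequencies drift from a shared ancestral frequency
#' with FST-scale parameter `f_species`, islands drifting within species with
#' `f_island`, ~3 sites per island and a handful of colonies per site,
#' island-correlated temperature descriptors, environment-linked selected
#' loci, and exact clonal replicates.
#'
#' @param n_species number of latent species (lineages)
#' @param n_islands number of islands
#' @param sites_per_island sampling sites per island
#' @param samples_per_site colonies sampled per site
#' @param n_sites_genomic number of biallelic SNPs to simulate
#' @param contig_length_bp length of the single simulated contig; SNP
#'   positions are drawn uniformly without replacement from it
#' @param f_species FST-scale drift between species, in (0,1)
#' @param f_island FST-scale drift of islands within species, in (0,1)
#' @param n_selected number of environment-associated loci
#' @param cline_slope logit-scale allele-frequency shift per unit of the
#'   standardized island environment score at selected loci
#' @param n_env_descriptors number of per-site temperature descriptors
#' @param env_island_sd dispersion of the descriptor response to the latent
#'   island gradient
#' @param env_site_sd within-island (site-level) descriptor noise SD
#' @param n_clone_pairs number of clonal pairs to plant (each pair shares a
#'   species and an island; the second member's genotypes are overwritten
#'   with an exact copy of the first's)
#' @param missing_rate per-call missing probability applied after cloning
#' @param seed integer RNG seed; one stream drives the whole dataset
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(n_species = 3, n_islands = 11, sites_per_island = 3,
                       samples_per_site = 3, n_sites_genomic = 5000,
                       contig_length_bp = 20L * n_sites_genomic,
                       f_species = 0.15, f_island = 0.02,
                       n_selected = 0, cline_slope = 2,
                       n_env_descriptors = 63,
                       env_island_sd = 1, env_site_sd = 0.3,
                       n_clone_pairs = 0, missing_rate = 0, seed = 1) {
  cfg <- list(
    n_species = n_species, n_islands = n_islands,
    sites_per_island = sites_per_island, samples_per_site = samples_per_site,
    n_sites_genomic = n_sites_genomic, contig_length_bp = contig_length_bp,
    f_species = f_species, f_island = f_island,
    n_selected = n_selected, cline_slope = cline_slope,
    n_env_descriptors = n_env_descriptors,
    env_island_sd = env_island_sd, env_site_sd = env_site_sd,
    n_clone_pairs = n_clone_pairs, missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  counts <- c("n_species", "n_islands", "sites_per_island", "samples_per_site",
              "n_sites_genomic", "n_env_descriptors")
  for (nm in counts) {
    if (cfg[[nm]] < 1) stop(nm, " must be >= 1")
  }
  if (cfg$n_selected < 0 || cfg$n_clone_pairs < 0) {
    stop("n_selected and n_clone_pairs must be >= 0")
  }
  if (cfg$n_selected > cfg$n_sites_genomic) {
    stop("n_selected exceeds n_sites_genomic")
  }
  if (cfg$f_species <= 0 || cfg$f_species >= 1 ||
      cfg$f_island <= 0 || cfg$f_island >= 1) {
    stop("f_species and f_island must lie in (0, 1)")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (cfg$contig_length_bp < cfg$n_sites_genomic) {
    stop("contig_length_bp must be >= n_sites_genomic")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Balding-Nichols draw: population frequency around ancestral p with
# FST-scale parameter f.
rbalding_nichols <- function(p, f) {
  theta <- (1 - f) / f
  stats::rbeta(length(p), theta * p, theta * (1 - p))
}

#' Simulate a full dataset (genotypes, metadata, environment, truth)
#'
#' The generator is the F-model run forwards. Ancestral frequencies are
#' Uniform(0.05, 0.95); species frequencies are Balding-Nichols draws around
#' them at `f_species`; island-within-species frequencies are Balding-Nichols
#' at `f_island` around the species frequency. For the `n_selected` selected
#' loci the island frequency is additionally shifted on the logit scale by
#' `cline_slope` times the standardized island environment score, so allele
#' frequencies track the thermal gradient. Genotypes are Binomial(2, p).
#' Environment descriptors are noisy affine images of one latent island-level
#' gradient, so they are strongly mutually correlated, as heavily
#' inter-correlated sea-surface-temperature summaries are.
#'
#' @param config a [sim_config()]
#' @return a list with elements `gm` (a [genotype_matrix()]), `meta`
#'   (data.frame: sample_id, island, site, lineage, lat, lon, depth_m),
#'   `env` (data.frame: site_id, island, then descriptor columns), and
#'   `truth` (list: selected_site_ids, pop_freqs, clone_pairs,
#'   species_assignment, island_gradient).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  L <- cfg$n_sites_genomic
  n_total <- cfg$n_islands * cfg$sites_per_island * cfg$samples_per_site

  # --- sampling design -----------------------------------------------------
  island <- rep(seq_len(cfg$n_islands),
                each = cfg$sites_per_island * cfg$samples_per_site)
  site_within <- rep(rep(seq_len(cfg$sites_per_island),
                         each = cfg$samples_per_site), cfg$n_islands)
  site <- paste0("I", sprintf("%02d", island), "S", site_within)
  sample_id <- sprintf("I%02dS%dC%03d", island, site_within, seq_len(n_total))
  # species assigned round-robin within each island so every island carries
  # every species (clone pairs need same-species, same-island partners)
  species <- integer(n_total)
  for (i in seq_len(cfg$n_islands)) {
    idx <- which(island == i)
    species[idx] <- rep_len(seq_len(cfg$n_species), length(idx))
  }

  # --- geography and environment ------------------------------------------
  lat <- stats::runif(cfg$n_islands, -25, 25)
  lon <- stats::runif(cfg$n_islands, 120, 280) # pan-Pacific spread
  lon <- ifelse(lon > 180, lon - 360, lon)
  gradient <- as.numeric(scale(stats::rnorm(cfg$n_islands)))
  site_ids <- unique(site)
  site_island <- as.integer(sub("^I(\\d+)S.*$", "\\1", site_ids))
  z_site <- gradient[site_island] +
    stats::rnorm(length(site_ids), 0, cfg$env_site_sd)
  slope <- stats::rnorm(cfg$n_env_descriptors, 1, 0.25) * cfg$env_island_sd
  intercept <- stats::rnorm(cfg$n_env_descriptors, 25, 2)
  env_mat <- outer(z_site, slope) +
    matrix(stats::rnorm(length(site_ids) * cfg$n_env_descriptors,
                        0, 0.1 * cfg$env_island_sd),
           nrow = length(site_ids))
  env_mat <- sweep(env_mat, 2, intercept, `+`)
  colnames(env_mat) <- sprintf("sst_%02d", seq_len(cfg$n_env_descriptors))
  env <- data.frame(site_id = site_ids, island = site_island, env_mat,
                    stringsAsFactors = FALSE)

  # --- allele frequencies (two-level Balding-Nichols) ----------------------
  p_anc <- stats::runif(L, 0.05, 0.95)
  p_species <- sapply(seq_len(cfg$n_species), function(s) {
    rbalding_nichols(p_anc, cfg$f_species)
  }) # L x S
  selected <- if (cfg$n_selected > 0) {
    sort(sample.int(L, cfg$n_selected))
  } else integer(0)
  # island-within-species frequencies, L x S x I
  p_isl <- array(NA_real_, dim = c(L, cfg$n_species, cfg$n_islands))
  for (s in seq_len(cfg$n_species)) {
    for (i in seq_len(cfg$n_islands)) {
      p <- rbalding_nichols(p_species[, s], cfg$f_island)
      if (length(selected) > 0) {
        lp <- stats::qlogis(pmin(pmax(p[selected], 1e-6), 1 - 1e-6))
        p[selected] <- stats::plogis(lp + cfg$cline_slope * gradient[i])
      }
      p_isl[, s, i] <- p
    }
  }

  # --- genotypes -----------------------------------------------------------
  dos <- matrix(NA_integer_, nrow = n_total, ncol = L)
  for (j in seq_len(n_total)) {
    dos[j, ] <- stats::rbinom(L, 2L, p_isl[, species[j], island[j]])
  }

  # --- clones --------------------------------------------------------------
  clone_pairs <- list()
  if (cfg$n_clone_pairs > 0) {
    key <- paste(species, island)
    pool <- split(seq_len(n_total), key)
    pool <- pool[vapply(pool, length, 1L) >= 2]
    if (length(pool) < cfg$n_clone_pairs) {
      stop("not enough same-species, same-island sample pairs for clones")
    }
    chosen <- sample(seq_along(pool), cfg$n_clone_pairs)
    for (k in chosen) {
      pr <- sample(pool[[k]], 2)
      pr <- sort(pr)
      dos[pr[2], ] <- dos[pr[1], ]
      clone_pairs[[length(clone_pairs) + 1]] <-
        c(sample_id[pr[1]], sample_id[pr[2]])
    }
  }

  pos <- sort(sample.int(cfg$contig_length_bp, L))
  sites_df <- data.frame(contig = "contig_1", pos = pos,
                         qual = round(stats::runif(L, 30, 60), 1),
                         stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, sites_df, sample_id)

  if (cfg$missing_rate > 0) {
    gm <- inject_missingness(gm, cfg$missing_rate,
                             seed = cfg$seed + 1000003L)
  }

  meta <- data.frame(
    sample_id = sample_id, island = sprintf("I%02d", island), site = site,
    lineage = paste0("SP", species),
    lat = lat[island], lon = lon[island],
    depth_m = round(stats::runif(n_total, 2, 20), 1),
    stringsAsFactors = FALSE
  )

  truth <- list(
    selected_site_ids = selected,
    pop_freqs = p_isl,
    clone_pairs = clone_pairs,
    species_assignment = stats::setNames(paste0("SP", species), sample_id),
    island_gradient = gradient
  )
  list(gm = gm, meta = meta, env = env, truth = truth, config = cfg)
}

#' Inject missing genotype calls at random
#'
#' @param gm a [genotype_matrix()]
#' @param rate per-call missing probability in `[0, 1)`
#' @param seed integer RNG seed
#' @return a `genotype_matrix` with calls set to `NA`; site records unchanged
#' @export
inject_missingness <- function(gm, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(gm)
  set.seed(seed)
  d <- gm$dosages
  drop <- stats::runif(length(d)) < rate
  d[drop] <- NA_integer_
  genotype_matrix(d, gm$sites, gm$sample_ids)
}

#' Simulate per-population allele counts directly from the F-model
#'
#' Forward simulation of the selection-scan model: locus-wise ancestral
#' frequencies are Uniform(0.05, 0.95), population frequencies are
#' Beta-distributed around them with FST `plogis(alpha_l + beta_p)`, and ALT
#' counts are Binomial over `2 * n_diploid` alleles. Used to calibrate the
#' selection scan against known locus effects.
#'
#' @param n_loci number of loci
#' @param n_pops number of populations
#' @param fst baseline population FST (sets `beta_p = qlogis(fst)` for all
#'   populations); may be a vector of length `n_pops`
#' @param alpha per-locus logit-scale selection effects (length `n_loci`,
#'   default all 0)
#' @param n_diploid diploid sample size per population
#' @param seed integer RNG seed
#' @return list with `alt` and `total` count matrices (loci x populations),
#'   `alpha`, `beta`, and `p_anc`
#' @export
simulate_allele_counts <- function(n_loci, n_pops, fst = 0.05, alpha = NULL,
                                   n_diploid = 20, seed = 1) {
  set.seed(seed)
  if (is.null(alpha)) alpha <- rep(0, n_loci)
  stopifnot(length(alpha) == n_loci)
  beta <- stats::qlogis(rep_len(fst, n_pops))
  p_anc <- stats::runif(n_loci, 0.05, 0.95)
  fmat <- stats::plogis(outer(alpha, beta, `+`)) # loci x pops
  theta <- (1 - fmat) / fmat
  a <- theta * p_anc
  b <- theta * (1 - p_anc)
  p <- matrix(stats::rbeta(n_loci * n_pops, a, b), nrow = n_loci)
  total <- matrix(2L * n_diploid, n_loci, n_pops)
  alt <- matrix(stats::rbinom(n_loci * n_pops, 2L * n_diploid, p),
                nrow = n_loci)
  list(alt = alt, total = total, alpha = alpha, beta = beta, p_anc = p_anc)
}

#' Write a simulated dataset to disk
#'
#' Emits the VCF, sample-metadata TSV, environment TSV and truth-table TSV
#' for a dataset produced by [simulate_dataset()].
#'
#' @param sim result of [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_vcf(sim$gm, file.path(dir, "genotypes.vcf"))
  utils::write.table(sim$meta, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$env, file.path(dir, "environment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(
    kind = c(rep("selected_site", length(sim$truth$selected_site_ids)),
             rep("clone_pair", length(sim$truth$clone_pairs))),
    value = c(as.character(sim$truth$selected_site_ids),
              vapply(sim$truth$clone_pairs, paste, "", collapse = ",")),
    stringsAsFactors = FALSE
  )
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
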