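#' Run the full inference chain on one dataset
#'
#' Orchestrates simulate (optional) -> site filters -> LD pruning -> clone
#' removal -> ancestry clustering -> windowed FST and GID calling -> RDA
#' outlier scan -> F-model selection scan -> enrichment synthesis, under one
#' global seed. Intended for the synthetic study design; each stage is also
#' exposed individually.
#'
#' @param sim a [simulate_dataset()] result (or a compatible list with
#'   `gm`, `meta`, `env`)
#' @param spec a [filter_spec()]
#' @param gid_quantile GID upper-tail fraction (default 0.01)
#' @param q_threshold RDA outlier q threshold (default 0.1)
#' @param top_n RDA top set size (default 100)
#' @param fdr_target selection-scan FDR (default 0.05)
#' @param mcmc_iter selection-scan MCMC iterations (default 3000)
#' @param seed global seed
#' @return list with each stage's result: `gm_filtered`, `gm_pruned`,
#'   `clones`, `gm_ramets`, `meta_ramets`, `track`, `gids`, `rda`,
#'   `outliers`, `fmodel`, `selection`, `report`
#' @export
run_pipeline <- function(sim, spec = filter_spec(), gid_quantile = 0.01,
                         q_threshold = 0.1, top_n = 100, fdr_target = 0.05,
                         mcmc_iter = 3000, seed = 1) {
  gm_f <- apply_site_filters(sim$gm, spec)
  gm_p <- ld_prune(gm_f, spec)

  d <- pairwise_distance(gm_p)
  thr <- detect_clone_threshold(d)
  clones <- assign_mll(d, thr)
  keep_ids <- names(clones$keep)[clones$keep]
  gm_r <- gm_subset(gm_p, samples = keep_ids)
  meta_r <- sim$meta[match(keep_ids, sim$meta$sample_id), , drop = FALSE]

  lineage <- stats::setNames(meta_r$lineage, meta_r$sample_id)
  track <- lineage_window_fst(gm_r, lineage, window_bp = 500)
  gids <- call_gids(track, quantile = gid_quantile)

  pred <- sample_env_predictors(sim$env, meta_r)
  rda <- fit_rda(gm_r, pred)
  outliers <- outlier_scan(rda, q_threshold = q_threshold, top_n = top_n)

  counts <- allele_counts(gm_r, stats::setNames(meta_r$island,
                                                meta_r$sample_id))
  fm <- fit_fmodel(counts, n_iter = mcmc_iter, seed = seed)
  post <- rep(0, n_sites(gm_r))
  post[fm$kept_loci] <- fm$posterior_divergent
  fm_full <- fm
  fm_full$posterior_divergent <- post
  sel <- call_selection(fm_full, fdr_target = fdr_target)

  report <- build_report(outliers, gids, sel)
  list(gm_filtered = gm_f, gm_pruned = gm_p, clones = clones,
       gm_ramets = gm_r, meta_ramets = meta_r, track = track, gids = gids,
       rda = rda, outliers = outliers, fmodel = fm, selection = sel,
       report = report)
}
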