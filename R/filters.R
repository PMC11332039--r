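#' Site-filter and LD-pruning thresholds
#'
#' Defaults follow common practice for jointly genotyped coral colonies:
#' minor allele frequency >= 0.05, site quality >= 30, no missing data, and
#' pruning of any pair with squared dosage correlation >= 0.2 within a
#' window of 1000 consecutive sites.
#'
#' @param min_maf minimum minor allele frequency (inclusive)
#' @param min_qual minimum site QUAL (inclusive)
#' @param max_missing_fraction maximum fraction of missing calls per site
#' @param ld_r2_max r-squared at or above which the later site of a pair is
#'   pruned
#' @param ld_window_sites window size in consecutive sites (index distance)
#' @return a list of class `filter_spec`
#' @export
filter_spec <- function(min_maf = 0.05, min_qual = 30,
                        max_missing_fraction = 0,
                        ld_r2_max = 0.2, ld_window_sites = 1000) {
  stopifnot(
    min_maf >= 0, min_maf <= 0.5,
    max_missing_fraction >= 0, max_missing_fraction <= 1,
    ld_r2_max > 0, ld_r2_max <= 1,
    ld_window_sites >= 1
  )
  structure(list(min_maf = min_maf, min_qual = min_qual,
                 max_missing_fraction = max_missing_fraction,
                 ld_r2_max = ld_r2_max, ld_window_sites = ld_window_sites),
            class = "filter_spec")
}

#' Apply MAF / QUAL / missingness site filters
#'
#' Keeps sites with minor allele frequency >= `min_maf` (computed on
#' non-missing calls), QUAL >= `min_qual`, and missing fraction <=
#' `max_missing_fraction`. All boundaries inclusive; site order preserved.
#' The three criteria are independent, so their order of application is
#' immaterial and the operation is idempotent.
#'
#' @param gm a [genotype_matrix()]
#' @param spec a [filter_spec()]
#' @return the filtered `genotype_matrix`
#' @export
apply_site_filters <- function(gm, spec = filter_spec()) {
  if (n_sites(gm) == 0) stop("empty genotype matrix")
  d <- gm$dosages
  n_called <- colSums(!is.na(d))
  p_alt <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  miss_frac <- 1 - n_called / nrow(d)
  keep <- n_called > 0 &
    maf >= spec$min_maf &
    gm$sites$qual >= spec$min_qual &
    miss_frac <= spec$max_missing_fraction
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("all sites removed by filters")
  gm_subset(gm, sites = keep)
}

#' Prune sites in linkage disequilibrium
#'
#' Single left-to-right pass per contig: a site is discarded when its squared
#' Pearson correlation of dosages with any of the `ld_window_sites - 1` most
#' recently *retained* sites reaches `ld_r2_max`. The earlier site of an
#' offending pair is always the one kept, and the window is counted over
#' retained sites, so the pass is idempotent: re-pruning pruned output
#' changes nothing. r-squared against a monomorphic site is defined as 0.
#'
#' @param gm a [genotype_matrix()]
#' @param spec a [filter_spec()]
#' @return the pruned `genotype_matrix`
#' @export
ld_prune <- function(gm, spec = filter_spec()) {
  L <- n_sites(gm)
  if (L <= 1) return(gm)
  keep <- logical(L)
  contigs <- gm$sites$contig
  d <- gm$dosages
  has_missing <- anyNA(d)
  if (!has_missing) {
    # standardize once; monomorphic columns -> all-zero (r2 = 0 against all)
    mu <- colMeans(d)
    sd_ <- sqrt(colMeans(d^2) - mu^2)
    Z <- sweep(d, 2, mu)
    nz <- sd_ > 0
    Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, sd_[nz], `/`)
    Z[, !nz] <- 0
    n <- nrow(d)
  }
  for (ctg in unique(contigs)) {
    idx <- which(contigs == ctg)
    kept_local <- integer(0)
    for (j in idx) {
      n_back <- min(length(kept_local), spec$ld_window_sites - 1L)
      in_window <- kept_local[seq.int(length(kept_local) - n_back + 1,
                                      length.out = n_back)]
      ok <- TRUE
      if (length(in_window) > 0) {
        if (!has_missing) {
          r <- crossprod(Z[, in_window, drop = FALSE], Z[, j]) / n
          r2 <- as.numeric(r)^2
        } else {
          r2 <- vapply(in_window, function(k) {
            cc <- stats::complete.cases(d[, k], d[, j])
            if (sum(cc) < 3) return(0)
            x <- d[cc, k]; y <- d[cc, j]
            if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
            stats::cor(x, y)^2
          }, numeric(1))
        }
        ok <- all(r2 < spec$ld_r2_max - 1e-9)
      }
      if (ok) {
        keep[j] <- TRUE
        kept_local <- c(kept_local, j)
      }
    }
  }
  gm_subset(gm, sites = keep)
}
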