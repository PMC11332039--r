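#' Pairwise allele-sharing (Prevosti) distance
#'
#' Mean over co-typed sites of `|dosage_i - dosage_j| / 2`; 0 for identical
#' multilocus genotypes, 1 for opposite homozygotes everywhere. Computed
#' pairwise-complete over non-missing sites.
#'
#' @param gm a [genotype_matrix()] with at least 2 samples
#' @return a symmetric numeric matrix with zero diagonal, labelled by
#'   sample id
#' @export
pairwise_distance <- function(gm) {
  if (n_samples(gm) < 2) stop("need at least 2 samples")
  d <- gm$dosages
  if (!anyNA(d)) {
    # |di - dj| summed over sites == Manhattan distance of dosage rows
    dm <- as.matrix(stats::dist(d, method = "manhattan")) / (2 * ncol(d))
  } else {
    obs <- !is.na(d)
    d0 <- d
    d0[!obs] <- 0
    # sum |di - dj| over co-typed sites via the identity
    # |a-b| with dosages in {0,1,2}: compute through indicator cross-products
    n_pair <- tcrossprod(obs * 1) # co-typed site counts
    if (any(n_pair[upper.tri(n_pair)] == 0)) {
      stop("a sample pair has zero co-typed sites")
    }
    # decompose |a-b| = a + b - 2*min(a,b); min over {0,1,2} dosages:
    # min(a,b) = [a>=1][b>=1] + [a==2][b==2]
    ge1 <- (d >= 1 & obs) * 1
    eq2 <- (d == 2 & obs) * 1
    sum_a <- tcrossprod(d0 * obs, obs * 1)
    sum_min <- tcrossprod(ge1) + tcrossprod(eq2)
    abs_sum <- sum_a + t(sum_a) - 2 * sum_min
    dm <- abs_sum / (2 * n_pair)
    diag(dm) <- 0
  }
  dimnames(dm) <- list(gm$sample_ids, gm$sample_ids)
  dm
}

#' Detect the clonal distance threshold from the distance histogram
#'
#' Clonal replicates produce a near-zero mode in the pairwise-distance
#' histogram, separated by a gap from the main mode of genuinely distinct
#' genotypes. The threshold returned is the left edge of the first empty
#' histogram bin (Freedman-Diaconis widths) after the clonal mode. When no
#' pair lies below 10% of the median distance there is no clonal mode and 0
#' is returned.
#'
#' @param d symmetric distance matrix from [pairwise_distance()]
#' @return a single distance threshold (0 = no clones)
#' @export
detect_clone_threshold <- function(d) {
  if (nrow(d) < 3) stop("need at least 3 samples")
  v <- d[lower.tri(d)]
  med <- stats::median(v)
  if (med == 0) {
    warning("degenerate distances: all samples identical")
    return(0)
  }
  if (!any(v < 0.1 * med)) return(0)
  iqr <- stats::IQR(v)
  bw <- if (iqr > 0) 2 * iqr / length(v)^(1 / 3) else max(v) / 30
  breaks <- seq(0, max(v) + bw, by = bw)
  counts <- table(cut(v, breaks, right = FALSE, include.lowest = TRUE))
  counts <- as.integer(counts)
  first_empty <- which(counts == 0)[1]
  if (is.na(first_empty)) return(0)
  breaks[first_empty]
}

#' Assign samples to multilocus lineages (MLL)
#'
#' MLLs are the connected components of the graph linking sample pairs at
#' distance <= `threshold` (single-linkage agglomeration, the behaviour of
#' distance-based multilocus-genotype filtering). The representative of each
#' MLL is its lexicographically smallest sample id.
#'
#' @param d symmetric distance matrix from [pairwise_distance()]
#' @param threshold clonal distance threshold (>= 0), e.g. from
#'   [detect_clone_threshold()]
#' @return a list of class `clonal_partition` with `threshold`,
#'   `mll_assignment` (named integer vector), `representatives` (character),
#'   and `keep` (logical vector marking one ramet per genet)
#' @export
assign_mll <- function(d, threshold) {
  stopifnot(threshold >= 0)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(d)))
  if (nrow(d) == 1) {
    mll <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    # cutree(h) merges pairs with linkage height <= h: components of d <= t
    mll <- stats::cutree(hc, h = threshold)
    names(mll) <- ids
  }
  reps <- vapply(split(ids, mll), function(s) sort(s)[1], "")
  keep <- ids %in% reps
  structure(
    list(threshold = threshold,
         mll_assignment = mll,
         representatives = unname(reps),
         keep = stats::setNames(keep, ids)),
    class = "clonal_partition"
  )
}

#' @export
print.clonal_partition <- function(x, ...) {
  n <- length(x$mll_assignment)
  k <- length(x$representatives)
  cat(sprintf("clonal_partition: %d samples in %d MLL (threshold %.4g)\n",
              n, k, x$threshold))
  invisible(x)
}
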