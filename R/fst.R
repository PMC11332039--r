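#' Per-site Weir-Cockerham FST components for a population pair
#'
#' The 1984 variance-component estimator for two populations of diploids,
#' computed from genotype counts: `a` (among populations), `b` (among
#' individuals within populations), `c` (within individuals), and
#' `theta = a / (a + b + c)`. Sites where either population has fewer than 2
#' typed genotypes, or where `a + b + c == 0`, are returned as `NA` and
#' counted.
#'
#' @param gm a [genotype_matrix()]
#' @param groups named character/factor vector mapping sample id to group
#'   label (names must cover `gm$sample_ids`)
#' @param pair character vector of two group labels
#' @return data.frame with one row per site: `contig`, `pos`, `a`, `b`, `c`,
#'   `theta`; attribute `n_skipped` counts unusable sites
#' @export
wc_fst_site <- function(gm, groups, pair) {
  stopifnot(length(pair) == 2, !anyDuplicated(pair))
  g <- groups[gm$sample_ids]
  i1 <- which(g == pair[1])
  i2 <- which(g == pair[2])
  if (length(i1) == 0 || length(i2) == 0) stop("empty group in pair")
  comp <- wc_components(gm$dosages[i1, , drop = FALSE],
                        gm$dosages[i2, , drop = FALSE])
  out <- data.frame(contig = gm$sites$contig, pos = gm$sites$pos,
                    a = comp$a, b = comp$b, c = comp$c, theta = comp$theta,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- comp$n_skipped
  out
}

# vectorized two-population Weir-Cockerham (1984) components over sites;
# d1, d2: dosage matrices (samples x sites) for the two populations
wc_components <- function(d1, d2) {
  r <- 2
  n1 <- colSums(!is.na(d1))
  n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  h1 <- colMeans(d1 == 1, na.rm = TRUE)
  h2 <- colMeans(d2 == 1, na.rm = TRUE)
  usable <- n1 >= 2 & n2 >= 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  theta <- ifelse(tot == 0, NA_real_, a / tot)
  a[!usable] <- NA_real_; b[!usable] <- NA_real_; cc[!usable] <- NA_real_
  theta[!usable] <- NA_real_
  list(a = a, b = b, c = cc, theta = theta,
       n_skipped = sum(!usable | (usable & tot == 0), na.rm = TRUE))
}

#' Windowed FST track over 500 bp bins
#'
#' Aggregates per-site Weir-Cockerham components of one or more lineage
#' pairs into non-overlapping bins of `window_bp` from the contig start
#' (0-based half-open windows). Per window and pair, FST is the
#' ratio-of-sums `sum(a) / sum(a + b + c)` over the SNPs in the bin; the
#' among-lineage mean is the unweighted mean of the pairwise window values.
#' Windows containing no usable SNP are excluded.
#'
#' @param site_fst a data.frame as from [wc_fst_site()], or a named list of
#'   such data.frames (one per lineage pair, identical site order)
#' @param window_bp bin width in bp (default 500)
#' @return data.frame of class `window_fst_track`: `contig`, `start`, `end`
#'   (0-based half-open), one `fst_<pair>` column per pair, `mean_fst`,
#'   `n_snps`
#' @export
window_fst <- function(site_fst, window_bp = 500) {
  if (is.data.frame(site_fst)) site_fst <- list(pair1 = site_fst)
  ref <- site_fst[[1]]
  win_start <- ((ref$pos - 1) %/% window_bp) * window_bp
  key <- paste(ref$contig, win_start)
  keys <- unique(key)
  per_pair <- lapply(site_fst, function(sf) {
    tot <- sf$a + sf$b + sf$c
    ok <- !is.na(tot)
    sa <- tapply(ifelse(ok, sf$a, 0), key, sum)[keys]
    st <- tapply(ifelse(ok, tot, 0), key, sum)[keys]
    ifelse(st == 0, NA_real_, sa / st)
  })
  n_snps <- as.integer(
    tapply(!is.na(ref$a + ref$b + ref$c), key, sum)[keys])
  ord_ctg <- sub(" \\d+$", "", keys)
  ord_start <- as.integer(sub("^.* ", "", keys))
  out <- data.frame(contig = ord_ctg, start = ord_start,
                    end = ord_start + window_bp,
                    stringsAsFactors = FALSE)
  for (nm in names(per_pair)) out[[paste0("fst_", nm)]] <- as.numeric(per_pair[[nm]])
  pm <- do.call(cbind, per_pair)
  out$mean_fst <- rowMeans(pm, na.rm = TRUE)
  out$n_snps <- n_snps
  out <- out[out$n_snps > 0 & !is.nan(out$mean_fst), , drop = FALSE]
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("window_fst_track", "data.frame")
  out
}

#' Call genomic islands of differentiation (GID)
#'
#' GIDs are the `quantile` fraction (default top 1%) of windows with the
#' highest mean among-lineage FST. The count is `ceiling(quantile * W)` over
#' the `W` windows holding at least one SNP; ties at the cut are broken by
#' (contig, start) ascending so exactly the target count is kept.
#'
#' @param track a [window_fst()] track
#' @param quantile upper tail fraction (default 0.01)
#' @return the track subset flagged as GIDs, with attribute `quantile`
#' @export
call_gids <- function(track, quantile = 0.01) {
  if (nrow(track) == 0) stop("empty window track")
  if (nrow(track) < 100) warning("fewer than 100 windows; GID quantile is coarse")
  n_gid <- ceiling(quantile * nrow(track))
  ord <- order(-track$mean_fst, track$contig, track$start)
  gid <- track[ord[seq_len(n_gid)], , drop = FALSE]
  gid <- gid[order(gid$contig, gid$start), , drop = FALSE]
  rownames(gid) <- NULL
  attr(gid, "quantile") <- quantile
  gid
}

#' Genome-wide pairwise FST matrix between groups
#'
#' Ratio-of-sums Weir-Cockerham FST (`sum(a) / sum(a+b+c)` over all usable
#' sites) for every pair of groups. Groups with fewer than 2 samples are
#' dropped with a warning.
#'
#' @param gm a [genotype_matrix()]
#' @param groups named vector mapping sample id to group label
#' @return symmetric matrix of genome-wide FST with zero diagonal
#' @export
pairwise_group_fst <- function(gm, groups) {
  g <- groups[gm$sample_ids]
  tab <- table(g)
  usable <- names(tab)[tab >= 2]
  if (length(usable) < length(tab)) {
    warning("dropping groups with < 2 samples: ",
            paste(setdiff(names(tab), usable), collapse = ", "))
  }
  if (length(usable) < 2) stop("need at least 2 groups with >= 2 samples")
  k <- length(usable)
  m <- matrix(0, k, k, dimnames = list(usable, usable))
  idx <- split(seq_along(g), factor(g, levels = usable))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      comp <- wc_components(gm$dosages[idx[[i]], , drop = FALSE],
                            gm$dosages[idx[[j]], , drop = FALSE])
      tot <- comp$a + comp$b + comp$c
      ok <- !is.na(tot)
      m[i, j] <- m[j, i] <- sum(comp$a[ok]) / sum(tot[ok])
    }
  }
  m
}

#' Mean among-lineage window FST and per-pair tracks for a set of lineages
#'
#' Convenience wrapper: computes per-site Weir-Cockerham components for
#' every pair of lineage labels and bins them with [window_fst()].
#'
#' @param gm a [genotype_matrix()]
#' @param groups named vector mapping sample id to lineage
#' @param window_bp bin width (default 500)
#' @return a `window_fst_track`
#' @export
lineage_window_fst <- function(gm, groups, window_bp = 500) {
  labs <- sort(unique(as.character(groups[gm$sample_ids])))
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  site_fst <- lapply(pairs, function(pr) wc_fst_site(gm, groups, pr))
  names(site_fst) <- vapply(pairs, paste, "", collapse = "_")
  window_fst(site_fst, window_bp = window_bp)
}
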