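# group allele frequencies and allele sample sizes per site
group_freqs <- function(gm, groups, label) {
  idx <- which(groups[gm$sample_ids] == label)
  if (length(idx) == 0) stop("unknown or empty group: ", label)
  d <- gm$dosages[idx, , drop = FALSE]
  n_allele <- 2 * colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / pmax(n_allele, 1)
  list(p = p, n = n_allele)
}

# per-site bias-corrected f2 contributions between two labelled groups;
# the correction subtracts the p(1-p)/(n-1) sampling terms of each group
f2_per_site <- function(fa, fb) {
  (fa$p - fb$p)^2 -
    fa$p * (1 - fa$p) / pmax(fa$n - 1, 1) -
    fb$p * (1 - fb$p) / pmax(fb$n - 1, 1)
}

block_jackknife <- function(x, block_size) {
  n <- length(x)
  blocks <- ceiling(seq_len(n) / block_size)
  B <- max(blocks)
  if (B < 2) return(list(se = NA_real_, n_blocks = B))
  total <- sum(x)
  loo <- vapply(seq_len(B), function(b) {
    keep <- blocks != b
    sum(x[keep]) / sum(keep)
  }, numeric(1))
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(se = se, n_blocks = B)
}

#' f2 genetic distance between two groups
#'
#' Average over sites of the bias-corrected squared allele-frequency
#' difference `(p_A - p_B)^2 - p_A(1-p_A)/(n_A-1) - p_B(1-p_B)/(n_B-1)`
#' (allele sample sizes), with a block-jackknife standard error over
#' contiguous SNP blocks. `f2(A, A)` is 0 by definition. Sites where either
#' group has fewer than 2 typed samples are excluded.
#'
#' @param gm a [genotype_matrix()]
#' @param groups named vector mapping sample id to group label
#' @param A,B group labels
#' @param block_size jackknife block length in consecutive SNPs (default 500)
#' @return list of class `fstat_result`: `stat`, `se`, `z`, `n_sites`,
#'   `block_size`, `pops`
#' @export
f2_stat <- function(gm, groups, A, B, block_size = 500) {
  if (identical(A, B)) {
    return(structure(list(stat = 0, se = 0, z = NA_real_,
                          n_sites = n_sites(gm), block_size = block_size,
                          pops = c(A, B)),
                     class = "fstat_result"))
  }
  fa <- group_freqs(gm, groups, A)
  fb <- group_freqs(gm, groups, B)
  use <- fa$n >= 4 & fb$n >= 4
  if (!any(use)) stop("no co-typed sites with >= 2 samples per group")
  x <- f2_per_site(fa, fb)[use]
  jk <- block_jackknife(x, block_size)
  stat <- mean(x)
  structure(list(stat = stat, se = jk$se,
                 z = if (!is.na(jk$se) && jk$se > 0) stat / jk$se else NA_real_,
                 n_sites = length(x), block_size = block_size,
                 pops = c(A, B)),
            class = "fstat_result")
}

#' f4 admixture statistic
#'
#' `f4(A, B; C, D)` computed through the f2 decomposition
#' `(f2(A,D) + f2(B,C) - f2(A,C) - f2(B,D)) / 2`, under which the sampling
#' corrections cancel for four distinct groups and the identities
#' `f4(A,B;C,C) = 0`, `f4(A,B;A,B) = f2(A,B)` and antisymmetry in (A,B)
#' hold exactly. Z-scores come from a block jackknife over contiguous SNP
#' blocks; `|Z| >= 3` is conventionally treated as significant evidence
#' against treeness.
#'
#' @param gm a [genotype_matrix()]
#' @param groups named vector mapping sample id to group label
#' @param A,B,C,D distinct group labels
#' @param block_size jackknife block length in SNPs (default 500)
#' @return an `fstat_result` (with `significant` flag at `|Z| >= 3`)
#' @export
f4_stat <- function(gm, groups, A, B, C, D, block_size = 500) {
  labs <- c(A, B, C, D)
  # groups is a sample -> label mapping, so distinct labels cannot share
  # samples; guard against a many-to-many grouping object all the same
  g <- groups[gm$sample_ids]
  if (any(vapply(split(gm$sample_ids, g), anyDuplicated, 0L) > 0)) {
    stop("overlapping group memberships between tested populations")
  }
  fr <- lapply(stats::setNames(unique(labs), unique(labs)),
               function(l) group_freqs(gm, groups, l))
  use <- Reduce(`&`, lapply(fr, function(f) f$n >= 4))
  if (!any(use)) stop("no usable co-typed sites")
  f2s <- function(x, y) {
    if (identical(x, y)) return(rep(0, sum(use)))
    f2_per_site(fr[[x]], fr[[y]])[use]
  }
  x <- (f2s(A, D) + f2s(B, C) - f2s(A, C) - f2s(B, D)) / 2
  jk <- block_jackknife(x, block_size)
  stat <- mean(x)
  z <- if (!is.na(jk$se) && jk$se > 0) stat / jk$se else NA_real_
  structure(list(stat = stat, se = jk$se, z = z,
                 significant = !is.na(z) && abs(z) >= 3,
                 n_sites = length(x), block_size = block_size,
                 pops = labs),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("f-statistic (%s): %.6g (SE %.3g, Z %.3g, %d sites)\n",
              paste(x$pops, collapse = ","), x$stat, x$se, x$z, x$n_sites))
  invisible(x)
}
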