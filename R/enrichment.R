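#' Round half-up percentage
#'
#' `100 * num / den` rounded half-up to 2 decimals (base `round()` rounds
#' half to even, which would mis-print tabulated proportions).
#'
#' @param num,den counts
#' @return numeric percentage
#' @export
percent_half_up <- function(num, den) {
  if (den == 0) return(NaN)
  x <- 100 * num / den
  floor(x * 100 + 0.5) / 100
}

#' Map SNP positions into genomic windows
#'
#' Windows are 0-based half-open `[start, end)`; a SNP at 1-based position
#' `P` falls in a window iff `start <= P - 1 < end`. Windows must be sorted
#' and non-overlapping per contig.
#'
#' @param sites data.frame with `contig` and `pos` (1-based)
#' @param windows data.frame with `contig`, `start`, `end`
#' @return logical vector: does each SNP fall in any window
#' @export
snp_in_window <- function(sites, windows) {
  out <- logical(nrow(sites))
  for (ctg in unique(sites$contig)) {
    w <- windows[windows$contig == ctg, , drop = FALSE]
    si <- which(sites$contig == ctg)
    if (nrow(w) == 0) next
    if (is.unsorted(w$start, strictly = TRUE)) stop("unsorted windows")
    if (any(w$start[-1] < w$end[-nrow(w)])) stop("overlapping windows")
    p0 <- sites$pos[si] - 1L
    iv <- findInterval(p0, w$start)
    hit <- iv >= 1 & p0 < w$end[pmax(iv, 1)]
    out[si] <- hit
  }
  out
}

#' Join temperature outliers, GIDs and selection calls into an enrichment
#' report
#'
#' The synthesis table of the pipeline: how many SNPs are temperature
#' outliers, how many of the top outliers sit in genomic islands of
#' differentiation (GID), how many of those are under divergent selection,
#' and how these proportions compare with the genome-wide fraction under
#' selection. Percentages are exact recomputations from the counts (rounded
#' half-up to 2 decimals for display; raw fractions kept alongside).
#'
#' @param outliers an [outlier_scan()] table
#' @param gids a [call_gids()] window subset
#' @param selection a [call_selection()] result whose loci correspond
#'   one-to-one (in order) to the rows of `outliers`
#' @return list of class `enrichment_report`
#' @export
build_report <- function(outliers, gids, selection) {
  n_snps <- nrow(outliers)
  if (length(selection$posterior) != n_snps) {
    stop("mismatched SNP sets: outlier table has ", n_snps,
         " SNPs but selection call has ", length(selection$posterior))
  }
  sel <- logical(n_snps)
  sel[selection$flagged] <- TRUE
  in_gid <- snp_in_window(outliers[, c("contig", "pos")], gids)

  n_out <- sum(outliers$is_outlier)
  top <- outliers$is_top
  n_top <- sum(top)
  n_top_gid <- sum(top & in_gid)
  n_top_sel <- sum(top & sel)
  n_top_gid_sel <- sum(top & in_gid & sel)
  genome_frac_sel <- mean(sel)

  ratio <- function(num, den, base) {
    if (den == 0 || base == 0) return(NA_real_)
    (num / den) / base
  }
  structure(list(
    n_snps = n_snps,
    n_outliers = n_out,
    pct_outliers = percent_half_up(n_out, n_snps),
    n_top = n_top,
    n_top_in_gid = n_top_gid,
    pct_top_in_gid = percent_half_up(n_top_gid, n_top),
    n_top_selected = n_top_sel,
    pct_top_selected = percent_half_up(n_top_sel, n_top),
    n_top_in_gid_selected = n_top_gid_sel,
    pct_top_in_gid_selected = percent_half_up(n_top_gid_sel, n_top_gid),
    genome_fraction_selected = genome_frac_sel,
    pct_genome_selected = percent_half_up(sum(sel), n_snps),
    enrich_top_selected = ratio(n_top_sel, n_top, genome_frac_sel),
    enrich_top_gid_selected = ratio(n_top_gid_sel, n_top_gid,
                                    genome_frac_sel)
  ), class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("Temperature outlier SNPs: %d of %d (%.2f%%) at q < 0.1\n",
              x$n_outliers, x$n_snps, x$pct_outliers))
  cat(sprintf("Top %d outliers in GIDs: %d (%.2f%%)\n",
              x$n_top, x$n_top_in_gid, x$pct_top_in_gid))
  cat(sprintf("Top outliers under divergent selection: %d (%.2f%%)\n",
              x$n_top_selected, x$pct_top_selected))
  cat(sprintf("Top outliers in GIDs and under selection: %d of %d (%.2f%%)\n",
              x$n_top_in_gid_selected, x$n_top_in_gid,
              x$pct_top_in_gid_selected))
  cat(sprintf("Genome-wide fraction under divergent selection: %.2f%%\n",
              x$pct_genome_selected))
  cat(sprintf("Enrichment (top-selected / genome): %.2f\n",
              x$enrich_top_selected))
  cat(sprintf("Enrichment (top-in-GID-selected / genome): %.2f\n",
              x$enrich_top_gid_selected))
  invisible(x)
}

#' Write an enrichment report as TSV
#' @param report an `enrichment_report`
#' @param path output path
#' @return `path` invisibly
#' @export
write_report <- function(report, path) {
  df <- data.frame(field = names(unclass(report)),
                   value = unlist(unclass(report)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
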