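#' Construct a genotype matrix object
#'
#' The central container of the pipeline: a samples x sites matrix of diploid
#' ALT-allele dosages (0, 1, 2 or `NA` for missing) together with per-site
#' records (contig, 1-based position, QUAL) and ordered sample identifiers.
#'
#' @param dosages integer matrix, samples in rows, sites in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `contig`, `pos` (1-based), `qual`.
#'   Positions must be strictly increasing within each contig.
#' @param sample_ids character vector of row identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sites, sample_ids) {
  dosages <- as.matrix(dosages)
  stopifnot(
    nrow(dosages) == length(sample_ids),
    ncol(dosages) == nrow(sites),
    all(c("contig", "pos", "qual") %in% names(sites))
  )
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  for (ctg in unique(sites$contig)) {
    p <- sites$pos[sites$contig == ctg]
    if (any(diff(p) <= 0)) {
      stop("site positions must be strictly increasing within contig ", ctg)
    }
  }
  rownames(dosages) <- sample_ids
  structure(
    list(dosages = dosages, sites = as.data.frame(sites),
         sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf(
    "genotype_matrix: %d samples x %d sites on %d contig(s), %.2f%% missing\n",
    n_samples(x), n_sites(x), length(unique(x$sites$contig)), 100 * miss
  ))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param gm a `genotype_matrix`
#' @return integer count
#' @export
n_samples <- function(gm) nrow(gm$dosages)

#' @rdname n_samples
#' @export
n_sites <- function(gm) ncol(gm$dosages)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param gm a `genotype_matrix`
#' @param samples index vector (integer, logical or sample id) over samples
#' @param sites index vector (integer or logical) over sites
#' @return a `genotype_matrix`
#' @export
gm_subset <- function(gm, samples = NULL, sites = NULL) {
  d <- gm$dosages
  ids <- gm$sample_ids
  rec <- gm$sites
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, ids)
    d <- d[samples, , drop = FALSE]
    ids <- ids[samples]
  }
  if (!is.null(sites)) {
    d <- d[, sites, drop = FALSE]
    rec <- rec[sites, , drop = FALSE]
    rownames(rec) <- NULL
  }
  genotype_matrix(d, rec, ids)
}

gt_to_dosage <- function(gt) {
  # unphased or phased diploid GT string -> ALT dosage
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[gt %in% c("1/1", "1|1")] <- 2L
  out
}

#' Read a VCF file into a genotype matrix
#'
#' Keeps biallelic SNP records only; multi-allelic or non-SNP records are
#' dropped and counted in a warning. Genotypes `./.` become missing.
#'
#' @param path path to an (uncompressed or gzipped) VCF with a GT field
#' @return a `genotype_matrix`; the number of excluded records is attached as
#'   attribute `n_excluded`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  n_excluded <- sum(!is_snp)
  if (n_excluded > 0) {
    warning(n_excluded, " multi-allelic or non-SNP record(s) excluded")
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = nrow(fix),
                     dimnames = list(NULL, colnames(vcf@gt)[-1]))
  }
  gt_raw <- gt_raw[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  dos <- apply(gt_raw, 2, gt_to_dosage)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1)
  sites <- data.frame(
    contig = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    qual = as.numeric(fix[, "QUAL"]),
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(t(dos), sites, colnames(gt_raw))
  attr(gm, "n_excluded") <- n_excluded
  gm
}

#' Write a genotype matrix as a minimal VCF v4.2 file
#'
#' Emits `CHROM POS ID REF ALT QUAL FILTER INFO FORMAT` columns with
#' `REF = A`, `ALT = T`, `FILTER = PASS` and unphased GT genotypes, the
#' subset of VCF the simulator produces.
#'
#' @param gm a `genotype_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(gm, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- gm$dosages
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[as.character(d[ok])]
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  )
  body <- paste(
    gm$sites$contig, gm$sites$pos, ".", "A", "T",
    format(gm$sites$qual, trim = TRUE), "PASS", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
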