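#' Fit a redundancy analysis of genotypes on environment predictors
#'
#' Constrained ordination of the centered (unscaled) dosage matrix on
#' sample-level environment predictors — multivariate regression followed by
#' an eigen-decomposition of the fitted values, via
#' \code{vegan::\link[vegan]{rda}}. Each sample inherits the retained
#' environment PCs of its site.
#'
#' @param gm a [genotype_matrix()] with no missing data (pruned input)
#' @param env_predictors data.frame/matrix of predictors, one row per sample
#'   in `gm` order (e.g. from [sample_env_predictors()])
#' @return list of class `rda_model`: the vegan fit (`fit`), per-SNP
#'   `loadings` on the constrained axes, constrained `eigenvalues`,
#'   `n_axes_retained` (broken-stick rule, >= 1), `prop_constrained`
#' @export
fit_rda <- function(gm, env_predictors) {
  Y <- gm$dosages
  if (anyNA(Y)) stop("RDA requires no missing data; filter and prune first")
  X <- as.data.frame(env_predictors)
  if (nrow(X) != nrow(Y)) stop("predictor rows must match samples")
  if (nrow(Y) < ncol(X) + 2) stop("need at least predictors + 2 samples")
  qrX <- qr(scale(as.matrix(X), center = TRUE, scale = FALSE))
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient (collinear) predictors: ",
         paste(bad, collapse = ", "))
  }
  fit <- vegan::rda(Y ~ ., data = X)
  k <- length(fit$CCA$eig)
  loadings <- fit$CCA$v[, seq_len(k), drop = FALSE]
  eig <- fit$CCA$eig
  # retain axes above the broken-stick expectation, min 1, max k
  bs <- rev(cumsum(1 / rev(seq_len(k)))) / k
  n_ax <- max(1L, sum(eig / sum(eig) > bs))
  structure(
    list(fit = fit, loadings = loadings, eigenvalues = unname(eig),
         n_axes_retained = as.integer(n_ax),
         prop_constrained = sum(eig) / fit$tot.chi,
         sites = gm$sites),
    class = "rda_model"
  )
}

#' Expand per-site environment PCs to per-sample predictors
#'
#' @param env environment table (`site_id` column + descriptors)
#' @param meta sample metadata with `sample_id` and `site` columns
#' @param variance_target,max_pcs as in [env_pca_distance()]
#' @return data.frame of retained PCs, one row per sample in `meta` order
#' @export
sample_env_predictors <- function(env, meta, variance_target = 0.80,
                                  max_pcs = 5) {
  dm <- env_pca_distance(env, variance_target = variance_target,
                         max_pcs = max_pcs, level = "site")
  scores <- attr(dm, "scores")
  idx <- match(meta$site, rownames(scores))
  if (anyNA(idx)) stop("sites in metadata missing from environment table")
  out <- as.data.frame(scores[idx, , drop = FALSE])
  rownames(out) <- meta$sample_id
  out
}

#' Scan RDA loadings for genotype-environment outlier SNPs
#'
#' The Mahalanobis-distance outlier protocol of landscape-genomics RDA:
#' per-SNP loadings on the retained constrained axes are scaled per axis,
#' their squared Mahalanobis distance `D2` is rescaled by the genomic
#' inflation factor `lambda = median(D2) / qchisq(0.5, df)`, p-values are
#' the upper chi-squared tail with `df = n_axes`, and q-values are
#' Benjamini-Hochberg. SNPs with `q < q_threshold` are outliers; the
#' `top_n` lowest-p SNPs (ties by larger `D2`, then genomic position) are
#' flagged `is_top`.
#'
#' @param model an `rda_model`
#' @param n_axes number of retained axes to use (default
#'   `model$n_axes_retained`)
#' @param q_threshold outlier q-value threshold (default 0.1)
#' @param top_n size of the top set (default 100)
#' @return data.frame of class `outlier_table`: `contig`, `pos`, `D2`, `p`,
#'   `q`, `is_outlier`, `is_top`; attribute `lambda`
#' @export
outlier_scan <- function(model, n_axes = model$n_axes_retained,
                         q_threshold = 0.1, top_n = 100) {
  if (n_axes > ncol(model$loadings)) stop("n_axes exceeds model axes")
  Z <- model$loadings[, seq_len(n_axes), drop = FALSE]
  if (nrow(Z) <= n_axes) stop("fewer SNPs than axes")
  Z <- scale(Z)
  D2 <- stats::mahalanobis(Z, colMeans(Z), stats::cov(Z))
  lambda <- stats::median(D2) / stats::qchisq(0.5, df = n_axes)
  p <- stats::pchisq(D2 / lambda, df = n_axes, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  q <- stats::p.adjust(p, method = "BH")
  ord <- order(p, -D2, model$sites$contig, model$sites$pos)
  is_top <- logical(length(p))
  is_top[ord[seq_len(min(top_n, length(p)))]] <- TRUE
  out <- data.frame(contig = model$sites$contig, pos = model$sites$pos,
                    D2 = D2, p = p, q = q,
                    is_outlier = q < q_threshold, is_top = is_top,
                    stringsAsFactors = FALSE)
  attr(out, "lambda") <- lambda
  attr(out, "n_axes") <- n_axes
  class(out) <- c("outlier_table", "data.frame")
  out
}
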