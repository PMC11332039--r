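#' Genotype PCA
#'
#' PCA of the column-centered (unscaled) dosage matrix — the convention of
#' allele-count PCA for genotype data. Eigenvalues are those of the sample
#' covariance matrix; scores are the centered data projected on the
#' loadings. Deterministic up to component sign.
#'
#' @param gm a [genotype_matrix()] with no missing data
#' @param n_components number of components to return
#' @param scale. logical; also scale columns to unit variance (default FALSE)
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `eigenvalues`, `loadings` (sites x components), `prop_var`
#' @export
gt_pca <- function(gm, n_components = 10, scale. = FALSE) {
  d <- gm$dosages
  if (anyNA(d)) stop("PCA requires no missing data; filter first")
  if (n_components > min(dim(d))) {
    stop("n_components exceeds min(samples, sites)")
  }
  pr <- stats::prcomp(d, center = TRUE, scale. = scale.)
  ev <- pr$sdev^2
  structure(
    list(scores = pr$x[, seq_len(n_components), drop = FALSE],
         eigenvalues = ev,
         loadings = pr$rotation[, seq_len(n_components), drop = FALSE],
         prop_var = ev / sum(ev)),
    class = "pca_result"
  )
}

# one-hot encode dosages: n x (3L) matrix of indicators for genotype 0/1/2;
# missing entries produce an all-zero triple, matched by a 0 weight mask
one_hot_genotypes <- function(d) {
  n <- nrow(d); L <- ncol(d)
  X <- matrix(0, n, 3L * L)
  W <- matrix(0, n, 3L * L)
  for (g in 0:2) {
    cols <- 3L * (seq_len(L) - 1L) + g + 1L
    X[, cols] <- (d == g & !is.na(d)) * 1
  }
  obs <- !is.na(d)
  for (g in 0:2) {
    cols <- 3L * (seq_len(L) - 1L) + g + 1L
    W[, cols] <- obs * 1
  }
  list(X = X, W = W)
}

# Euclidean projection of each row of Q onto the probability simplex
project_rows_simplex <- function(Q) {
  t(apply(Q, 1, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u - (css - 1) / seq_along(u) > 0))
    tau <- (css[rho] - 1) / rho
    pmax(v - tau, 0)
  }))
}

#' Estimate ancestry coefficients by regularized nonnegative factorization
#'
#' A least-squares stand-in for sparse-NMF ancestry estimation: the one-hot
#' encoded genotype matrix `X` (samples x 3*sites) is factorized as `Q G`
#' with admixture rows `Q` on the probability simplex, ancestral
#' genotype-frequency entries `G` in `[0, 1]`, and a ridge penalty
#' `alpha * ||G||^2`. Projected-gradient block updates guarantee a
#' non-increasing objective; the best of `n_restarts` random starts is kept.
#'
#' @param gm a [genotype_matrix()]
#' @param K number of ancestral populations (>= 1)
#' @param seed integer RNG seed
#' @param alpha ridge penalty on `G` (default 10)
#' @param n_restarts random restarts (default 10)
#' @param max_iter outer iterations per restart (default 100)
#' @param tol relative objective change convergence tolerance
#' @param mask optional logical matrix (samples x sites): entries to hold
#'   out of the fit (used by the cross-entropy criterion)
#' @return list of class `ancestry_result`: `K`, `Q` (rows sum to 1), `G`
#'   (K x 3*sites in `[0,1]`), `objective`, `converged`
#' @export
estimate_ancestry <- function(gm, K, seed = 1, alpha = 10, n_restarts = 10,
                              max_iter = 100, tol = 1e-6, mask = NULL) {
  stopifnot(K >= 1)
  d <- gm$dosages
  oh <- one_hot_genotypes(d)
  X <- oh$X; W <- oh$W
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(d)))
    for (g in 0:2) {
      cols <- 3L * (seq_len(ncol(d)) - 1L) + g + 1L
      W[, cols] <- W[, cols] * (!mask)
    }
  }
  n <- nrow(X)
  if (K == 1) {
    Q <- matrix(1, n, 1, dimnames = list(gm$sample_ids, NULL))
    G <- matrix(colSums(W * X) / pmax(colSums(W), 1), 1)
    obj <- sum(W * (X - Q %*% G)^2) + alpha * sum(G^2)
    return(structure(list(K = 1L, Q = Q, G = G, objective = obj,
                          converged = TRUE),
                     class = "ancestry_result"))
  }
  set.seed(seed)
  best <- NULL
  xbar <- colSums(W * X) / pmax(colSums(W), 1)
  # PCA scores drive the k-means initialization of Q (breaks the symmetric
  # stationary point where all ancestral profiles coincide)
  d_imp <- d
  if (anyNA(d_imp)) {
    cm <- colMeans(d_imp, na.rm = TRUE)
    nas <- which(is.na(d_imp), arr.ind = TRUE)
    d_imp[nas] <- cm[nas[, 2]]
  }
  pcs <- tryCatch(
    stats::prcomp(d_imp, center = TRUE)$x[, seq_len(min(K, ncol(d_imp), nrow(d_imp) - 1)), drop = FALSE],
    error = function(e) matrix(stats::rnorm(n * K), n))
  for (rs in seq_len(n_restarts)) {
    km <- tryCatch(stats::kmeans(pcs, centers = K, nstart = 1),
                   error = function(e) list(cluster = sample.int(K, n, TRUE)))
    Q <- matrix(0.1 / max(K - 1, 1), n, K)
    Q[cbind(seq_len(n), km$cluster)] <- 0.9
    # ancestral profiles: within-cluster mean one-hot frequencies, shrunk
    G <- t(vapply(seq_len(K), function(k) {
      idx <- which(km$cluster == k)
      if (length(idx) == 0) idx <- sample.int(n, 1)
      0.8 * colSums(X[idx, , drop = FALSE]) / max(length(idx), 1) + 0.2 * xbar
    }, numeric(ncol(X))))
    obj <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # G step: projected gradient, Lipschitz bound from Q'Q (W <= 1)
      R <- W * (Q %*% G - X)
      LG <- 2 * (norm(crossprod(Q), "2") + alpha)
      G <- G - (2 * (crossprod(Q, R) + alpha * G)) / LG
      G[G < 0] <- 0; G[G > 1] <- 1
      # Q step: projected gradient onto row simplices
      R <- W * (Q %*% G - X)
      LQ <- 2 * max(norm(tcrossprod(G), "2"), 1e-8)
      Q <- project_rows_simplex(Q - (2 * (R %*% t(G))) / LQ)
      obj_new <- sum((W * (X - Q %*% G))^2) + alpha * sum(G^2)
      if (is.finite(obj) && abs(obj - obj_new) <= tol * max(obj, 1)) {
        obj <- obj_new
        converged <- TRUE
        break
      }
      obj <- obj_new
    }
    if (is.null(best) || obj < best$objective) {
      best <- list(K = as.integer(K), Q = Q, G = G, objective = obj,
                   converged = converged)
    }
  }
  if (!best$converged) warning("ancestry estimation did not fully converge")
  rownames(best$Q) <- gm$sample_ids
  structure(best, class = "ancestry_result")
}

# per-entry predicted genotype-class probabilities for (sample, site) pairs
predict_geno_prob <- function(Q, G, sample_idx, site_idx) {
  P <- matrix(NA_real_, length(sample_idx), 3)
  for (g in 0:2) {
    cols <- 3L * (site_idx - 1L) + g + 1L
    P[, g + 1L] <- rowSums(Q[sample_idx, , drop = FALSE] *
                             t(G[, cols, drop = FALSE]))
  }
  P <- pmax(P, 1e-9)
  P / rowSums(P)
}

#' Choose the number of ancestral populations by cross-entropy
#'
#' Masks a fraction of genotype entries, fits each candidate `K` on the
#' unmasked data, and scores the masked entries by the cross-entropy of
#' their observed genotype class under the predicted class probabilities
#' `Q G`. The best `K` minimizes this held-out criterion.
#'
#' @param gm a [genotype_matrix()]
#' @param K_range integer vector of candidate K (subset of 1..20)
#' @param holdout_fraction fraction of entries masked (default 0.05)
#' @param seed integer RNG seed
#' @param ... passed to [estimate_ancestry()]
#' @return list: `best_K`, `cross_entropy` (named numeric over `K_range`),
#'   `fits` (list of `ancestry_result`)
#' @export
choose_K <- function(gm, K_range = 1:5, holdout_fraction = 0.05, seed = 1,
                     ...) {
  stopifnot(all(K_range >= 1), all(K_range <= 20))
  d <- gm$dosages
  set.seed(seed)
  mask <- matrix(stats::runif(length(d)) < holdout_fraction, nrow(d))
  mask <- mask & !is.na(d)
  if (sum(mask) < 10) stop("holdout too small to score; increase data or fraction")
  midx <- which(mask, arr.ind = TRUE)
  obs_class <- d[mask] + 1L
  oh <- one_hot_genotypes(d)
  X <- oh$X
  W <- oh$W
  for (g in 0:2) {
    cols <- 3L * (seq_len(ncol(d)) - 1L) + g + 1L
    W[, cols] <- W[, cols] * (!mask)
  }
  xbar <- colSums(W * X) / pmax(colSums(W), 1)
  ce <- stats::setNames(numeric(length(K_range)), K_range)
  fits <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    fit <- estimate_ancestry(gm, K, seed = seed + i, mask = mask, ...)
    # held-out genotype-class probabilities from smoothed ancestral
    # frequencies re-estimated given Q (pseudo-count toward the pooled
    # frequencies, so predictions are never degenerate)
    num <- crossprod(fit$Q, W * X)
    den <- crossprod(fit$Q, W)
    G_pred <- (num + matrix(xbar, K, ncol(X), byrow = TRUE)) / (den + 1)
    P <- predict_geno_prob(fit$Q, G_pred, midx[, 1], midx[, 2])
    ce[i] <- -mean(log(P[cbind(seq_len(nrow(P)), obs_class)]))
    fits[[i]] <- fit
  }
  # which.min breaks exact ties toward the smaller K (parsimony)
  list(best_K = K_range[which.min(ce)], cross_entropy = ce, fits = fits)
}

#' Assign each sample to its majority ancestral cluster
#'
#' @param ancestry an `ancestry_result`
#' @return integer vector of cluster labels (arg-max admixture coefficient),
#'   named by sample
#' @export
cluster_assignment <- function(ancestry) {
  a <- apply(ancestry$Q, 1, which.max)
  stats::setNames(as.integer(a), rownames(ancestry$Q))
}

#' Second-round subclustering within each ancestral cluster
#'
#' Re-runs the cross-entropy K choice and ancestry estimation separately on
#' the samples of each first-round cluster (assignment by highest admixture
#' coefficient), to expose within-lineage subclades. Clusters with fewer
#' than 4 samples are skipped with a warning.
#'
#' @param gm a [genotype_matrix()]
#' @param ancestry first-round `ancestry_result`
#' @param K_range candidate K per subcluster (default 1:3)
#' @param seed integer RNG seed
#' @param ... passed to [choose_K()]
#' @return named list (one element per cluster) of [choose_K()] results,
#'   `NULL` for skipped clusters
#' @export
subcluster <- function(gm, ancestry, K_range = 1:3, seed = 1, ...) {
  assign <- cluster_assignment(ancestry)
  out <- list()
  for (k in sort(unique(assign))) {
    members <- names(assign)[assign == k]
    if (length(members) < 4) {
      warning("cluster ", k, " has < 4 samples; skipped")
      out[[as.character(k)]] <- NULL
      next
    }
    sub <- gm_subset(gm, samples = members)
    # drop sites monomorphic within the cluster (uninformative)
    poly <- apply(sub$dosages, 2, function(x) length(unique(x[!is.na(x)])) > 1)
    if (sum(poly) >= 10) sub <- gm_subset(sub, sites = poly)
    out[[as.character(k)]] <- choose_K(sub, K_range = K_range,
                                       seed = seed + k, ...)
  }
  out
}
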