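#' Linearize an FST matrix as FST / (1 - FST)
#'
#' The standard linearization for isolation-by-distance regressions; small
#' negative FST estimates are retained (flagged via attribute
#' `n_negative`).
#'
#' @param fst_matrix symmetric FST matrix with entries < 1
#' @return matrix of the same shape
#' @export
linearize_fst <- function(fst_matrix) {
  if (any(fst_matrix >= 1)) stop("FST = 1 linearizes to an infinite distance")
  out <- fst_matrix / (1 - fst_matrix)
  attr(out, "n_negative") <- sum(out[lower.tri(out)] < 0)
  out
}

#' Great-circle distance matrix between coordinates
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param coords data.frame or matrix with columns `lon` and `lat` in
#'   decimal degrees; row names (or a `label` column) label the matrix
#' @return symmetric distance matrix in km
#' @export
great_circle_km <- function(coords) {
  coords <- as.data.frame(coords)
  labels <- if ("label" %in% names(coords)) coords$label else rownames(coords)
  lon <- coords$lon %% 360
  lon <- ifelse(lon > 180, lon - 360, lon)
  lat <- coords$lat
  if (any(lat < -90 | lat > 90) || any(is.na(lon)) || any(is.na(lat))) {
    stop("invalid coordinates")
  }
  m <- geosphere::distm(cbind(lon, lat),
                        fun = function(p1, p2) {
                          geosphere::distHaversine(p1, p2, r = 6371)
                        })
  dimnames(m) <- list(labels, labels)
  m
}

#' Island coordinates as the mean of their site coordinates
#'
#' @param meta sample metadata with columns `island`, `lat`, `lon`
#' @return data.frame with one row per island: `island`, `lat`, `lon`
#' @export
island_coordinates <- function(meta) {
  agg <- stats::aggregate(meta[, c("lat", "lon")],
                          by = list(island = meta$island), FUN = mean)
  rownames(agg) <- agg$island
  agg
}

#' Environmental distance from a PCA-reduced descriptor table
#'
#' Standardizes the descriptor columns (constant columns dropped with a
#' warning), runs a PCA, retains the smallest number of components whose
#' cumulative variance reaches `variance_target` (capped at `max_pcs`), and
#' returns Euclidean distances between rows on the retained scores. With
#' `level = "island"`, site scores are first averaged per island.
#'
#' @param env environment table: a data.frame with a `site_id` column,
#'   optionally an `island` column, and numeric descriptor columns
#' @param variance_target cumulative variance fraction to reach (default 0.80)
#' @param max_pcs cap on retained components (default 5)
#' @param level `"site"` or `"island"`
#' @return distance matrix; attributes `n_pcs` and `scores`
#' @export
env_pca_distance <- function(env, variance_target = 0.80, max_pcs = 5,
                             level = c("site", "island")) {
  level <- match.arg(level)
  meta_cols <- intersect(c("site_id", "island"), names(env))
  X <- as.matrix(env[, setdiff(names(env), meta_cols), drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 sites")
  if (anyNA(X)) stop("missing descriptor values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant descriptor column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  pv <- pr$sdev^2 / sum(pr$sdev^2)
  n_pcs <- min(which(cumsum(pv) >= variance_target - 1e-12)[1], max_pcs,
               na.rm = TRUE)
  if (is.na(n_pcs)) n_pcs <- min(max_pcs, length(pv))
  scores <- pr$x[, seq_len(n_pcs), drop = FALSE]
  labels <- if ("site_id" %in% names(env)) env$site_id else rownames(env)
  rownames(scores) <- labels
  if (level == "island") {
    if (!"island" %in% names(env)) stop("island column required for island level")
    scores <- apply(scores, 2, function(col) {
      tapply(col, env$island, mean)
    })
    if (is.null(dim(scores))) scores <- matrix(scores, ncol = n_pcs)
  }
  m <- as.matrix(stats::dist(scores))
  attr(m, "n_pcs") <- n_pcs
  attr(m, "scores") <- scores
  m
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles with a one-sided (greater)
#' permutation test: `p = (1 + #{permuted r >= observed}) / (1 + n_perm)`,
#' permuting rows and columns of `y` simultaneously. Backed by
#' \code{vegan::\link[vegan]{mantel}}.
#'
#' @param x,y symmetric distance matrices with matching labels (y is
#'   reordered to x's labels when both are labelled)
#' @param n_perm number of permutations (default 9999)
#' @param seed integer RNG seed
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `seed`
#' @export
mantel_test <- function(x, y, n_perm = 9999, seed = 1) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!is.null(rownames(x)) && !is.null(rownames(y))) {
    if (!setequal(rownames(x), rownames(y))) stop("label sets differ")
    y <- y[rownames(x), rownames(x)]
  }
  if (nrow(x) < 4) stop("need at least 4 labels")
  if (stats::sd(x[lower.tri(x)]) == 0 || stats::sd(y[lower.tri(y)]) == 0) {
    stop("zero-variance distance triangle")
  }
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(x), stats::as.dist(y),
                      method = "pearson", permutations = n_perm)
  structure(list(r = unname(mt$statistic), p = mt$signif,
                 n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.3f, P = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}
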