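#' Per-population allele counts from a genotype matrix
#'
#' @param gm a [genotype_matrix()]
#' @param groups named vector mapping sample id to population label
#' @return list with `alt` and `total` allele-count matrices (loci x
#'   populations) and `sites`
#' @export
allele_counts <- function(gm, groups) {
  g <- factor(groups[gm$sample_ids])
  idx <- split(seq_along(g), g)
  alt <- sapply(idx, function(i) colSums(gm$dosages[i, , drop = FALSE],
                                         na.rm = TRUE))
  total <- sapply(idx, function(i) {
    2 * colSums(!is.na(gm$dosages[i, , drop = FALSE]))
  })
  list(alt = as.matrix(alt), total = as.matrix(total), sites = gm$sites)
}

# beta-binomial log-likelihood matrix (loci x pops), marginalizing the
# population allele frequency of the Balding-Nichols / F-model:
#   p_{l,p} ~ Beta(theta*pbar_l, theta*(1-pbar_l)),
#   theta_{l,p} = (1 - F)/F,  F_{l,p} = plogis(alpha_l + beta_p)
# so log theta = -(alpha_l + beta_p). The binomial choose term is constant
# in the parameters and omitted.
fmodel_loglik <- function(y, n, pbar, alpha, beta) {
  theta <- exp(-outer(alpha, beta, `+`))
  a <- theta * pbar
  b <- theta * (1 - pbar)
  lbeta_mat <- function(x, y) lgamma(x) + lgamma(y) - lgamma(x + y)
  lbeta_mat(y + a, n - y + b) - lbeta_mat(a, b)
}

#' Fit the hierarchical F-model selection scan by MCMC
#'
#' Locus-specific selection effects `alpha_l` and population-specific drift
#' effects `beta_p` decompose locus-by-population FST as
#' `F = plogis(alpha_l + beta_p)`; population allele frequencies are
#' Balding-Nichols draws around ancestral frequencies `pbar_l`, and observed
#' ALT counts are binomial — marginalized here to a beta-binomial
#' likelihood. `alpha_l` carries a spike-and-slab prior (point mass at 0
#' with prior inclusion `pi_alpha`; Gaussian slab), so the posterior
#' inclusion probability of a positive effect is the per-locus evidence of
#' divergent selection. Metropolis-within-Gibbs updates are vectorized
#' across loci (independent given `beta`) and across populations.
#'
#' @param counts list with `alt`, `total` matrices (loci x populations),
#'   e.g. from [allele_counts()] or [simulate_allele_counts()]
#' @param n_iter total MCMC iterations (default 3000)
#' @param burn_in discarded iterations (default `n_iter %/% 3`)
#' @param thin keep every `thin`-th draw (default 5)
#' @param seed integer RNG seed
#' @param pi_alpha prior inclusion probability of the slab (default 0.1)
#' @param slab_sd slab prior SD (default 2)
#' @param beta_prior_mean,beta_prior_sd Gaussian prior on `beta_p`
#' @param fixed_beta optional numeric vector: hold `beta` fixed (two-pass
#'   contig mode, where demographic parameters converged in a first pass are
#'   reused)
#' @return list of class `fmodel_fit`: posterior draw matrices
#'   `alpha_draws`, `delta_draws`, `beta_draws`, per-locus
#'   `posterior_divergent` = P(delta = 1 and alpha > 0), split-Rhat per
#'   `beta`, acceptance rates, and the (possibly reduced) locus index
#'   `kept_loci` after dropping loci monomorphic across all populations
#' @export
fit_fmodel <- function(counts, n_iter = 3000, burn_in = n_iter %/% 3,
                       thin = 5, seed = 1, pi_alpha = 0.1, slab_sd = 2,
                       beta_prior_mean = -2, beta_prior_sd = 3,
                       fixed_beta = NULL) {
  y <- counts$alt
  n <- counts$total
  stopifnot(all(dim(y) == dim(n)), n_iter > burn_in)
  mono <- rowSums(y) == 0 | rowSums(y) == rowSums(n)
  if (any(mono)) {
    warning(sum(mono), " locus/loci monomorphic across all populations skipped")
    y <- y[!mono, , drop = FALSE]
    n <- n[!mono, , drop = FALSE]
  }
  L <- nrow(y)
  P <- ncol(y)
  if (P < 2) stop("need at least 2 populations")
  set.seed(seed)

  # initial values
  pbar <- pmin(pmax(rowSums(y) / rowSums(n), 0.02), 0.98)
  alpha <- rep(0, L)
  delta <- rep(FALSE, L)
  beta <- if (!is.null(fixed_beta)) rep_len(fixed_beta, P) else rep(-2, P)

  ll <- fmodel_loglik(y, n, pbar, alpha, beta) # loci x pops
  row_ll <- rowSums(ll)

  sd_pbar <- 0.3; sd_alpha <- 0.6; sd_beta <- 0.15; sd_slab_prop <- 1.5
  n_keep <- (n_iter - burn_in) %/% thin
  alpha_draws <- matrix(NA_real_, n_keep, L)
  delta_draws <- matrix(NA, n_keep, L)
  beta_draws <- matrix(NA_real_, n_keep, P)
  acc <- c(pbar = 0, alpha = 0, beta = 0)
  kept <- 0L

  lprior_alpha <- function(a) stats::dnorm(a, 0, slab_sd, log = TRUE)

  for (it in seq_len(n_iter)) {
    ## -- pbar update (logit random walk, uniform(0,1) prior) --------------
    lp <- stats::qlogis(pbar)
    lp_new <- lp + stats::rnorm(L, 0, sd_pbar)
    pbar_new <- stats::plogis(lp_new)
    ll_new <- fmodel_loglik(y, n, pbar_new, alpha, beta)
    row_new <- rowSums(ll_new)
    # Jacobian of the logit transform: log p(1-p)
    log_acc <- (row_new + log(pbar_new * (1 - pbar_new))) -
      (row_ll + log(pbar * (1 - pbar)))
    take <- log(stats::runif(L)) < log_acc
    pbar[take] <- pbar_new[take]
    ll[take, ] <- ll_new[take, , drop = FALSE]
    row_ll[take] <- row_new[take]
    acc["pbar"] <- acc["pbar"] + mean(take)

    ## -- alpha / delta update (spike-and-slab, vectorized over loci) ------
    # move 1: within-slab random walk for currently included loci
    if (any(delta)) {
      a_new <- alpha
      a_new[delta] <- alpha[delta] + stats::rnorm(sum(delta), 0, sd_alpha)
      ll_new <- fmodel_loglik(y, n, pbar, a_new, beta)
      row_new <- rowSums(ll_new)
      log_acc <- row_new - row_ll + lprior_alpha(a_new) - lprior_alpha(alpha)
      take <- delta & (log(stats::runif(L)) < log_acc)
      alpha[take] <- a_new[take]
      ll[take, ] <- ll_new[take, , drop = FALSE]
      row_ll[take] <- row_new[take]
      if (any(delta)) acc["alpha"] <- acc["alpha"] + mean(take[delta])
    }
    # move 2: toggle inclusion (birth from proposal q = N(0, sd_slab_prop),
    # death back to the point mass); independent across loci
    a_new <- ifelse(delta, 0, stats::rnorm(L, 0, sd_slab_prop))
    ll_new <- fmodel_loglik(y, n, pbar, a_new, beta)
    row_new <- rowSums(ll_new)
    lq <- stats::dnorm(a_new, 0, sd_slab_prop, log = TRUE)
    lq_old <- stats::dnorm(alpha, 0, sd_slab_prop, log = TRUE)
    log_prior_odds <- log(pi_alpha) - log(1 - pi_alpha)
    log_acc <- ifelse(
      delta,
      # death: remove alpha
      (row_new - row_ll) - lprior_alpha(alpha) - log_prior_odds + lq_old,
      # birth: add alpha = a_new
      (row_new - row_ll) + lprior_alpha(a_new) + log_prior_odds - lq
    )
    take <- log(stats::runif(L)) < log_acc
    alpha[take] <- a_new[take]
    delta[take] <- !delta[take]
    ll[take, ] <- ll_new[take, , drop = FALSE]
    row_ll[take] <- row_new[take]

    ## -- beta update (random walk, independent across populations) --------
    if (is.null(fixed_beta)) {
      b_new <- beta + stats::rnorm(P, 0, sd_beta)
      ll_new <- fmodel_loglik(y, n, pbar, alpha, b_new)
      col_old <- colSums(ll)
      col_new <- colSums(ll_new)
      log_acc <- (col_new + stats::dnorm(b_new, beta_prior_mean,
                                         beta_prior_sd, log = TRUE)) -
        (col_old + stats::dnorm(beta, beta_prior_mean, beta_prior_sd,
                                log = TRUE))
      take_b <- log(stats::runif(P)) < log_acc
      beta[take_b] <- b_new[take_b]
      if (any(take_b)) {
        ll[, take_b] <- ll_new[, take_b, drop = FALSE]
        row_ll <- rowSums(ll)
      }
      acc["beta"] <- acc["beta"] + mean(take_b)
    }

    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      alpha_draws[kept, ] <- alpha
      delta_draws[kept, ] <- delta
      beta_draws[kept, ] <- beta
    }
  }

  posterior_divergent <- colMeans(delta_draws & alpha_draws > 0)
  rhat <- apply(beta_draws, 2, split_rhat)
  non_conv <- any(!is.na(rhat) & rhat > 1.1)
  if (non_conv) warning("split-Rhat > 1.1 for at least one beta; ",
                        "increase n_iter")
  structure(
    list(alpha_draws = alpha_draws, delta_draws = delta_draws,
         beta_draws = beta_draws,
         posterior_divergent = posterior_divergent,
         beta_hat = colMeans(beta_draws), rhat_beta = rhat,
         converged = !non_conv,
         acceptance = acc / n_iter, kept_loci = which(!mono),
         settings = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                         seed = seed, pi_alpha = pi_alpha,
                         slab_sd = slab_sd)),
    class = "fmodel_fit"
  )
}

# split-Rhat of a single chain (first vs second half)
split_rhat <- function(x) {
  m <- length(x) %/% 2
  if (m < 4) return(NA_real_)
  halves <- list(x[seq_len(m)], x[(m + 1):(2 * m)])
  means <- vapply(halves, mean, 1)
  vars <- vapply(halves, stats::var, 1)
  W <- mean(vars)
  B <- m * stats::var(means)
  if (W == 0) return(1)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Call loci under divergent selection at a target FDR
#'
#' Loci are ranked by posterior probability of divergent selection; the
#' flagged set is the largest prefix whose mean posterior neutrality
#' `(1 - P)` does not exceed `fdr_target` — the posterior-alpha FDR rule of
#' F-model selection scans.
#'
#' @param fit an `fmodel_fit` (or any list with `posterior_divergent`)
#' @param fdr_target target false discovery rate in (0, 1)
#' @return list of class `selection_call`: `flagged` (locus indices, in the
#'   fit's locus order), `posterior`, `realized_fdr`, `fraction_flagged`
#' @export
call_selection <- function(fit, fdr_target = 0.05) {
  if (fdr_target <= 0 || fdr_target >= 1) stop("fdr_target must be in (0,1)")
  post <- fit$posterior_divergent
  ord <- order(post, decreasing = TRUE)
  cum_fdr <- cumsum(1 - post[ord]) / seq_along(ord)
  n_flag <- if (any(cum_fdr <= fdr_target)) max(which(cum_fdr <= fdr_target)) else 0L
  flagged <- if (n_flag > 0) sort(ord[seq_len(n_flag)]) else integer(0)
  structure(
    list(flagged = flagged, posterior = post,
         realized_fdr = if (n_flag > 0) cum_fdr[n_flag] else 0,
         fraction_flagged = n_flag / length(post),
         fdr_target = fdr_target),
    class = "selection_call"
  )
}

#' @export
print.selection_call <- function(x, ...) {
  cat(sprintf(
    "selection_call: %d/%d loci flagged (%.2f%%) at FDR %.3g (realized %.3g)\n",
    length(x$flagged), length(x$posterior), 100 * x$fraction_flagged,
    x$fdr_target, x$realized_fdr))
  invisible(x)
}
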