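#' @importFrom stats pchisq
NULL

# log10-scale weighted log-sum-exp: log10( sum(w * 10^x) )
.lse10 <- function(x, w) {
  keep <- w > 0
  if (!any(keep)) stop("empty weight support")
  x <- x[keep]; w <- w[keep]
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log10(sum(w * 10^(x - mx)))
}

#' Averaged Bayes factor over partitions and effect-size scales
#'
#' `BF_av = sum_gamma sum_k w_gamma pi_k BF(gamma, k)`, the prior-weighted
#' average of the per-partition Bayes factors, computed by log-sum-exp. With
#' all partition weight on the all-direct partition it reduces to the
#' standard multivariate test's `BF_all`; with equal weight `1/d` on the `d`
#' univariate-test partitions it reduces to `BF_uni`.
#'
#' @param log10_bfs matrix of log10 Bayes factors, one row per non-null
#'   partition of the prior (aligned with `prior@partitions`), one column per
#'   `sigma_a` grid point.
#' @param prior a [PartitionPrior-class].
#' @param sigma_weights probability vector over the `sigma_a` grid (defaults
#'   to uniform).
#' @return log10 of the averaged Bayes factor.
#' @export
bfAv <- function(log10_bfs, prior,
                 sigma_weights = rep(1 / ncol(log10_bfs), ncol(log10_bfs))) {
  log10_bfs <- as.matrix(log10_bfs)
  stopifnot(is(prior, "PartitionPrior"),
            nrow(log10_bfs) == length(prior@partitions),
            length(sigma_weights) == ncol(log10_bfs))
  sigma_weights <- sigma_weights / sum(sigma_weights)
  W <- outer(prior@weights, sigma_weights)
  .lse10(as.numeric(log10_bfs), as.numeric(W))
}

#' Posterior over partitions and trait categories
#'
#' Combines prior weights and Bayes factors into the posterior distribution
#' over partition models: `P(gamma | data) \propto (1 - pi0) w_gamma
#' BF(gamma)` and `P(H0 | data) = pi0 / (pi0 + (1 - pi0) BF_av)`. The two
#' routes to the null probability (direct formula and normalized partition
#' table) are computed and asserted to agree. Per-trait category
#' probabilities marginalize the partition posterior.
#'
#' @slot p_null posterior probability of the global null.
#' @slot partition_names partition strings for the non-null partitions.
#' @slot partition_probs posterior probabilities of the non-null partitions.
#' @slot trait_category_probs `d x 3` row-stochastic matrix with columns
#'   `U`, `D`, `I`.
#' @slot p_assoc per-trait posterior probability of association
#'   (`1 - P(trait in U)`).
#' @slot log10_bf_av log10 averaged Bayes factor.
#' @export
setClass("PosteriorSummary",
  representation(p_null = "numeric", partition_names = "character",
                 partition_probs = "numeric",
                 trait_category_probs = "matrix", p_assoc = "numeric",
                 log10_bf_av = "numeric"),
  validity = function(object) {
    tot <- object@p_null + sum(object@partition_probs)
    if (abs(tot - 1) > 1e-6) return("posterior probabilities must sum to 1")
    if (any(abs(rowSums(object@trait_category_probs) - 1) > 1e-6))
      return("trait category rows must sum to 1")
    TRUE
  }
)

setMethod("show", "PosteriorSummary", function(object) {
  cat("PosteriorSummary: log10 BF_av =", signif(object@log10_bf_av, 4),
      ", P(null) =", signif(object@p_null, 4), "\n")
  cat("Per-trait category probabilities:\n")
  print(round(object@trait_category_probs, 3))
  k <- order(object@partition_probs, decreasing = TRUE)
  k <- k[seq_len(min(3, length(k)))]
  cat("Top partitions:\n")
  for (i in k)
    cat(sprintf("  %-30s %.4f\n", object@partition_names[i],
                object@partition_probs[i]))
})

#' @rdname PosteriorSummary-class
#' @param log10_bfs,prior,sigma_weights as in [bfAv()].
#' @return `posteriorPartitions` returns a [PosteriorSummary-class].
#' @export
posteriorPartitions <- function(log10_bfs, prior,
                                sigma_weights = rep(1 / ncol(as.matrix(log10_bfs)),
                                                    ncol(as.matrix(log10_bfs)))) {
  log10_bfs <- as.matrix(log10_bfs)
  stopifnot(is(prior, "PartitionPrior"),
            nrow(log10_bfs) == length(prior@partitions))
  sigma_weights <- sigma_weights / sum(sigma_weights)
  pi0 <- prior@pi0
  # per-partition grid-averaged log10 BF
  lbf_g <- unname(apply(log10_bfs, 1, function(x) .lse10(x, sigma_weights)))
  lbf_av <- .lse10(lbf_g, prior@weights)
  # posterior over {null} + non-null partitions, on log10 scale
  lw <- c(log10(pi0), log10((1 - pi0) * prior@weights) + lbf_g)
  mx <- max(lw[is.finite(lw)])
  pr <- 10^(lw - mx)
  pr <- pr / sum(pr)
  p_null <- pr[1]
  pp <- pr[-1]
  # direct route per the averaged-BF formula, asserted to agree
  p_null_direct <- pi0 / (pi0 + (1 - pi0) * 10^lbf_av)
  if (is.finite(p_null_direct) && abs(p_null - p_null_direct) > 1e-10)
    stop("internal inconsistency between null-probability routes")
  d <- prior@partitions[[1]]@d
  tc <- matrix(0, d, 3, dimnames = list(NULL, c("U", "D", "I")))
  tc[, "U"] <- p_null
  for (i in seq_along(pp)) {
    g <- prior@partitions[[i]]
    tc[g@U, "U"] <- tc[g@U, "U"] + pp[i]
    tc[g@D, "D"] <- tc[g@D, "D"] + pp[i]
    tc[g@I, "I"] <- tc[g@I, "I"] + pp[i]
  }
  new("PosteriorSummary", p_null = p_null,
      partition_names = vapply(prior@partitions, formatPartition,
                               character(1)),
      partition_probs = pp, trait_category_probs = tc,
      p_assoc = 1 - tc[, "U"], log10_bf_av = lbf_av)
}

# Vectorized limiting Bayes factor for one partition across many variants
# sharing the phenotype cross-product matrix yty and sample size n, but with
# variant-specific gtg (length-k vector) and gty (d x k matrix).  Same
# algebra as logBFLimit().
.logbf_limit_vec <- function(n, gtg, gty, yty, gamma, sigma_a,
                             m = nrow(yty)) {
  D <- gamma@D; U <- gamma@U
  p <- length(D)
  if (p == 0L) return(rep(0, length(gtg)))
  GU <- gty[U, , drop = FALSE]
  GD <- gty[D, , drop = FALSE]
  if (length(U)) {
    AUU <- yty[U, U, drop = FALSE]
    W1 <- .chol_solve(AUU, GU, "yty[U,U]")
    gss <- gtg - colSums(GU * W1)
    gy <- GD - crossprod(yty[U, D, drop = FALSE], W1)
    S0 <- yty[D, D, drop = FALSE] -
      crossprod(yty[U, D, drop = FALSE],
                .chol_solve(AUU, yty[U, D, drop = FALSE], "yty[U,U]"))
  } else {
    gss <- gtg
    gy <- GD
    S0 <- yty[D, D, drop = FALSE]
  }
  q <- colSums(gy * .chol_solve(S0, gy, "residual cross-products"))
  t_rel <- pmin(pmax(q / gss, 0), 1 - 1e-14)
  nu <- sigma_a^2 * gss / (1 + sigma_a^2 * gss)
  lbf <- -p / 2 * log1p(sigma_a^2 * gss) -
    (n + m - length(gamma@I)) / 2 * log1p(-nu * t_rel)
  lbf / log(10)
}

#' Permutation p-value for the averaged Bayes factor
#'
#' Permutes the genotype vector against the phenotype rows, recomputes
#' `log10 BF_av` for each permutation, and returns the add-one estimator
#' `p = (1 + #[permuted >= observed]) / (n_perm + 1)`, which cannot be zero.
#' Reproducible given `seed`.
#'
#' @param Y `n x d` phenotype matrix.
#' @param g genotype vector.
#' @param prior a [PartitionPrior-class].
#' @param sigma_grid vector of `sigma_a` values.
#' @param sigma_weights weights over the grid (default uniform).
#' @param n_perm number of permutations (>= 99 recommended; fewer triggers a
#'   warning).
#' @param seed integer seed.
#' @return list with `p_value`, `observed` (log10 BF_av) and `null_draws`
#'   (the permuted log10 BF_av values).
#' @export
permutationPvalue <- function(Y, g, prior, sigma_grid = defaultSigmaGrid(),
                              sigma_weights = NULL, n_perm = 999,
                              seed = 1) {
  if (n_perm < 99) warning("n_perm < 99 gives a coarse p-value")
  Y <- as.matrix(Y)
  if (is.null(sigma_weights))
    sigma_weights <- rep(1 / length(sigma_grid), length(sigma_grid))
  stats <- sufficientFromRaw(Y, g)
  obs <- bfAv(logBFMatrix(stats, prior@partitions, sigma_grid), prior,
              sigma_weights)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  gc <- g - mean(g)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) gc[sample.int(n)], numeric(n))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  gty_all <- crossprod(Yc, P)                 # d x n_perm
  gtg_all <- rep(sum(gc^2), n_perm)           # invariant under permutation
  W <- outer(prior@weights, sigma_weights)
  lbf_cube <- vapply(seq_along(sigma_grid), function(k)
    t(vapply(prior@partitions, function(gam)
      .logbf_limit_vec(n, gtg_all, gty_all, stats@yty, gam, sigma_grid[k]),
      numeric(n_perm))),
    matrix(0, length(prior@partitions), n_perm))
  null_draws <- vapply(seq_len(n_perm), function(i)
    .lse10(as.numeric(lbf_cube[, i, ]), as.numeric(W)), numeric(1))
  list(p_value = (1 + sum(null_draws >= obs)) / (n_perm + 1),
       observed = obs, null_draws = null_draws)
}

#' Default effect-size scale grid
#'
#' Prior standard deviations of the genotype effect (per allele, relative to
#' the residual scale) averaged over in `BF_av`; spans small to large effects.
#' @return numeric vector `c(0.05, 0.1, 0.2, 0.4, 0.8)`.
#' @export
defaultSigmaGrid <- function() c(0.05, 0.1, 0.2, 0.4, 0.8)

#' Stage-1 screen for promising variants
#'
#' A computationally cheap filter applied before the full partition analysis:
#' for each variant the multivariate statistic `z' R^-1 z` is referred to a
#' chi-squared distribution on `d` degrees of freedom and each squared
#' univariate Z-score to chi-squared on 1 df; the variant is promising if the
#' smallest of these `d + 1` p-values is below `p_threshold`.
#'
#' @param Z `m x d` matrix of Z-scores.
#' @param R phenotype correlation matrix or [CorrelationEstimate-class].
#' @param p_threshold promotion threshold (default `1e-4`).
#' @return data.frame with columns `p_multi`, `p_uni_min`, `promising`.
#' @export
stage1Screen <- function(Z, R, p_threshold = 1e-4) {
  Z <- as.matrix(Z)
  R <- .repair_correlation(corMatrix(R))
  d <- ncol(Z)
  quad <- rowSums((Z %*% .chol_solve(R, diag(d), "R")) * Z)
  p_multi <- pchisq(quad, df = d, lower.tail = FALSE)
  p_uni <- pchisq(Z^2, df = 1, lower.tail = FALSE)
  p_uni_min <- apply(p_uni, 1, min)
  data.frame(p_multi = p_multi, p_uni_min = p_uni_min,
             promising = pmin(p_multi, p_uni_min) < p_threshold)
}

#' Greedy distance-based pruning of ranked associations
#'
#' Walks the results in decreasing order of a score (typically
#' `log10_bf_av`) and keeps a variant only if no already-kept variant on the
#' same chromosome lies within `window` base pairs — a proxy for removing
#' redundant associations due to linkage disequilibrium. Ties in the score
#' are broken by (chromosome, position).
#'
#' @param results data.frame with columns `chrom`, `pos` and the score
#'   column.
#' @param window exclusion window in base pairs (default 500000, i.e. 0.5 Mb).
#' @param score name of the score column (default `"log10_bf_av"`).
#' @return the kept rows, ordered by decreasing score.
#' @export
ldPruneByDistance <- function(results, window = 5e5,
                              score = "log10_bf_av") {
  if (!all(c("chrom", "pos", score) %in% names(results)))
    stop("results must have chrom, pos and ", score, " columns")
  if (anyNA(results$pos) || anyNA(results$chrom))
    stop("missing chromosome or position")
  ord <- order(-results[[score]], as.character(results$chrom), results$pos)
  res <- results[ord, , drop = FALSE]
  keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    prev <- which(keep & res$chrom == res$chrom[i] &
                    abs(res$pos - res$pos[i]) <= window)
    keep[i] <- length(prev) == 0L
  }
  res[keep, , drop = FALSE]
}
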