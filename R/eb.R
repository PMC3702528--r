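#' Empirical-Bayes mixture weights over (partition, effect-size scale)
#'
#' @slot weights numeric vector of mixture weights over the components
#'   (columns of the Bayes-factor matrix the fit was run on), summing to 1.
#' @slot loglik_trace natural-log likelihood after each EM iteration of the
#'   best run; non-decreasing within tolerance.
#' @slot n_snps number of variants used in the fit.
#' @slot converged logical.
#' @export
setClass("EBWeights",
  representation(weights = "numeric", loglik_trace = "numeric",
                 n_snps = "integer", converged = "logical"),
  validity = function(object) {
    if (abs(sum(object@weights) - 1) > 1e-8)
      return("weights must sum to 1")
    if (any(object@weights < 0)) return("weights must be non-negative")
    if (length(object@loglik_trace) > 1 &&
        any(diff(object@loglik_trace) < -1e-9))
      return("log-likelihood trace must be non-decreasing")
    TRUE
  }
)

setMethod("show", "EBWeights", function(object) {
  cat("EBWeights over", length(object@weights), "components from",
      object@n_snps, "variants;",
      if (object@converged) "converged" else "NOT converged",
      "after", length(object@loglik_trace), "iterations\n")
  k <- order(object@weights, decreasing = TRUE)
  k <- k[seq_len(min(5, length(k)))]
  nm <- names(object@weights)
  for (i in k)
    cat(sprintf("  %-40s %.4f\n",
                if (is.null(nm)) paste0("component ", i) else nm[i],
                object@weights[i]))
})

# One EM run from a given starting weight vector; lbf in log10, rows = SNPs.
.em_run <- function(lbf, w, tol, max_iter) {
  n <- nrow(lbf)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  ln10 <- log(10)
  for (it in seq_len(max_iter)) {
    lg <- sweep(lbf, 2, log10(pmax(w, 1e-300)), "+")   # log10(w_j BF_ij)
    mx <- apply(lg, 1, max)
    p <- 10^(lg - mx)
    rs <- rowSums(p)
    ll <- sum((mx + log10(rs)) * ln10)
    trace <- c(trace, ll)
    r <- p / rs
    w <- pmax(colMeans(r), 1e-12)
    w <- w / sum(w)
    if (is.finite(ll_old) && (ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(w = w, trace = trace, converged = converged)
}

#' Fit mixture weights over Bayes-factor components by EM
#'
#' Maximizes `L(w) = prod_i sum_j w_j BF_i(j)` over probability vectors `w`,
#' where `BF_i(j)` is the Bayes factor of variant `i` under component `j`
#' (typically a (partition, sigma_a grid point) pair). The E-step computes
#' responsibilities proportional to `w_j BF_i(j)`; the M-step sets `w` to
#' their mean. The best of `n_starts` runs (one from the supplied or uniform
#' initialization, the rest from random Dirichlet draws) is returned.
#' Components never drop out: weights are floored at `1e-12` so the index
#' space stays stable.
#'
#' @param lbf matrix of log10 Bayes factors, variants in rows, components in
#'   columns; all entries must be finite.
#' @param init starting weights, or `"uniform"`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per run.
#' @param n_starts number of independent starts.
#' @param seed integer seed for the random starts.
#' @return An [EBWeights-class].
#' @export
emFit <- function(lbf, init = "uniform", tol = 1e-8, max_iter = 2000,
                  n_starts = 4, seed = 1) {
  lbf <- as.matrix(lbf)
  if (nrow(lbf) < 1) stop("need at least one variant")
  bad <- which(!apply(lbf, 1, function(x) all(is.finite(x))))
  if (length(bad))
    stop("non-finite Bayes factors for variant row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  k <- ncol(lbf)
  w0 <- if (identical(init, "uniform")) rep(1 / k, k) else {
    if (length(init) != k || any(init < 0) || sum(init) <= 0)
      stop("init must be a non-negative length-k vector")
    init / sum(init)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  starts <- c(list(w0), lapply(seq_len(max(0, n_starts - 1)), function(i) {
    x <- stats::rgamma(k, 1)
    x / sum(x)
  }))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  runs <- lapply(starts, .em_run, lbf = lbf, tol = tol, max_iter = max_iter)
  best <- which.max(vapply(runs, function(r) max(r$trace), numeric(1)))
  r <- runs[[best]]
  w <- r$w
  names(w) <- colnames(lbf)
  new("EBWeights", weights = w, loglik_trace = r$trace,
      n_snps = nrow(lbf), converged = r$converged)
}

#' Posterior partition summary under empirical-Bayes weights
#'
#' Plugs fitted joint weights over (partition, sigma_a) into the posterior
#' calculation: `P(gamma, k | data) \propto (1 - pi0) w_hat[gamma, k]
#' BF(gamma, k)`, marginalized over the grid for the partition and trait
#' summaries. When the weights were fitted on variants selected for strong
#' association, they are biased towards associated partitions, so the
#' resulting posteriors borrow that enrichment.
#'
#' @param log10_bfs matrix of log10 Bayes factors for one variant, non-null
#'   partitions in rows, grid points in columns.
#' @param partitions list of [Partition-class] objects aligned with the rows.
#' @param eb an [EBWeights-class] whose components are the (row-major)
#'   (partition, grid) cells of `log10_bfs`, or a matrix of weights with the
#'   same shape as `log10_bfs`.
#' @param pi0 prior probability of the global null.
#' @return A [PosteriorSummary-class].
#' @export
posteriorWithEB <- function(log10_bfs, partitions, eb, pi0 = 0.5) {
  log10_bfs <- as.matrix(log10_bfs)
  W <- if (is(eb, "EBWeights")) eb@weights else as.numeric(eb)
  if (length(W) != length(log10_bfs))
    stop("weight and Bayes-factor index spaces differ")
  W <- matrix(W, nrow = nrow(log10_bfs))
  if (nrow(log10_bfs) != length(partitions))
    stop("partitions must align with the Bayes-factor rows")
  # marginal per-partition weights and grid-averaged BFs
  w_gamma <- rowSums(W)
  lbf_g <- vapply(seq_along(partitions), function(i) {
    wi <- W[i, ]
    if (sum(wi) <= 0) return(-Inf)
    .lse10(log10_bfs[i, ], wi / sum(wi))
  }, numeric(1))
  prior <- customPartitionPrior(partitions, pmax(w_gamma, 1e-300), pi0 = pi0)
  posteriorPartitions(matrix(lbf_g, ncol = 1), prior, sigma_weights = 1)
}
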