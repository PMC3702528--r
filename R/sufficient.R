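#' @importFrom stats cor cov complete.cases
NULL

#' Phenotype correlation estimated from null variants
#'
#' Under the global null the correlation matrix of the per-trait Z-scores
#' equals the correlation matrix of the phenotypes, so it can be estimated
#' from variants showing no evidence of association.
#'
#' @slot R `d x d` correlation matrix (unit diagonal, positive semi-definite).
#' @slot n_null_snps number of variants used.
#' @slot z_threshold the |Z| cutoff that defined "null".
#' @export
setClass("CorrelationEstimate",
  representation(R = "matrix", n_null_snps = "integer",
                 z_threshold = "numeric"),
  validity = function(object) {
    R <- object@R
    if (nrow(R) != ncol(R)) return("R must be square")
    if (max(abs(diag(R) - 1)) > 1e-8) return("R must have unit diagonal")
    if (max(abs(R - t(R))) > 1e-8) return("R must be symmetric")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) return("R must be positive semi-definite")
    TRUE
  }
)

setMethod("show", "CorrelationEstimate", function(object) {
  cat("CorrelationEstimate from", object@n_null_snps,
      "null variants (|Z| <", object@z_threshold, "):\n")
  print(round(object@R, 3))
})

#' @describeIn CorrelationEstimate-class extract the correlation matrix
#' @param x a `CorrelationEstimate` (or a plain matrix, returned as-is).
#' @export
corMatrix <- function(x) {
  if (is(x, "CorrelationEstimate")) x@R else as.matrix(x)
}

# Repair a nearly-valid correlation matrix: clip negative eigenvalues at
# zero, then rescale to unit diagonal.
.repair_correlation <- function(R) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 0) {
    v <- pmax(e$values, 0)
    R <- e$vectors %*% (v * t(e$vectors))
    s <- sqrt(pmax(diag(R), .Machine$double.eps))
    R <- R / outer(s, s)
  }
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Exact sufficient statistics from raw data
#'
#' Mean-centers the genotype vector and each phenotype column and forms the
#' cross-products that the Bayes factor engine consumes. Complete data only;
#' use [handleMissing()] first if phenotypes have missing entries.
#'
#' @param Y `n x d` phenotype matrix (no missing values).
#' @param g length-`n` genotype or dosage vector.
#' @param trait_names trait names (defaults to `colnames(Y)`).
#' @return A [SufficientStats-class].
#' @export
sufficientFromRaw <- function(Y, g, trait_names = colnames(Y)) {
  Y <- as.matrix(Y)
  if (anyNA(Y) || anyNA(g))
    stop("missing values present; use handleMissing()")
  if (length(g) != nrow(Y)) stop("length(g) must equal nrow(Y)")
  gc <- g - mean(g)
  if (sum(gc^2) <= 0)
    stop("degenerate genotype: zero variance after centering")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(ncol(Y)))
  sufficientStats(n = nrow(Y), gtg = sum(gc^2),
                  gty = as.numeric(crossprod(gc, Yc)),
                  yty = crossprod(Yc), trait_names = trait_names)
}

#' Approximate sufficient statistics from effect estimates
#'
#' Under Hardy-Weinberg equilibrium the centered genotype sum of squares is
#' approximately `2 n f (1 - f)` for minor allele frequency `f`; the
#' genotype-phenotype cross-products follow from the univariate OLS identity
#' `betahat_j = g'y_j / g'g`; and with standardized phenotypes the phenotype
#' cross-product matrix is `n` times their correlation matrix.
#'
#' @param betahat length-`d` vector of per-trait univariate effect estimates
#'   (on standardized phenotypes, per copy of the minor allele).
#' @param maf minor allele frequency, in (0, 0.5].
#' @param n sample size.
#' @param R phenotype correlation matrix or [CorrelationEstimate-class].
#' @param trait_names trait names.
#' @return A [SufficientStats-class].
#' @export
sufficientFromEffects <- function(betahat, maf, n, R,
                                  trait_names = NULL) {
  R <- corMatrix(R)
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (length(betahat) != nrow(R)) stop("betahat and R dimensions differ")
  gtg <- 2 * n * maf * (1 - maf)
  if (is.null(trait_names))
    trait_names <- colnames(R) %||% paste0("trait", seq_along(betahat))
  sufficientStats(n = n, gtg = gtg, gty = betahat * gtg, yty = n * R,
                  trait_names = trait_names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Approximate sufficient statistics from Z-scores
#'
#' For standardized phenotypes the univariate Z-score satisfies
#' `z_j ~= g'y_j / sqrt(g'g)`, so `g'y_j = z_j * sqrt(g'g)` with
#' `g'g ~= 2 n f (1 - f)` from Hardy-Weinberg equilibrium, and
#' `Y'Y ~= n R`. Z-scores are signed with respect to the minor allele.
#'
#' @param z length-`d` vector of per-trait Z-scores.
#' @param maf minor allele frequency, in (0, 0.5].
#' @param n sample size (if per-trait sizes differ, the minimum).
#' @param R phenotype correlation matrix or [CorrelationEstimate-class].
#' @param trait_names trait names.
#' @return A [SufficientStats-class].
#' @export
sufficientFromZ <- function(z, maf, n, R, trait_names = NULL) {
  R <- corMatrix(R)
  if (length(z) != nrow(R)) stop("z and R dimensions differ")
  if (!all(is.finite(z))) stop("z must be finite")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  gtg <- 2 * n * maf * (1 - maf)
  if (is.null(trait_names))
    trait_names <- colnames(R) %||% paste0("trait", seq_along(z))
  sufficientStats(n = n, gtg = gtg, gty = z * sqrt(gtg), yty = n * R,
                  trait_names = trait_names)
}

#' Estimate the phenotype correlation matrix from null variants
#'
#' Retains the rows of a Z-score matrix whose entries are all below
#' `z_threshold` in absolute value (putative null variants) and returns their
#' sample correlation matrix, repaired to be a valid correlation matrix if
#' needed.
#'
#' @param Z `m x d` matrix of Z-scores (one row per variant).
#' @param z_threshold |Z| cutoff defining putative null variants (default 2).
#' @return A [CorrelationEstimate-class].
#' @export
estimateNullCorrelation <- function(Z, z_threshold = 2) {
  Z <- as.matrix(Z)
  d <- ncol(Z)
  keep <- rowSums(abs(Z) < z_threshold) == d & complete.cases(Z)
  m <- sum(keep)
  if (m < d + 1)
    stop("only ", m, " putative null variants retained; need at least ",
         d + 1)
  R <- .repair_correlation(cor(Z[keep, , drop = FALSE]))
  dimnames(R) <- list(colnames(Z), colnames(Z))
  new("CorrelationEstimate", R = R, n_null_snps = as.integer(m),
      z_threshold = as.numeric(z_threshold))
}

#' Sufficient statistics from data with missing phenotype values
#'
#' Cross-products are computed from pairwise-complete observations (each
#' entry using all individuals observed for that pair of variables) and
#' rescaled to a common sample size, taken as the smallest per-trait count of
#' jointly observed (genotype, phenotype) pairs. The resulting phenotype
#' cross-product matrix may not be positive semi-definite and is repaired by
#' eigenvalue clipping.
#'
#' @param Y `n x d` phenotype matrix, `NA` for missing.
#' @param g length-`n` genotype vector (may also contain `NA`).
#' @param trait_names trait names.
#' @return list with elements `stats` (a [SufficientStats-class], with `n`
#'   equal to the minimum per-trait sample size) and `per_trait_n` (integer
#'   vector of per-trait complete counts).
#' @export
handleMissing <- function(Y, g, trait_names = colnames(Y)) {
  Y <- as.matrix(Y)
  d <- ncol(Y)
  if (length(g) != nrow(Y)) stop("length(g) must equal nrow(Y)")
  if (any(colSums(!is.na(Y)) == 0)) stop("a trait is entirely missing")
  per_trait_n <- as.integer(colSums(!is.na(Y) & !is.na(g)))
  n_use <- min(per_trait_n)
  if (n_use < 2) stop("a trait has fewer than 2 jointly observed rows")
  for (j in seq_len(d)) for (k in seq_len(j)) {
    if (sum(!is.na(Y[, j]) & !is.na(Y[, k])) < 2)
      stop("trait pair (", k, ",", j, ") has fewer than 2 joint observations")
  }
  M <- cbind(g, Y)
  V <- cov(M, use = "pairwise.complete.obs")
  ss <- V * (n_use - 1)          # rescale pairwise covariances to common n
  gv <- ss[1, 1]
  if (!is.finite(gv) || gv <= 0)
    stop("degenerate genotype: zero variance after centering")
  yty <- ss[-1, -1, drop = FALSE]
  ev <- eigen((yty + t(yty)) / 2, symmetric = TRUE)
  if (min(ev$values) < 0)
    yty <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(d))
  list(stats = sufficientStats(n = n_use, gtg = gv, gty = ss[1, -1],
                               yty = yty, trait_names = trait_names),
       per_trait_n = per_trait_n)
}
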