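#' @importFrom stats pf
NULL

# ---------------------------------------------------------------------------
# Domain types
# ---------------------------------------------------------------------------

#' Hyperparameters of the conjugate Bayesian multivariate regression prior
#'
#' The BMVR model is `Y = X B + E`, rows of `E` iid `N(0, Sigma)`, with the
#' conjugate prior `Sigma ~ IW(lambda * I, m)` and `B | Sigma ~ MN(0, K,
#' Sigma)` where `K` is diagonal: the intercept row of `B` has prior scale
#' `sigma_b` and the genotype row has prior scale `sigma_a` (both relative to
#' the residual scale, since the prior covariance is scaled by `Sigma`).
#'
#' In *limit mode* the analysis uses the limits `sigma_b -> Inf` (equivalent
#' to mean-centering each column) and `lambda -> 0`, which connect the Bayes
#' factors to classical likelihood-ratio statistics.
#'
#' @slot sigma_a prior standard-deviation scale for genotype effects.
#' @slot sigma_b prior scale for intercepts (and for coefficients of
#'   conditioned-on phenotypes); `Inf` in limit mode.
#' @slot lambda inverse-Wishart scale multiplier (`H = lambda * I`); `0` in
#'   limit mode.
#' @slot m inverse-Wishart degrees of freedom of the joint `d`-trait prior.
#' @slot limit logical; use the limiting prior.
#' @export
setClass("BMVRPrior",
  representation(sigma_a = "numeric", sigma_b = "numeric",
                 lambda = "numeric", m = "numeric", limit = "logical"),
  validity = function(object) {
    if (object@sigma_a < 0) return("sigma_a must be non-negative")
    if (object@limit) {
      if (object@sigma_a <= 0) return("limit mode requires sigma_a > 0")
    } else {
      if (!is.finite(object@sigma_b) || object@sigma_b <= 0)
        return("finite mode requires sigma_b > 0")
      if (object@lambda <= 0) return("finite mode requires lambda > 0")
    }
    TRUE
  }
)

#' Construct BMVR prior hyperparameters
#'
#' @param sigma_a prior SD scale of genotype effects.
#' @param sigma_b intercept prior scale (finite mode only).
#' @param lambda inverse-Wishart scale multiplier (finite mode only).
#' @param m inverse-Wishart degrees of freedom of the joint prior; defaults
#'   to the trait count `d` at the point of use (`NA` here), the smallest
#'   integer making the d-dimensional inverse-Wishart proper.
#' @param limit logical; if `TRUE`, use the limiting prior
#'   (`sigma_b -> Inf`, `lambda -> 0`).
#' @return A [BMVRPrior-class].
#' @examples
#' bmvrPrior(0.4)                         # limiting prior
#' bmvrPrior(0.4, sigma_b = 10, lambda = 0.1, m = 4, limit = FALSE)
#' @export
bmvrPrior <- function(sigma_a, sigma_b = Inf, lambda = 0, m = NA_real_,
                      limit = is.infinite(sigma_b)) {
  new("BMVRPrior", sigma_a = as.numeric(sigma_a),
      sigma_b = as.numeric(sigma_b), lambda = as.numeric(lambda),
      m = as.numeric(m), limit = isTRUE(limit))
}

setMethod("show", "BMVRPrior", function(object) {
  if (object@limit)
    cat("BMVRPrior (limiting): sigma_a =", object@sigma_a,
        " m =", object@m, "\n")
  else
    cat("BMVRPrior: sigma_a =", object@sigma_a, " sigma_b =", object@sigma_b,
        " lambda =", object@lambda, " m =", object@m, "\n")
})

#' Per-variant sufficient statistics
#'
#' The Bayes factors depend on the raw data `(Y, g)` only through the
#' centered cross-products `gtg = t(g - mean(g)) %*% (g - mean(g))`,
#' `gty = t(g - mean(g)) %*% Yc` and `yty = t(Yc) %*% Yc` (columns of `Yc`
#' mean-centered), together with the sample size `n`. This makes analyses
#' possible from summary data without raw genotypes or phenotypes.
#'
#' @slot n sample size.
#' @slot gtg centered genotype sum of squares (scalar).
#' @slot gty length-`d` vector of centered genotype-phenotype cross-products.
#' @slot yty `d x d` centered phenotype cross-product matrix.
#' @slot trait_names character vector of trait names.
#' @export
setClass("SufficientStats",
  representation(n = "numeric", gtg = "numeric", gty = "numeric",
                 yty = "matrix", trait_names = "character"),
  validity = function(object) {
    d <- length(object@gty)
    if (!all(dim(object@yty) == c(d, d)))
      return("yty must be d x d with d = length(gty)")
    if (max(abs(object@yty - t(object@yty))) > 1e-8 * (1 + max(abs(object@yty))))
      return("yty must be symmetric")
    if (object@gtg < 0) return("gtg must be non-negative")
    if (length(object@trait_names) != d)
      return("trait_names must have length d")
    ev <- eigen(object@yty, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      return("yty must be positive semi-definite")
    TRUE
  }
)

#' @describeIn SufficientStats-class construct from explicit components
#' @param n,gtg,gty,yty,trait_names see slots.
#' @export
sufficientStats <- function(n, gtg, gty, yty,
                            trait_names = paste0("trait", seq_along(gty))) {
  yty <- as.matrix(yty)
  yty <- (yty + t(yty)) / 2
  dimnames(yty) <- NULL
  new("SufficientStats", n = as.numeric(n), gtg = as.numeric(gtg),
      gty = unname(as.numeric(gty)), yty = yty,
      trait_names = as.character(trait_names))
}

#' @describeIn SufficientStats-class number of traits
#' @param x,object a `SufficientStats`.
#' @export
setGeneric("nTraits", function(x) standardGeneric("nTraits"))
#' @rdname SufficientStats-class
#' @export
setMethod("nTraits", "SufficientStats", function(x) length(x@gty))

setMethod("show", "SufficientStats", function(object) {
  cat("SufficientStats: n =", object@n, ", d =", nTraits(object),
      ", gtg =", signif(object@gtg, 4), "\n  traits:",
      paste(object@trait_names, collapse = ", "), "\n")
})

#' Result of the multivariate likelihood-ratio test for one partition
#'
#' Holds the maximized Gaussian likelihood ratio `Lambda` for regressing the
#' direct traits on (intercept, unassociated traits, genotype) against the
#' same regression without genotype, together with the squared norm of the
#' genotype residuals after OLS on (intercept, unassociated traits), which
#' enters the bridge to the limiting Bayes factor.
#'
#' @slot log_lambda natural log of the likelihood ratio `Lambda >= 1`.
#' @slot g_resid_ss squared norm of the genotype residual vector.
#' @slot n sample size.
#' @slot d_D number of direct (response) traits.
#' @slot n_control number of conditioned-on (unassociated) traits.
#' @export
setClass("LrtResult",
  representation(log_lambda = "numeric", g_resid_ss = "numeric",
                 n = "numeric", d_D = "integer", n_control = "integer"),
  validity = function(object) {
    if (object@log_lambda < -1e-8) return("Lambda must be >= 1")
    if (object@g_resid_ss < 0) return("g_resid_ss must be non-negative")
    TRUE
  }
)

#' @describeIn LrtResult-class the likelihood ratio on the natural scale
#'   (may overflow to `Inf` for very strong signals; prefer `log_lambda`)
#' @param x,object an `LrtResult`.
#' @export
setGeneric("lambdaStat", function(x) standardGeneric("lambdaStat"))
#' @rdname LrtResult-class
#' @export
setMethod("lambdaStat", "LrtResult", function(x) exp(x@log_lambda))

setMethod("show", "LrtResult", function(object) {
  cat("LrtResult: log Lambda =", signif(object@log_lambda, 6),
      ", g_resid_ss =", signif(object@g_resid_ss, 6),
      ", n =", object@n, ", |D| =", object@d_D,
      ", |U| =", object@n_control, "\n")
})

# ---------------------------------------------------------------------------
# Numerical helpers
# ---------------------------------------------------------------------------

#' Log multivariate gamma function
#'
#' `log Gamma_d(a) = d(d-1)/4 * log(pi) + sum_{j=1}^d log Gamma(a + (1-j)/2)`,
#' the normalizer appearing in Wishart and matrix-t densities.
#'
#' @param a argument; must exceed `(d - 1) / 2`.
#' @param d dimension.
#' @return `log Gamma_d(a)`.
#' @export
multivariateGammaLog <- function(a, d) {
  if (any(a <= (d - 1) / 2))
    stop("multivariate gamma requires a > (d - 1) / 2")
  d * (d - 1) / 4 * log(pi) +
    rowSums(outer(a, seq_len(d), function(aa, j) lgamma(aa + (1 - j) / 2)))
}

# Cholesky log-determinant with symmetrization and graded jitter; errors if
# the matrix cannot be repaired within 1e-10 * trace.
.chol_logdet <- function(M, what = "matrix") {
  M <- (M + t(M)) / 2
  jitters <- c(0, 10^(-14:-10)) * max(sum(diag(M)), .Machine$double.eps)
  for (j in jitters) {
    R <- tryCatch(chol(M + diag(j, nrow(M))), error = function(e) NULL)
    if (!is.null(R)) return(2 * sum(log(diag(R))))
  }
  stop(what, " is not positive definite (within jitter tolerance)")
}

# Solve M x = b for symmetric PD M via Cholesky, with the same repair policy.
.chol_solve <- function(M, b, what = "matrix") {
  M <- (M + t(M)) / 2
  jitters <- c(0, 10^(-14:-10)) * max(sum(diag(M)), .Machine$double.eps)
  for (j in jitters) {
    R <- tryCatch(chol(M + diag(j, nrow(M))), error = function(e) NULL)
    if (!is.null(R)) return(backsolve(R, forwardsolve(t(R), b)))
  }
  stop(what, " is not positive definite (within jitter tolerance)")
}

# ---------------------------------------------------------------------------
# Exact conjugate marginal likelihood (matrix-t)
# ---------------------------------------------------------------------------

#' Log marginal likelihood of a Bayesian multivariate regression
#'
#' Computes the exact log marginal likelihood `log p(Y | X)` of the conjugate
#' BMVR: `Y = X B + E`, rows of `E` iid `N(0, Sigma)`,
#' `B | Sigma ~ MN(0, K, Sigma)`, `Sigma ~ IW(H, m)`. Integrating `B` and
#' `Sigma` analytically yields a matrix-t density:
#'
#' \deqn{\log p(Y|X) = -\tfrac{nd}{2}\log\pi
#'   + \log\Gamma_d(\tfrac{n+m}{2}) - \log\Gamma_d(\tfrac{m}{2})
#'   + \tfrac{m}{2}\log|H| - \tfrac{n+m}{2}\log|S|
#'   - \tfrac{d}{2}(\log|K| + \log|K^{-1} + X'X|)}
#'
#' with `S = H + Y'Y - Y'X (K^{-1} + X'X)^{-1} X'Y` (a Bayesian analogue of
#' the residual sum-of-squares matrix). All determinants are computed via
#' Cholesky log-determinants.
#'
#' @param Y `n x d` response matrix.
#' @param X `n x q` covariate matrix (include an intercept column if wanted).
#' @param K length-`q` vector: diagonal of the prior row-covariance of `B`
#'   (prior variances, relative to `Sigma`, of each covariate's coefficients).
#' @param H `d x d` inverse-Wishart scale matrix (or a scalar, meaning
#'   `H = scalar * I`).
#' @param m inverse-Wishart degrees of freedom; must exceed `d - 1`.
#' @return log marginal likelihood (natural log).
#' @export
logMarginalBMVR <- function(Y, X, K, H, m) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y); d <- ncol(Y); q <- ncol(X)
  if (nrow(X) != n) stop("Y and X must have the same number of rows")
  if (length(K) == 1L) K <- rep(K, q)
  if (length(K) != q || any(K <= 0)) stop("K must be q positive variances")
  if (length(H) == 1L) H <- diag(as.numeric(H), d)
  if (m <= d - 1) stop("inverse-Wishart df must exceed d - 1")
  xtx <- crossprod(X)
  xty <- crossprod(X, Y)
  Omega <- xtx + diag(1 / K, q)
  S <- H + crossprod(Y) - crossprod(xty, .chol_solve(Omega, xty, "K^-1 + X'X"))
  -n * d / 2 * log(pi) +
    multivariateGammaLog((n + m) / 2, d) - multivariateGammaLog(m / 2, d) +
    m / 2 * .chol_logdet(H, "H") -
    (n + m) / 2 * .chol_logdet(S, "S") -
    d / 2 * (sum(log(K)) + .chol_logdet(Omega, "K^-1 + X'X"))
}

# Same marginal evaluated from centered sufficient statistics.  The model has
# an explicit intercept column; because all cross-products are mean-centered
# the intercept column is orthogonal to everything else, so X'X and X'Y are
# assembled block-wise from (n, gtg, gty, yty).
#   resp: indices of response traits; covs: indices of conditioned-on traits;
#   include_g: add the genotype column.
.bmvr_logmarg_stats <- function(stats, resp, covs, include_g,
                                sigma_b, sigma_a, lambda, m) {
  n <- stats@n
  dr <- length(resp)
  yty <- stats@yty
  # covariates: intercept, Y_covs, (g)
  q <- 1L + length(covs) + as.integer(include_g)
  xtx <- matrix(0, q, q)
  xtx[1, 1] <- n
  if (length(covs))
    xtx[2:(1 + length(covs)), 2:(1 + length(covs))] <- yty[covs, covs]
  if (include_g) {
    xtx[q, q] <- stats@gtg
    if (length(covs)) {
      xtx[q, 2:(1 + length(covs))] <- stats@gty[covs]
      xtx[2:(1 + length(covs)), q] <- stats@gty[covs]
    }
  }
  xty <- matrix(0, q, dr)
  if (length(covs)) xty[2:(1 + length(covs)), ] <- yty[covs, resp]
  if (include_g) xty[q, ] <- stats@gty[resp]
  K <- c(sigma_b^2, rep(sigma_b^2, length(covs)),
         if (include_g) sigma_a^2)
  H <- diag(lambda, dr)
  Omega <- xtx + diag(1 / K, q)
  S <- H + yty[resp, resp, drop = FALSE] -
    crossprod(xty, .chol_solve(Omega, xty, "K^-1 + X'X"))
  -n * dr / 2 * log(pi) +
    multivariateGammaLog((n + m) / 2, dr) - multivariateGammaLog(m / 2, dr) +
    m / 2 * dr * log(lambda) -
    (n + m) / 2 * .chol_logdet(S, "S") -
    dr / 2 * (sum(log(K)) + .chol_logdet(Omega, "K^-1 + X'X"))
}

# ---------------------------------------------------------------------------
# Partition Bayes factors
# ---------------------------------------------------------------------------

#' Log10 Bayes factor for one partition
#'
#' The Bayes factor of the partition model against the global null reduces to
#' a ratio of two Bayesian multivariate regressions: the direct traits
#' regressed on (intercept, unassociated traits, genotype) versus the same
#' regression without genotype. Indirect traits cancel; their only role is to
#' reduce the effective inverse-Wishart degrees of freedom of the conditional
#' regression from the joint `m` to `m - |I|` (the marginalization of an
#' inverse-Wishart over `|I|` coordinates).
#'
#' With the default `m = d`, in limit mode this gives the closed form
#' \deqn{\log BF = -\tfrac{|D|}{2}\log(1 + \sigma_a^2 \tilde g'\tilde g)
#'   - \tfrac{n + |U| + |D|}{2}\log\left(1 - \nu (1 - \Lambda^{-2/n})\right)}
#' where `\nu = sigma_a^2 g'g~ / (1 + sigma_a^2 g'g~)` and `Lambda` is the
#' likelihood-ratio statistic of [lrtStatistic()]. The finite-prior Bayes
#' factor converges to this value as `sigma_b` grows and `lambda` shrinks.
#'
#' @param stats a [SufficientStats-class].
#' @param gamma a [Partition-class] with `gamma@d == nTraits(stats)`.
#' @param prior a [BMVRPrior-class]; limit mode or finite mode.
#' @return log10 Bayes factor versus the global null (0 for the null
#'   partition).
#' @seealso [logBFLimit()] for the limit-mode fast path, [prop1BF()] for the
#'   likelihood-ratio bridge.
#' @export
logBFPartition <- function(stats, gamma, prior) {
  stopifnot(is(stats, "SufficientStats"), is(gamma, "Partition"),
            is(prior, "BMVRPrior"))
  if (gamma@d != nTraits(stats))
    stop("partition dimension does not match the statistics")
  if (isGlobalNull(gamma)) return(0)
  if (prior@limit)
    return(logBFLimit(stats, gamma, prior@sigma_a,
                      m = if (is.na(prior@m)) nTraits(stats) else prior@m))
  m_joint <- if (is.na(prior@m)) nTraits(stats) else prior@m
  m_cond <- m_joint - length(gamma@I)
  if (m_cond <= length(gamma@D) - 1)
    stop("joint df too small for the conditional regression of this partition")
  num <- .bmvr_logmarg_stats(stats, gamma@D, gamma@U, TRUE,
                             prior@sigma_b, prior@sigma_a, prior@lambda, m_cond)
  den <- .bmvr_logmarg_stats(stats, gamma@D, gamma@U, FALSE,
                             prior@sigma_b, prior@sigma_a, prior@lambda, m_cond)
  (num - den) / log(10)
}

# Residual quantities of g and Y_D after projecting out (intercept, Y_U),
# computed purely from centered sufficient statistics.
.residual_blocks <- function(stats, D, U) {
  gty <- stats@gty; yty <- stats@yty
  if (length(U)) {
    W <- .chol_solve(yty[U, U, drop = FALSE],
                     cbind(gty[U], yty[U, D, drop = FALSE]), "yty[U,U]")
    gss <- stats@gtg - sum(gty[U] * W[, 1])
    gy <- gty[D] - as.numeric(crossprod(yty[U, D, drop = FALSE], W[, 1]))
    S0 <- yty[D, D, drop = FALSE] -
      crossprod(yty[U, D, drop = FALSE], W[, -1, drop = FALSE])
  } else {
    gss <- stats@gtg
    gy <- gty[D]
    S0 <- yty[D, D, drop = FALSE]
  }
  list(gss = gss, gy = gy, S0 = (S0 + t(S0)) / 2)
}

#' Limiting-prior log10 Bayes factor (closed form)
#'
#' Evaluates the limit-mode Bayes factor for a partition directly from
#' sufficient statistics, without forming the two marginal likelihoods. See
#' [logBFPartition()] for the formula. This is an independent code path from
#' the [lrtStatistic()] + [prop1BF()] bridge, and the two agree to numerical
#' precision.
#'
#' @inheritParams logBFPartition
#' @param sigma_a prior SD scale for genotype effects.
#' @param m joint inverse-Wishart degrees of freedom (default: trait count).
#' @return log10 Bayes factor.
#' @export
logBFLimit <- function(stats, gamma, sigma_a, m = nTraits(stats)) {
  stopifnot(is(stats, "SufficientStats"), is(gamma, "Partition"))
  if (gamma@d != nTraits(stats))
    stop("partition dimension does not match the statistics")
  if (isGlobalNull(gamma)) return(0)
  if (sigma_a <= 0) stop("sigma_a must be positive")
  n <- stats@n
  d <- nTraits(stats)
  if (n < d + 2) stop("limit-mode Bayes factors require n >= d + 2")
  if (stats@gtg <= 0)
    stop("degenerate genotype: zero variance after centering")
  D <- gamma@D; U <- gamma@U
  p <- length(D)
  rb <- .residual_blocks(stats, D, U)
  if (rb$gss <= 0)
    stop("degenerate genotype: fully explained by conditioned-on traits")
  t_rel <- sum(rb$gy * .chol_solve(rb$S0, rb$gy, "residual cross-products")) /
    rb$gss
  t_rel <- min(max(t_rel, 0), 1 - 1e-14)
  nu <- sigma_a^2 * rb$gss / (1 + sigma_a^2 * rb$gss)
  m_cond <- m - length(gamma@I)
  if (m_cond <= p - 1)
    stop("joint df too small for the conditional regression of this partition")
  lbf <- -p / 2 * log1p(sigma_a^2 * rb$gss) -
    (n + m_cond) / 2 * log1p(-nu * t_rel)
  lbf / log(10)
}

#' Likelihood-ratio statistic for one partition from raw data
#'
#' Computes the maximized Gaussian likelihood ratio for regressing the direct
#' traits on (intercept, unassociated traits, genotype) against the same
#' regression without genotype, with the error covariance profiled out:
#' `Lambda = (det(RSS0) / det(RSS1))^(n/2)`. Also returns the squared norm of
#' the OLS residuals of genotype on (intercept, unassociated traits), which
#' the limiting Bayes factor needs.
#'
#' @param Y `n x d` phenotype matrix.
#' @param g length-`n` genotype (or dosage) vector.
#' @param gamma a [Partition-class].
#' @return An [LrtResult-class].
#' @export
lrtStatistic <- function(Y, g, gamma) {
  Y <- as.matrix(Y)
  stopifnot(is(gamma, "Partition"), gamma@d == ncol(Y),
            length(g) == nrow(Y))
  if (isGlobalNull(gamma)) stop("the null partition has no test")
  n <- nrow(Y)
  D <- gamma@D; U <- gamma@U
  if (n <= length(U) + 2)
    stop("need n > |U| + 2 observations")
  X0 <- cbind(`(intercept)` = 1, Y[, U, drop = FALSE])
  X1 <- cbind(X0, genotype = g)
  q0 <- qr(X0); q1 <- qr(X1)
  if (q0$rank < ncol(X0) || q1$rank < ncol(X1)) {
    cols <- colnames(X1)[q1$pivot[-seq_len(q1$rank)]]
    stop("collinear design; offending columns: ",
         paste(cols, collapse = ", "))
  }
  YD <- Y[, D, drop = FALSE]
  R0 <- qr.resid(q0, YD)
  R1 <- qr.resid(q1, YD)
  gtil <- qr.resid(q0, g)
  ld0 <- .chol_logdet(crossprod(R0), "null residual SSQ")
  ld1 <- .chol_logdet(crossprod(R1), "full residual SSQ")
  new("LrtResult", log_lambda = max(n / 2 * (ld0 - ld1), 0),
      g_resid_ss = sum(gtil^2), n = n, d_D = length(D),
      n_control = length(U))
}

#' Bridge from the likelihood-ratio statistic to the limiting Bayes factor
#'
#' Reconstructs the limit-mode log10 Bayes factor from the likelihood ratio
#' and the genotype residual sum of squares:
#' \deqn{\log BF = -\tfrac{d_D}{2}\log(1+\sigma_a^2\,\tilde g'\tilde g)
#'  - \tfrac{n + |U| + d_D}{2}\log(1 - \nu(1 - \Lambda^{-2/n}))}
#' with `nu = sigma_a^2 g~'g~ / (1 + sigma_a^2 g~'g~)` (under the default
#' joint inverse-Wishart df `m = d`, for which `m - |I| = |U| + d_D`). It
#' equals
#' [logBFLimit()] on the same data. The Bayes factor is monotone increasing
#' in `Lambda` for fixed `g~'g~`, so with a shared `sigma_a * ||g~||` the
#' Bayesian and likelihood-ratio rankings of variants coincide.
#'
#' @param lrt an [LrtResult-class].
#' @param sigma_a prior SD scale for genotype effects.
#' @param n sample size (defaults to the one recorded in `lrt`).
#' @param d_D number of direct traits (defaults to the one in `lrt`).
#' @return log10 Bayes factor.
#' @export
prop1BF <- function(lrt, sigma_a, n = lrt@n, d_D = lrt@d_D) {
  stopifnot(is(lrt, "LrtResult"), sigma_a > 0)
  gss <- lrt@g_resid_ss
  nu <- sigma_a^2 * gss / (1 + sigma_a^2 * gss)
  wilks <- exp(-2 / n * lrt@log_lambda)      # = det(RSS1)/det(RSS0) in (0,1]
  lbf <- -d_D / 2 * log1p(sigma_a^2 * gss) -
    (n + lrt@n_control + d_D) / 2 * log(1 - nu * (1 - wilks))
  lbf / log(10)
}

#' Wilks-lambda F test p-value for an LrtResult
#'
#' Uses Rao's F transformation of the Wilks statistic
#' `W = Lambda^(-2/n) = det(RSS1)/det(RSS0)`. For a single tested covariate
#' the transformation is exact: `F = (1 - W)/W * (n_e - p + 1)/p` with
#' `n_e = n - |U| - 2` error degrees of freedom, referred to
#' `F(p, n_e - p + 1)`. Matches `anova(manova(...), test = "Wilks")` when
#' `U` is empty.
#'
#' @param lrt an [LrtResult-class].
#' @return the p-value.
#' @export
lrtPvalue <- function(lrt) {
  n <- lrt@n; p <- lrt@d_D
  W <- exp(-2 / n * lrt@log_lambda)
  ne <- n - lrt@n_control - 2
  df2 <- ne - p + 1
  if (df2 <= 0) stop("not enough residual degrees of freedom")
  Fstat <- (1 - W) / W * df2 / p
  pf(Fstat, p, df2, lower.tail = FALSE)
}

#' Bayes factors for many partitions and a grid of effect-size scales
#'
#' Convenience wrapper evaluating [logBFLimit()] for every supplied partition
#' and every `sigma_a` in a grid, as needed by model averaging and the
#' empirical-Bayes weight fit.
#'
#' @param stats a [SufficientStats-class].
#' @param partitions list of [Partition-class] objects.
#' @param sigma_grid numeric vector of `sigma_a` values.
#' @param m joint inverse-Wishart degrees of freedom.
#' @return numeric matrix of log10 Bayes factors, `length(partitions)` rows
#'   by `length(sigma_grid)` columns, with `dimnames` giving partition
#'   strings and grid values.
#' @export
logBFMatrix <- function(stats, partitions, sigma_grid,
                        m = nTraits(stats)) {
  out <- vapply(sigma_grid, function(s)
    vapply(partitions, function(g) logBFLimit(stats, g, s, m = m),
           numeric(1)),
    numeric(length(partitions)))
  out <- matrix(out, nrow = length(partitions),
                dimnames = list(vapply(partitions, formatPartition,
                                       character(1)),
                                as.character(sigma_grid)))
  out
}
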