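#' @importFrom stats rnorm rbinom runif quantile
NULL

#' A simulated association study
#'
#' @slot Y `n x d` phenotype matrix.
#' @slot g genotype vector (0/1/2 minor-allele counts).
#' @slot truth the generating [Partition-class].
#' @slot scenario scenario name.
#' @slot params list of generator parameters.
#' @export
setClass("SimulatedStudy",
  representation(Y = "matrix", g = "numeric", truth = "Partition",
                 scenario = "character", params = "list"),
  validity = function(object) {
    if (nrow(object@Y) != length(object@g))
      return("Y and g must have the same number of rows")
    if (object@truth@d != ncol(object@Y))
      return("truth partition dimension must match Y")
    TRUE
  }
)

setMethod("show", "SimulatedStudy", function(object) {
  cat("SimulatedStudy '", object@scenario, "': n = ", nrow(object@Y),
      ", d = ", ncol(object@Y), ", truth ", formatPartition(object@truth),
      "\n", sep = "")
})

.rmvn <- function(n, Sigma) MASS::mvrnorm(n, rep(0, nrow(Sigma)), Sigma)

#' Simulate a bivariate association scenario
#'
#' Genotypes are `g ~ Binomial(2, maf)`; phenotypes follow
#' `Y_j = b_j g + e_j` with standard-normal errors of correlation `rho`.
#' The scenario fixes `b2`: `"bivariate-U"` sets `b2 = 0` (trait 2
#' unassociated but correlated with trait 1) and `"bivariate-I"` sets
#' `b2 = rho * b1`, which makes trait 2 conditionally independent of genotype
#' given trait 1 (indirectly associated). `"bivariate-D"` gives trait 2 its
#' own effect of opposite sign (`b2 = -b`): with positively correlated
#' residuals, opposite-sign effects are the configuration where both traits
#' are unambiguously directly associated (far from the indirect boundary
#' `b2 = rho * b1`), the classic case where a joint analysis is most
#' advantageous.
#'
#' @param scenario one of `"bivariate-D"`, `"bivariate-U"`, `"bivariate-I"`.
#' @param n number of individuals (default 1000).
#' @param maf minor allele frequency (default 0.2).
#' @param b per-allele effect on trait 1 in residual-SD units (default 0.25,
#'   giving mid-range power at the default `n`).
#' @param rho residual correlation (default 0.4).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param null if `TRUE`, zero all genotype effects but keep the error
#'   covariance of the alternative (matched null datasets).
#' @return A [SimulatedStudy-class]; the truth partition reflects the
#'   scenario (or the global null when `null = TRUE`).
#' @export
simulateBivariate <- function(scenario = c("bivariate-D", "bivariate-U",
                                           "bivariate-I"),
                              n = 1000, maf = 0.2, b = 0.25, rho = 0.4,
                              seed = NULL, null = FALSE) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  b2 <- switch(scenario, "bivariate-D" = -b, "bivariate-U" = 0,
               "bivariate-I" = rho * b)
  beta <- c(b, b2)
  if (null) beta <- c(0, 0)
  g <- rbinom(n, 2, maf)
  E <- .rmvn(n, matrix(c(1, rho, rho, 1), 2))
  Y <- outer(g, beta) + E
  colnames(Y) <- c("trait1", "trait2")
  truth <- if (null) Partition(2) else switch(scenario,
    "bivariate-D" = Partition(2, D = 1:2),
    "bivariate-U" = Partition(2, D = 1),
    "bivariate-I" = Partition(2, D = 1, I = 2))
  new("SimulatedStudy", Y = Y, g = as.numeric(g), truth = truth,
      scenario = scenario,
      params = list(n = n, maf = maf, b = b, rho = rho, null = null))
}

.five_d_names <- c("independence", "one-direct-rest-unassoc",
                   "one-direct-rest-indirect", "multivariate-1",
                   "multivariate-2", "latent-factor")

#' Simulate a five-dimensional association scenario
#'
#' Six designs spanning the qualitatively different ways five related traits
#' can relate to one variant:
#' \describe{
#'   \item{independence}{independent traits, trait 1 directly associated.}
#'   \item{one-direct-rest-unassoc}{traits 2-5 independent of genotype;
#'     trait 1 is directly associated and correlated with all of them.}
#'   \item{one-direct-rest-indirect}{trait 1 directly associated; traits 2-5
#'     are noisy copies of trait 1 (noise SD ratios 0.5, 1, 2, 4), hence
#'     indirectly associated.}
#'   \item{multivariate-1}{traits 1-2 direct, trait 3 indirect (average of
#'     1-2 plus noise), traits 4-5 unassociated; errors equicorrelated 0.3.}
#'   \item{multivariate-2}{traits 1-2 direct, traits 3-5 unassociated;
#'     errors equicorrelated 0.3.}
#'   \item{latent-factor}{a latent factor carries the genotype effect and
#'     every trait is the factor plus noise, so all five are direct.}
#' }
#'
#' @param scenario one of the six names above.
#' @param n,maf,b,seed,null as in [simulateBivariate()].
#' @return A [SimulatedStudy-class].
#' @export
simulate5d <- function(scenario = .five_d_names, n = 1000, maf = 0.2,
                       b = 0.25, seed = NULL, null = FALSE) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  g <- rbinom(n, 2, maf)
  be <- if (null) 0 else b
  noise_sd <- c(0.5, 1, 2, 4)
  if (scenario == "independence") {
    Y <- matrix(rnorm(n * 5), n, 5)
    Y[, 1] <- Y[, 1] + be * g
    truth <- Partition(5, D = 1)
  } else if (scenario == "one-direct-rest-unassoc") {
    Z <- matrix(rnorm(n * 4), n, 4)
    y1 <- be * g + 0.35 * rowSums(Z) + rnorm(n)
    Y <- cbind(y1, Z)
    truth <- Partition(5, D = 1)
  } else if (scenario == "one-direct-rest-indirect") {
    y1 <- be * g + rnorm(n)
    Y <- cbind(y1, vapply(noise_sd, function(s) y1 + s * rnorm(n),
                          numeric(n)))
    truth <- Partition(5, D = 1, I = 2:5)
  } else if (scenario == "multivariate-1") {
    S <- matrix(0.3, 4, 4); diag(S) <- 1
    E <- .rmvn(n, S)
    y1 <- be * g + E[, 1]
    y2 <- be * g + E[, 2]
    y3 <- (y1 + y2) / 2 + rnorm(n)
    Y <- cbind(y1, y2, y3, E[, 3], E[, 4])
    truth <- Partition(5, D = 1:2, I = 3)
  } else if (scenario == "multivariate-2") {
    S <- matrix(0.3, 5, 5); diag(S) <- 1
    E <- .rmvn(n, S)
    Y <- E
    Y[, 1] <- Y[, 1] + be * g
    Y[, 2] <- Y[, 2] + be * g
    truth <- Partition(5, D = 1:2)
  } else {                                   # latent-factor
    f <- be * g + rnorm(n)
    Y <- vapply(c(0.5, 1, 1, 2, 4), function(s) f + s * rnorm(n),
                numeric(n))
    truth <- Partition(5, D = 1:5)
  }
  if (null) truth <- Partition(5)
  colnames(Y) <- paste0("trait", 1:5)
  new("SimulatedStudy", Y = Y, g = as.numeric(g), truth = truth,
      scenario = scenario,
      params = list(n = n, maf = maf, b = b, null = null))
}

#' Matched null replicates for a scenario
#'
#' Re-simulates a scenario with every genotype effect set to zero while the
#' error covariance structure is kept identical to the alternative, as needed
#' for size (type-I error) estimation.
#'
#' @param scenario a bivariate or five-dimensional scenario name.
#' @param n_reps number of replicate datasets.
#' @param seed integer seed; replicate `i` uses `seed + i`.
#' @param ... passed to the scenario generator.
#' @return list of [SimulatedStudy-class] objects, all with null truth.
#' @export
simulateNullMatched <- function(scenario, n_reps, seed = 1, ...) {
  gen <- if (scenario %in% .five_d_names) simulate5d else simulateBivariate
  lapply(seq_len(n_reps), function(i)
    gen(scenario, seed = seed + i, null = TRUE, ...))
}

#' Power against size curves from simulated statistics
#'
#' For each statistic, every pooled observed value is used as a rejection
#' threshold; size is the exceedance fraction among null replicates and power
#' the exceedance fraction among alternative replicates. Curves are monotone
#' non-decreasing and invariant to strictly monotone transformations of the
#' statistic.
#'
#' @param alt_stats matrix (replicates x statistics) under the alternative.
#' @param null_stats matrix (replicates x statistics) under the null; column
#'   names must match `alt_stats`.
#' @return named list of data.frames with columns `size` and `power`.
#' @export
powerSizeCurves <- function(alt_stats, null_stats) {
  alt_stats <- as.matrix(alt_stats); null_stats <- as.matrix(null_stats)
  if (!identical(colnames(alt_stats), colnames(null_stats)))
    stop("alternative and null statistic sets differ")
  out <- lapply(seq_len(ncol(alt_stats)), function(j) {
    thr <- sort(unique(c(alt_stats[, j], null_stats[, j])),
                decreasing = TRUE)
    data.frame(
      size = vapply(thr, function(t) mean(null_stats[, j] >= t), numeric(1)),
      power = vapply(thr, function(t) mean(alt_stats[, j] >= t), numeric(1)))
  })
  names(out) <- colnames(alt_stats)
  out
}

#' Power at a fixed size
#'
#' @param alt,null numeric vectors of a statistic under alternative and null.
#' @param size target type-I error rate (default 0.05).
#' @return estimated power: fraction of alternative values exceeding the
#'   `(1 - size)` quantile of the null values.
#' @export
powerAtSize <- function(alt, null, size = 0.05) {
  thr <- quantile(null, probs = 1 - size, names = FALSE, type = 1)
  mean(alt > thr)
}

#' Simulate a table of GWAS summary statistics
#'
#' Emulates the structure of a meta-analysis summary table: per-variant
#' identifier, chromosome, position, minor allele frequency, sample size and
#' `d` Z-scores. Null variants draw `z ~ N(0, R)`; associated variants draw
#' a partition from `partition_mix` and receive mean shifts consistent with
#' it: direct traits get `effect_scale` (with random sign, shared across the
#' direct set), unassociated traits get zero, and indirect traits get the
#' shift implied by regression on the direct traits
#' (`R[I,D] R[D,D]^{-1} mu_D`).
#'
#' @param n_snps number of variants.
#' @param d number of traits.
#' @param frac_assoc fraction of associated variants, in `[0, 1]`.
#' @param partition_mix list with elements `partitions` (list of
#'   [Partition-class]) and `probs`; default: all-direct with probability 1.
#' @param effect_scale mean Z-shift for direct traits (default 6).
#' @param R phenotype correlation matrix or [CorrelationEstimate-class].
#' @param n per-variant sample size (default 10000).
#' @param seed integer seed.
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `maf`, `n`,
#'   `z_<trait>` columns, and a `truth` column of partition strings.
#' @export
simulateSummaryRecords <- function(n_snps, d, frac_assoc = 0,
                                   partition_mix = NULL, effect_scale = 6,
                                   R = diag(d), n = 10000, seed = 1) {
  if (frac_assoc < 0 || frac_assoc > 1) stop("frac_assoc must lie in [0, 1]")
  R <- corMatrix(R)
  if (nrow(R) != d) stop("R must be d x d")
  if (is.null(partition_mix))
    partition_mix <- list(partitions = list(Partition(d, D = seq_len(d))),
                          probs = 1)
  set.seed(seed)
  Z <- .rmvn(n_snps, R)
  truth <- rep("NULL", n_snps)
  n_assoc <- round(frac_assoc * n_snps)
  if (n_assoc > 0) {
    idx <- sample.int(n_snps, n_assoc)
    pk <- sample.int(length(partition_mix$partitions), n_assoc,
                     replace = TRUE, prob = partition_mix$probs)
    for (i in seq_len(n_assoc)) {
      gam <- partition_mix$partitions[[pk[i]]]
      mu <- numeric(d)
      mu[gam@D] <- effect_scale * sample(c(-1, 1), 1)
      if (length(gam@I))
        mu[gam@I] <- as.numeric(R[gam@I, gam@D, drop = FALSE] %*%
          .chol_solve(R[gam@D, gam@D, drop = FALSE], mu[gam@D], "R[D,D]"))
      Z[idx[i], ] <- Z[idx[i], ] + mu
      truth[idx[i]] <- formatPartition(gam)
    }
  }
  chrom <- sort(sample(1:22, n_snps, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_snps), chrom), function(ix)
    sort(sample.int(2.4e8, length(ix)))), use.names = FALSE)
  out <- data.frame(snp_id = sprintf("snp%06d", seq_len(n_snps)),
                    chrom = as.character(chrom), pos = pos,
                    maf = runif(n_snps, 0.05, 0.5), n = n)
  zn <- colnames(R) %||% paste0("trait", seq_len(d))
  colnames(Z) <- paste0("z_", zn)
  cbind(out, as.data.frame(Z), truth = truth)
}
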