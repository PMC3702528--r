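# Independent oracles and small data generators used across the suite.

# Brute-force partition enumeration: all 3^d category assignments, filtered
# by the structural constraint. Returns a sorted vector of partition strings.
bruteForcePartitions <- function(d) {
  grid <- do.call(expand.grid, rep(list(c("U", "D", "I")), d))
  keys <- apply(grid, 1, function(cats) {
    D <- which(cats == "D"); I <- which(cats == "I")
    if (length(D) == 0 && length(I) > 0) return(NA_character_)
    formatPartition(Partition(d, D = D, I = I))
  })
  sort(keys[!is.na(keys)])
}

# Monte-Carlo oracle for the conjugate BMVR marginal likelihood: average the
# Gaussian likelihood over draws from the prior. Returns the log marginal
# estimate and a delta-method standard error on the log scale.
mcMarginalOracle <- function(Y, X, K, H, m, ndraw = 2e5, seed = 99) {
  set.seed(seed)
  n <- nrow(Y); d <- ncol(Y); q <- ncol(X)
  if (length(H) == 1L) H <- diag(H, d)
  Vinv <- solve(H)
  ll <- numeric(ndraw)
  for (s in seq_len(ndraw)) {
    Om <- stats::rWishart(1, m, Vinv)[, , 1]
    Sig <- solve(Om)
    B <- diag(sqrt(K), q) %*% matrix(stats::rnorm(q * d), q, d) %*% chol(Sig)
    R <- Y - X %*% B
    ll[s] <- -n * d / 2 * log(2 * pi) -
      n / 2 * as.numeric(determinant(Sig)$modulus) -
      0.5 * sum((R %*% Om) * R)
  }
  mx <- max(ll)
  w <- exp(ll - mx)
  list(est = mx + log(mean(w)), se = stats::sd(w) / sqrt(ndraw) / mean(w))
}

# Grid-quadrature oracle for the univariate (d = 1) marginal likelihood:
# numerically integrates Normal(y; b0 + b1 g, s2) against the
# normal-inverse-gamma prior over a dense (b0, b1, log s2) grid.
quadratureMarginalOracle <- function(y, g, K, H, m,
                                     b0_lim = 12, b1_lim = 6,
                                     n_b = 201, n_s = 241) {
  n <- length(y)
  b0g <- seq(-b0_lim, b0_lim, length.out = n_b)
  b1g <- seq(-b1_lim, b1_lim, length.out = n_b)
  s2g <- exp(seq(log(1e-3), log(400), length.out = n_s))
  db0 <- diff(b0g[1:2]); db1 <- diff(b1g[1:2])
  dls2 <- diff(log(s2g[1:2]))
  chunks <- numeric(0)
  for (s2 in s2g) {
    lp_s2 <- m / 2 * log(H / 2) - lgamma(m / 2) -
      (m / 2 + 1) * log(s2) - H / (2 * s2) + log(s2) + log(dls2)
    rss <- matrix(0, length(b0g), length(b1g))
    for (i in seq_along(b0g)) {
      E <- outer(b1g, g) + b0g[i] - matrix(y, length(b1g), n, byrow = TRUE)
      rss[i, ] <- rowSums(E^2)
    }
    ll <- -n / 2 * log(2 * pi * s2) - rss / (2 * s2) +
      matrix(-0.5 * log(2 * pi * K[1] * s2) - b0g^2 / (2 * K[1] * s2),
             length(b0g), length(b1g)) +
      matrix(-0.5 * log(2 * pi * K[2] * s2) - b1g^2 / (2 * K[2] * s2),
             length(b0g), length(b1g), byrow = TRUE) +
      lp_s2 + log(db0) + log(db1)
    mx <- max(ll)
    chunks <- c(chunks, mx + log(sum(exp(ll - mx))))
  }
  mx <- max(chunks)
  mx + log(sum(exp(chunks - mx)))
}

# Wilks lambda via explicit OLS residual determinants, used as the
# independent path for reverse-regression checks: likelihood ratio of
# regressing resp on (X0, X_extra) versus X0 alone.
wilksOracle <- function(resp, X0, X_extra) {
  resp <- as.matrix(resp)
  n <- nrow(resp)
  q0 <- qr(X0); q1 <- qr(cbind(X0, X_extra))
  R0 <- qr.resid(q0, resp); R1 <- qr.resid(q1, resp)
  n / 2 * (as.numeric(determinant(crossprod(R0))$modulus) -
             as.numeric(determinant(crossprod(R1))$modulus))
}

# Small random association dataset: g ~ Binom(2, maf), Y = g b' + E with
# unit-variance errors of equicorrelation rho.
makeToyData <- function(n, beta, rho = 0.3, maf = 0.3) {
  d <- length(beta)
  g <- stats::rbinom(n, 2, maf)
  S <- matrix(rho, d, d); diag(S) <- 1
  Y <- outer(g, beta) + MASS::mvrnorm(n, rep(0, d), S)
  list(Y = Y, g = g)
}

# Univariate Z-scores, effect estimates and empirical MAF from raw data,
# as a meta-analysis would report them (per-trait OLS on genotype).
summaryFromRaw <- function(Y, g) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  gc <- g - mean(g)
  gtg <- sum(gc^2)
  beta <- as.numeric(crossprod(gc, scale(Y, scale = FALSE))) / gtg
  rss <- colSums(scale(Y, scale = FALSE)^2) - beta^2 * gtg
  se <- sqrt(rss / (n - 2) / gtg)
  list(z = beta / se, betahat = beta, maf = min(mean(g) / 2, 1 - mean(g) / 2),
       n = n)
}
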