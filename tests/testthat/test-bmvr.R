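test_that("multivariate gamma reduces to, and builds on, the scalar gamma", {
  a <- c(0.7, 1.3, 4.5)
  expect_equal(multivariateGammaLog(a, 1), lgamma(a))
  expect_equal(multivariateGammaLog(2, 2),
               0.5 * log(pi) + lgamma(2) + lgamma(1.5))
  expect_equal(multivariateGammaLog(2, 2), 0.45158, tolerance = 1e-4)
  grid <- seq(3.1, 9, by = 0.1)   # past the lgamma dip in every term
  expect_true(all(diff(multivariateGammaLog(grid, 4)) > 0))
  expect_error(multivariateGammaLog(0.5, 3), "a >")
})

test_that("exact marginal likelihood matches a quadrature oracle (d = 1)", {
  set.seed(3)
  n <- 5
  g <- rbinom(n, 2, 0.4)
  y <- rnorm(n) + 0.4 * g
  K <- c(2^2, 0.6^2); H <- 0.5; m <- 1.5
  exact <- logMarginalBMVR(matrix(y), cbind(1, g), K, H, m)
  oracle <- quadratureMarginalOracle(y, g, K, H, m)
  expect_equal(exact, oracle, tolerance = 1e-3)
})

test_that("marginal likelihood is exchangeable in the rows", {
  set.seed(5)
  n <- 9
  g <- rbinom(n, 2, 0.3)
  Y <- matrix(rnorm(2 * n), n, 2)
  a <- logMarginalBMVR(Y, cbind(1, g), c(4, 0.25), diag(0.5, 2), 3)
  i <- sample(n)
  b <- logMarginalBMVR(Y[i, ], cbind(1, g[i]), c(4, 0.25), diag(0.5, 2), 3)
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(logMarginalBMVR(Y, cbind(1, g), c(4, 0.25), diag(0.5, 2), 1),
               "df must exceed")
})

test_that("finite partition BF equals the explicit two-regression ratio", {
  set.seed(8)
  dat <- makeToyData(20, c(0.5, 0, 0.2), rho = 0.4)
  st <- sufficientFromRaw(dat$Y, dat$g)
  gc <- dat$g - mean(dat$g)
  Yc <- scale(dat$Y, scale = FALSE)
  pr <- bmvrPrior(0.4, sigma_b = 3, lambda = 0.2, m = 3, limit = FALSE)
  for (gam in list(Partition(3, D = 1), Partition(3, D = c(1, 3)),
                   Partition(3, D = 2, I = 3))) {
    m_cond <- 3 - length(gam@I)
    num <- logMarginalBMVR(Yc[, gam@D, drop = FALSE],
                           cbind(1, Yc[, gam@U, drop = FALSE], gc),
                           c(rep(9, 1 + length(gam@U)), 0.16),
                           diag(0.2, length(gam@D)), m_cond)
    den <- logMarginalBMVR(Yc[, gam@D, drop = FALSE],
                           cbind(1, Yc[, gam@U, drop = FALSE]),
                           rep(9, 1 + length(gam@U)),
                           diag(0.2, length(gam@D)), m_cond)
    expect_equal(logBFPartition(st, gam, pr), (num - den) / log(10),
                 tolerance = 1e-10)
  }
  expect_equal(logBFPartition(st, Partition(3), pr), 0)
})

test_that("finite-prior BF converges to the limiting BF", {
  set.seed(7)
  dat <- makeToyData(30, c(0.4, 0.2))
  st <- sufficientFromRaw(dat$Y, dat$g)
  for (gam in list(Partition(2, D = 1, I = 2), Partition(2, D = 1:2),
                   Partition(2, D = 2))) {
    lim <- logBFLimit(st, gam, 0.4)
    diffs <- vapply(c(2, 4, 6), function(k)
      abs(logBFPartition(st, gam,
                         bmvrPrior(0.4, sigma_b = 10^k, lambda = 10^-k,
                                   m = 2, limit = FALSE)) - lim),
      numeric(1))
    expect_true(all(diff(diffs) < 0))        # approach is monotone
    expect_lt(diffs[3], 1e-5)
    expect_equal(logBFPartition(st, gam, bmvrPrior(0.4)), lim)
  }
})

test_that("null partition gives BF exactly 1 and degenerate genotype errors", {
  set.seed(9)
  dat <- makeToyData(25, c(0.3, 0.1))
  st <- sufficientFromRaw(dat$Y, dat$g)
  expect_identical(logBFLimit(st, Partition(2), 0.4), 0)
  expect_error(sufficientFromRaw(dat$Y, rep(1, 25)), "degenerate")
  st0 <- sufficientStats(25, 0, c(0, 0), st@yty)
  expect_error(logBFLimit(st0, Partition(2, D = 1), 0.4), "degenerate")
})

test_that("likelihood ratio reduces to scalar OLS for d = 1", {
  set.seed(10)
  n <- 40
  g <- rbinom(n, 2, 0.25)
  y <- 0.5 * g + rnorm(n)
  lrt <- lrtStatistic(matrix(y), g, Partition(1, D = 1))
  rss0 <- sum(resid(lm(y ~ 1))^2)
  rss1 <- sum(resid(lm(y ~ g))^2)
  expect_equal(exp(2 / n * lrt@log_lambda), rss0 / rss1, tolerance = 1e-10)
  expect_gte(lrt@log_lambda, 0)
})

test_that("Lambda is 1 when the genotype coefficient is exactly zero", {
  set.seed(11)
  n <- 30
  g <- rbinom(n, 2, 0.3)
  Yu <- rnorm(n)
  gtil <- qr.resid(qr(cbind(1, Yu)), g)
  w <- rnorm(n)
  yd <- w - gtil * sum(gtil * w) / sum(gtil^2)
  lrt <- lrtStatistic(cbind(yd, Yu), g, Partition(2, D = 1))
  expect_equal(lrt@log_lambda, 0, tolerance = 1e-9)
  expect_lte(prop1BF(lrt, 0.5), 0)     # no likelihood gain: BF at most 1
  expect_lte(prop1BF(lrt, 5), 0)
})

test_that("forward and reverse regressions give the same Lambda", {
  set.seed(12)
  for (rep in 1:20) {
    dat <- makeToyData(35, c(0.4, 0.2, 0), rho = 0.3)
    gam <- Partition(3, D = c(1, 2), I = integer(0))
    lrt <- lrtStatistic(dat$Y, dat$g, gam)
    X0 <- cbind(1, dat$Y[, gam@U, drop = FALSE])
    rev <- wilksOracle(dat$g, X0, dat$Y[, gam@D])
    expect_equal(lrt@log_lambda, rev, tolerance = 1e-8)
  }
})

test_that("collinear designs raise a named error", {
  set.seed(13)
  n <- 20
  g <- rbinom(n, 2, 0.3)
  Y <- cbind(rnorm(n), g)       # trait 2 duplicates the genotype
  expect_error(lrtStatistic(Y, g, Partition(2, D = 1)), "collinear")
})

test_that("the two limiting-BF code paths agree on random instances", {
  set.seed(14)
  parts <- enumeratePartitions(3)
  parts <- parts[!vapply(parts, isGlobalNull, logical(1))]
  for (rep in 1:25) {
    dat <- makeToyData(50, runif(3, -0.4, 0.4), rho = runif(1, 0, 0.6))
    st <- sufficientFromRaw(dat$Y, dat$g)
    gam <- parts[[sample(length(parts), 1)]]
    s <- runif(1, 0.05, 1)
    expect_equal(logBFLimit(st, gam, s),
                 prop1BF(lrtStatistic(dat$Y, dat$g, gam), s),
                 tolerance = 1e-10)
  }
})

test_that("BF increases with Lambda at fixed genotype residual norm", {
  lrt0 <- new("LrtResult", log_lambda = 0.5, g_resid_ss = 40, n = 100,
              d_D = 2L, n_control = 1L)
  lams <- seq(0.5, 6, by = 0.5)
  bfs <- vapply(lams, function(l) {
    prop1BF(new("LrtResult", log_lambda = l, g_resid_ss = 40, n = 100,
                d_D = 2L, n_control = 1L), 0.3)
  }, numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("Wilks p-values match the standard MANOVA implementation", {
  set.seed(15)
  dat <- makeToyData(60, c(0.3, 0.2, 0), rho = 0.4)
  lrt <- lrtStatistic(dat$Y, dat$g, Partition(3, D = 1:3))
  fit <- stats::manova(dat$Y ~ dat$g)
  sm <- summary(fit, test = "Wilks")$stats
  expect_equal(lrtPvalue(lrt), sm[1, "Pr(>F)"], tolerance = 1e-10)
  expect_equal(exp(-2 / 60 * lrt@log_lambda), sm[1, "Wilks"],
               tolerance = 1e-10)
})

test_that("BF_all is invariant to invertible affine phenotype transforms", {
  set.seed(16)
  dat <- makeToyData(80, c(0.4, -0.2, 0.1), rho = 0.3)
  gam <- Partition(3, D = 1:3)
  base <- logBFLimit(sufficientFromRaw(dat$Y, dat$g), gam, 0.4)
  for (rep in 1:5) {
    A <- matrix(rnorm(9), 3, 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
    shift <- rnorm(3)
    Y2 <- dat$Y %*% t(A) + matrix(shift, 80, 3, byrow = TRUE)
    tr <- logBFLimit(sufficientFromRaw(Y2, dat$g), gam, 0.4)
    expect_equal(tr, base, tolerance = 1e-6)
  }
})

test_that("BF matrix layout is partitions by grid with stable names", {
  set.seed(17)
  dat <- makeToyData(30, c(0.3, 0))
  st <- sufficientFromRaw(dat$Y, dat$g)
  pr <- partitionPrior(2)
  bf <- logBFMatrix(st, pr@partitions, c(0.1, 0.4))
  expect_equal(dim(bf), c(5L, 2L))
  expect_equal(rownames(bf),
               vapply(pr@partitions, formatPartition, character(1)))
  expect_equal(bf["D:1,2", "0.4"],
               logBFLimit(st, Partition(2, D = 1:2), 0.4))
})
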