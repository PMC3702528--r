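test_that("raw sufficient statistics match hand-computed cross-products", {
  Y <- matrix(c(1, 2, 3, 6,
                0, 1, 1, 2), 4, 2)
  g <- c(0, 1, 1, 2)
  st <- sufficientFromRaw(Y, g)
  gc <- g - 1
  Yc <- sweep(Y, 2, c(3, 1))
  expect_equal(st@n, 4)
  expect_equal(st@gtg, sum(gc^2))            # = 2
  expect_equal(st@gty, as.numeric(t(gc) %*% Yc))
  expect_equal(st@yty, t(Yc) %*% Yc, ignore_attr = TRUE)
})

test_that("duplicating every row doubles the statistics", {
  set.seed(21)
  dat <- makeToyData(15, c(0.3, 0.1))
  st1 <- sufficientFromRaw(dat$Y, dat$g)
  st2 <- sufficientFromRaw(rbind(dat$Y, dat$Y), c(dat$g, dat$g))
  expect_equal(st2@n, 2 * st1@n)
  expect_equal(st2@gtg, 2 * st1@gtg)
  expect_equal(st2@gty, 2 * st1@gty)
  expect_equal(st2@yty, 2 * st1@yty)
})

test_that("effect-based approximation applies Hardy-Weinberg variance", {
  R <- diag(2)
  st <- sufficientFromEffects(c(0, 0), maf = 0.5, n = 100, R = R)
  expect_equal(st@gtg, 50)                   # 2 * 100 * 0.25
  expect_equal(st@gty, c(0, 0))
  expect_equal(st@yty, 100 * R, ignore_attr = TRUE)
  expect_error(sufficientFromEffects(c(0, 0), maf = 0.7, n = 100, R = R),
               "maf")
  expect_error(sufficientFromEffects(c(0, 0), maf = 0, n = 100, R = R),
               "maf")
})

test_that("Z-based approximation scales with n and zeroes correctly", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  st0 <- sufficientFromZ(c(0, 0), maf = 0.2, n = 1000, R = R)
  expect_equal(st0@gty, c(0, 0))
  # zero Z-scores carry no evidence: every non-null limiting BF is at most 1
  for (gam in enumeratePartitions(2)[-1])
    expect_lte(logBFLimit(st0, gam, 0.4), 0)
  st1 <- sufficientFromZ(c(1, 2), maf = 0.2, n = 500, R = R)
  st2 <- sufficientFromZ(c(1, 2), maf = 0.2, n = 1000, R = R)
  expect_equal(st2@gtg / st1@gtg, 2)
  expect_error(sufficientFromZ(c(1, 2, 3), maf = 0.2, n = 10, R = R),
               "dimensions differ")
  expect_error(sufficientFromZ(c(1, Inf), maf = 0.2, n = 10, R = R),
               "finite")
})

test_that("null-variant correlation estimate is consistent and valid", {
  set.seed(22)
  R_true <- matrix(c(1, 0.6, 0.3,
                     0.6, 1, 0.5,
                     0.3, 0.5, 1), 3)
  Z <- MASS::mvrnorm(5000, rep(0, 3), R_true)
  # a generous threshold keeps nearly all rows: estimate is consistent
  est4 <- estimateNullCorrelation(Z, z_threshold = 4)
  expect_lt(max(abs(est4@R - R_true)), 0.05)
  # the default threshold truncates the tails, attenuating large
  # correlations; the estimate matches an independent truncated-normal
  # Monte-Carlo reference
  est <- estimateNullCorrelation(Z, z_threshold = 2)
  Zbig <- MASS::mvrnorm(2e5, rep(0, 3), R_true)
  ref <- cor(Zbig[rowSums(abs(Zbig) < 2) == 3, ])
  expect_lt(max(abs(est@R - ref)), 0.05)
  expect_equal(diag(est@R), rep(1, 3))
  expect_true(est@n_null_snps > 2000)
  # identical columns give a matrix of ones
  Zsame <- matrix(rnorm(200), 200, 3)[, c(1, 1, 1)] * 0.5
  expect_equal(estimateNullCorrelation(Zsame)@R, matrix(1, 3, 3),
               ignore_attr = TRUE)
  expect_error(estimateNullCorrelation(matrix(5, 10, 3)), "retained")
})

test_that("complete data passes through handleMissing unchanged", {
  set.seed(23)
  dat <- makeToyData(50, c(0.4, 0.1, 0))
  hm <- handleMissing(dat$Y, dat$g)
  st <- sufficientFromRaw(dat$Y, dat$g)
  expect_equal(hm$per_trait_n, rep(50L, 3))
  expect_equal(hm$stats@gtg, st@gtg)
  expect_equal(hm$stats@gty, st@gty)
  expect_equal(hm$stats@yty, st@yty, tolerance = 1e-12)
  # identical Bayes factors from either object
  for (gam in enumeratePartitions(3)[-1])
    expect_equal(logBFLimit(hm$stats, gam, 0.3),
                 logBFLimit(st, gam, 0.3), tolerance = 1e-10)
})

test_that("missing data uses pairwise statistics and the minimum n", {
  set.seed(24)
  dat <- makeToyData(1000, c(0.3, 0.2, 0), rho = 0.4)
  Y <- dat$Y
  Y[sample(1000, 400), 2] <- NA             # trait 2 observed on 600 rows
  hm <- handleMissing(Y, dat$g)
  expect_equal(hm$per_trait_n[2], 600L)
  expect_equal(hm$stats@n, 600)
  # 5% missing completely at random: BFs close to the complete-data truth
  Y2 <- dat$Y
  Y2[sample(length(Y2), round(0.05 * length(Y2)))] <- NA
  hm2 <- handleMissing(Y2, dat$g)
  st <- sufficientFromRaw(dat$Y, dat$g)
  parts <- enumeratePartitions(3)[-1]
  delta <- vapply(parts, function(gam)
    abs(logBFLimit(hm2$stats, gam, 0.2) - logBFLimit(st, gam, 0.2)),
    numeric(1))
  expect_lt(median(delta), 0.2)
  expect_error(handleMissing(matrix(NA_real_, 5, 2), rnorm(5)),
               "entirely missing")
})

test_that("Z-score path approximates the exact path at realistic n", {
  set.seed(25)
  parts <- enumeratePartitions(2)[-1]
  meds <- replicate(30, {
    dat <- makeToyData(1000, c(runif(1, 0, 0.15), 0), rho = 0.5)
    Ys <- scale(dat$Y)
    st_exact <- sufficientFromRaw(Ys, dat$g)
    sm <- summaryFromRaw(Ys, dat$g)
    st_z <- sufficientFromZ(sm$z, sm$maf, sm$n, cor(dat$Y))
    median(vapply(parts, function(gam)
      abs(logBFLimit(st_z, gam, 0.3) - logBFLimit(st_exact, gam, 0.3)),
      numeric(1)))
  })
  expect_lt(median(meds), 0.15)
})
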