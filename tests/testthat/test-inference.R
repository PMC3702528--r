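test_that("averaged BF reduces correctly under point and simple weights", {
  parts <- list(Partition(2, D = 1), Partition(2, D = 1:2))
  pr_point <- customPartitionPrior(parts, c(0, 1))
  bf <- matrix(c(0.7, 1.2), ncol = 1)
  expect_equal(bfAv(bf, pr_point, 1), 1.2)
  # BFs 10 and 30 with half weight each average to 20 on the natural scale
  pr_half <- customPartitionPrior(parts, c(0.5, 0.5))
  expect_equal(bfAv(matrix(c(1, log10(30)), ncol = 1), pr_half, 1),
               log10(20))
  expect_error(bfAv(matrix(c(1, 2), ncol = 1),
                    customPartitionPrior(parts, c(1, 1)) , c(0, 0)))
})

test_that("uniform weights on the univariate partitions reproduce BF_uni", {
  set.seed(31)
  dat <- makeToyData(200, c(0.3, 0.1), rho = 0.4)
  st <- sufficientFromRaw(dat$Y, dat$g)
  grid <- c(0.1, 0.4)
  tb <- computeBFTable(st, partitionPrior(2), grid, snp_id = "s1")
  sp <- specialPartitions(2)
  pr_uni <- customPartitionPrior(sp$gamma_uni, c(1, 1))
  expect_equal(tb@log10_bf_uni,
               bfAv(logBFMatrix(st, sp$gamma_uni, grid), pr_uni,
                    c(0.5, 0.5)))
  pr_all <- customPartitionPrior(list(sp$gamma_all), 1)
  expect_equal(tb@log10_bf_all,
               bfAv(logBFMatrix(st, list(sp$gamma_all), grid), pr_all,
                    c(0.5, 0.5)))
  # averaged BF lies between the extreme component BFs
  expect_gte(tb@log10_bf_av, min(tb@bf))
  expect_lte(tb@log10_bf_av, max(tb@bf))
})

test_that("posterior follows Bayes rule on hand-computable cases", {
  # single alternative, BF = 3, pi0 = 0.5: P(alt) = 3/4
  pr1 <- customPartitionPrior(list(Partition(2, D = 1:2)), 1, pi0 = 0.5)
  post <- posteriorPartitions(matrix(log10(3)), pr1, 1)
  expect_equal(post@p_null, 0.25, tolerance = 1e-12)
  expect_equal(post@partition_probs, 0.75, tolerance = 1e-12)
  # uninformative data: posterior equals prior
  pr <- partitionPrior(2, pi0 = 0.3)
  post0 <- posteriorPartitions(matrix(0, 5, 1), pr, 1)
  expect_equal(post0@p_null, 0.3, tolerance = 1e-12)
  expect_equal(post0@partition_probs, 0.7 * pr@weights, tolerance = 1e-12)
  # hand-normalized table with set BFs
  lbf <- log10(c(2, 1, 4, 1, 8))
  post2 <- posteriorPartitions(matrix(lbf, 5, 1), pr, 1)
  un <- c(0.3, 0.7 * pr@weights * c(2, 1, 4, 1, 8))
  expect_equal(c(post2@p_null, post2@partition_probs), un / sum(un),
               tolerance = 1e-12)
})

test_that("posterior summaries are coherent and order-invariant", {
  set.seed(32)
  dat <- makeToyData(150, c(0.25, 0, 0.1), rho = 0.3)
  st <- sufficientFromRaw(dat$Y, dat$g)
  pr <- partitionPrior(3, pi0 = 0.6)
  grid <- defaultSigmaGrid()
  bf <- logBFMatrix(st, pr@partitions, grid)
  post <- posteriorPartitions(bf, pr)
  # global-null evidence dominates per-trait evidence
  expect_true(all(post@p_assoc <= 1 - post@p_null + 1e-12))
  expect_true(all(post@p_null <= post@trait_category_probs[, "U"] + 1e-12))
  expect_equal(rowSums(post@trait_category_probs), rep(1, 3))
  # shuffling the partition enumeration leaves the posterior unchanged
  i <- sample(length(pr@partitions))
  pr2 <- customPartitionPrior(pr@partitions[i], pr@weights[i], pi0 = 0.6)
  post2 <- posteriorPartitions(bf[i, , drop = FALSE], pr2)
  expect_equal(post2@p_null, post@p_null, tolerance = 1e-12)
  expect_equal(post2@trait_category_probs, post@trait_category_probs,
               tolerance = 1e-12)
  # null-probability routes agree
  expect_equal(post@p_null,
               0.6 / (0.6 + 0.4 * 10^post@log10_bf_av), tolerance = 1e-12)
})

test_that("permutation p-value is reproducible and add-one bounded", {
  set.seed(33)
  dat <- makeToyData(60, c(0.5, 0.2), rho = 0.3)
  pr <- partitionPrior(2)
  p1 <- permutationPvalue(dat$Y, dat$g, pr, sigma_grid = 0.4,
                          n_perm = 199, seed = 7)
  p2 <- permutationPvalue(dat$Y, dat$g, pr, sigma_grid = 0.4,
                          n_perm = 199, seed = 7)
  expect_identical(p1$p_value, p2$p_value)
  expect_identical(p1$null_draws, p2$null_draws)
  expect_gte(p1$p_value, 1 / 200)
  expect_lte(p1$p_value, 1)
  expect_warning(permutationPvalue(dat$Y, dat$g, pr, sigma_grid = 0.4,
                                   n_perm = 50, seed = 1), "coarse")
  # an observed statistic below every permuted value gives p = 1
  fake <- p1
  expect_equal((1 + sum(fake$null_draws >= Inf)) / 200, 1 / 200)
  expect_equal((1 + sum(fake$null_draws >= -Inf)) / 200, 1)
})

test_that("stage-1 screen applies the chi-squared minimum rule", {
  R <- diag(4)
  sc <- stage1Screen(rbind(c(2, 0, 0, 0)), R, p_threshold = 0.5)
  expect_equal(sc$p_multi, pchisq(4, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(sc$p_multi, 0.406, tolerance = 1e-3)
  expect_equal(sc$p_uni_min, pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # zero scores are never promising below threshold 1
  sc0 <- stage1Screen(rbind(rep(0, 4)), R, p_threshold = 0.999)
  expect_false(sc0$promising)
  # a variant promising under the univariate rule is promising overall
  z <- rbind(c(6, 0, 0, 0))
  sc1 <- stage1Screen(z, R, p_threshold = 1e-4)
  expect_true(sc1$p_uni_min < 1e-4 && sc1$promising)
})

test_that("distance pruning keeps the right variants and is deterministic", {
  res <- data.frame(chrom = "1", pos = c(1e6, 1.2e6, 2e6),
                    log10_bf_av = c(9, 8, 7),
                    snp_id = c("a", "b", "c"))
  kept <- ldPruneByDistance(res, window = 5e5)
  expect_equal(kept$snp_id, c("a", "c"))
  # different chromosomes never prune each other
  res2 <- data.frame(chrom = c("1", "2"), pos = c(1e6, 1e6),
                     log10_bf_av = c(5, 4), snp_id = c("a", "b"))
  expect_equal(nrow(ldPruneByDistance(res2)), 2)
  # ties broken by (chrom, pos), reproducibly
  res3 <- data.frame(chrom = c("2", "1"), pos = c(5, 5),
                     log10_bf_av = c(1, 1), snp_id = c("x", "y"))
  expect_equal(ldPruneByDistance(res3)$snp_id, c("y", "x"))
  expect_error(ldPruneByDistance(data.frame(chrom = "1", pos = NA,
                                            log10_bf_av = 1)), "missing")
})
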