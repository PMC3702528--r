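#' Per-variant Bayes factor table
#'
#' Log10 Bayes factors of one variant for every non-null partition and every
#' effect-size scale in the grid, together with the three headline summaries:
#' the prior-averaged `BF_av`, the all-direct `BF_all` (the standard
#' multivariate test) and the equal-weight univariate average `BF_uni`.
#'
#' @slot snp_id variant identifier.
#' @slot bf matrix of log10 Bayes factors (non-null partitions x grid), with
#'   partition strings as row names and `sigma_a` values as column names.
#' @slot log10_bf_av,log10_bf_all,log10_bf_uni summary log10 Bayes factors.
#' @export
setClass("BFTable",
  representation(snp_id = "character", bf = "matrix",
                 log10_bf_av = "numeric", log10_bf_all = "numeric",
                 log10_bf_uni = "numeric"))

setMethod("show", "BFTable", function(object) {
  cat("BFTable for ", object@snp_id, ": ", nrow(object@bf),
      " partitions x ", ncol(object@bf), " sigma_a values\n",
      "  log10 BF_av = ", signif(object@log10_bf_av, 4),
      ", BF_all = ", signif(object@log10_bf_all, 4),
      ", BF_uni = ", signif(object@log10_bf_uni, 4), "\n", sep = "")
})

#' Compute the Bayes factor table of one variant
#'
#' @param stats a [SufficientStats-class].
#' @param prior a [PartitionPrior-class] (defines the non-null partitions
#'   and their weights for `BF_av`).
#' @param sigma_grid vector of `sigma_a` values.
#' @param sigma_weights weights over the grid (default uniform).
#' @param snp_id variant identifier.
#' @return A [BFTable-class].
#' @export
computeBFTable <- function(stats, prior, sigma_grid = defaultSigmaGrid(),
                           sigma_weights = NULL, snp_id = "snp") {
  if (is.null(sigma_weights))
    sigma_weights <- rep(1 / length(sigma_grid), length(sigma_grid))
  d <- nTraits(stats)
  bf <- logBFMatrix(stats, prior@partitions, sigma_grid)
  sp <- specialPartitions(d)
  key <- vapply(prior@partitions, formatPartition, character(1))
  row_of <- function(g) {
    i <- match(formatPartition(g), key)
    if (is.na(i)) logBFMatrix(stats, list(g), sigma_grid)[1, ] else bf[i, ]
  }
  lbf_all <- .lse10(row_of(sp$gamma_all), sigma_weights)
  uni_rows <- t(vapply(sp$gamma_uni, row_of, numeric(length(sigma_grid))))
  lbf_uni <- .lse10(apply(uni_rows, 1, function(x) .lse10(x, sigma_weights)),
                    rep(1 / d, d))
  new("BFTable", snp_id = snp_id, bf = bf,
      log10_bf_av = bfAv(bf, prior, sigma_weights),
      log10_bf_all = lbf_all, log10_bf_uni = lbf_uni)
}

#' Stack per-variant Bayes factor tables into an EM input matrix
#'
#' @param tables list of [BFTable-class] objects sharing partition and grid
#'   layout.
#' @return matrix, variants in rows, `(partition, sigma_a)` components in
#'   columns named `"<partition>@<sigma_a>"`.
#' @export
bfMatrixFromTables <- function(tables) {
  stopifnot(length(tables) > 0)
  proto <- tables[[1]]@bf
  out <- t(vapply(tables, function(tb) as.numeric(tb@bf),
                  numeric(length(proto))))
  colnames(out) <- as.character(outer(rownames(proto), colnames(proto),
                                      paste, sep = "@"))
  rownames(out) <- vapply(tables, function(tb) tb@snp_id, character(1))
  out
}

#' Two-stage genome scan over a summary-statistic table
#'
#' Runs the full workflow on per-variant Z-score records: (1) estimate the
#' phenotype correlation matrix from putative null variants (unless
#' supplied); (2) apply the cheap chi-squared screen to flag promising
#' variants; (3) for each promising variant, build approximate sufficient
#' statistics from (Z, MAF, n) and evaluate Bayes factors for every non-null
#' partition over the effect-size grid, with posterior partition and
#' trait-category summaries; (4) sort by `log10 BF_av` and greedily prune
#' variants within `window` bp of a higher-ranked variant on the same
#' chromosome.
#'
#' @param records summary data.frame (see [readSummaryStats()]).
#' @param R optional phenotype correlation ([CorrelationEstimate-class] or
#'   matrix); estimated from the records when `NULL`.
#' @param prior optional [PartitionPrior-class]; default
#'   `partitionPrior(d, pi0)`.
#' @param sigma_grid,sigma_weights effect-size grid and weights.
#' @param pi0 prior probability of the global null (default 0.5).
#' @param stage1_p stage-1 promotion threshold (default `1e-4`).
#' @param z_threshold |Z| cutoff defining null variants for the correlation
#'   estimate (default 2).
#' @param window pruning window in bp (default 500000).
#' @param min_n exclude variants with `n` below this cutoff (default 0).
#' @return list with elements `results` (data.frame, one row per promising
#'   variant, sorted by decreasing `log10_bf_av`, with a logical `kept`
#'   column marking pruning survivors), `tables` (list of
#'   [BFTable-class]), `posteriors` (list of [PosteriorSummary-class]),
#'   `R` (the correlation estimate used) and `counts` (variants per stage).
#' @export
runScan <- function(records, R = NULL, prior = NULL,
                    sigma_grid = defaultSigmaGrid(), sigma_weights = NULL,
                    pi0 = 0.5, stage1_p = 1e-4, z_threshold = 2,
                    window = 5e5, min_n = 0) {
  zcols <- grep("^z_", names(records), value = TRUE)
  if (!length(zcols)) stop("records have no z_<trait> columns")
  d <- length(zcols)
  traits <- sub("^z_", "", zcols)
  n_in <- nrow(records)
  records <- records[records$n >= min_n, , drop = FALSE]
  Z <- as.matrix(records[zcols])
  if (is.null(R)) R <- estimateNullCorrelation(Z, z_threshold)
  if (is.null(prior)) prior <- partitionPrior(d, pi0 = pi0)
  if (is.null(sigma_weights))
    sigma_weights <- rep(1 / length(sigma_grid), length(sigma_grid))
  screen <- stage1Screen(Z, R, p_threshold = stage1_p)
  idx <- which(screen$promising)
  tables <- vector("list", length(idx))
  posteriors <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    stats <- sufficientFromZ(as.numeric(Z[i, ]), records$maf[i],
                             records$n[i], R, trait_names = traits)
    tables[[k]] <- computeBFTable(stats, prior, sigma_grid, sigma_weights,
                                  snp_id = records$snp_id[i])
    posteriors[[k]] <- posteriorPartitions(tables[[k]]@bf, prior,
                                           sigma_weights)
  }
  res <- records[idx, c("snp_id", "chrom", "pos", "maf", "n"), drop = FALSE]
  res$log10_bf_av <- vapply(tables, function(tb) tb@log10_bf_av, numeric(1))
  res$log10_bf_all <- vapply(tables, function(tb) tb@log10_bf_all, numeric(1))
  res$log10_bf_uni <- vapply(tables, function(tb) tb@log10_bf_uni, numeric(1))
  res$p_null <- vapply(posteriors, function(p) p@p_null, numeric(1))
  for (j in seq_len(d)) for (cat in c("U", "D", "I"))
    res[[paste0("p_", cat, "_", traits[j])]] <-
      vapply(posteriors, function(p) p@trait_category_probs[j, cat],
             numeric(1))
  top3 <- vapply(posteriors, function(p) {
    k <- order(p@partition_probs, decreasing = TRUE)
    k <- k[seq_len(min(3, length(k)))]
    paste(sprintf("%s=%.3g", p@partition_names[k], p@partition_probs[k]),
          collapse = ";")
  }, character(1))
  res$top_partitions <- top3
  ord <- order(-res$log10_bf_av, as.character(res$chrom), res$pos)
  res <- res[ord, , drop = FALSE]
  tables <- tables[ord]
  posteriors <- posteriors[ord]
  kept_ids <- if (nrow(res))
    ldPruneByDistance(res, window = window)$snp_id else character(0)
  res$kept <- res$snp_id %in% kept_ids
  list(results = res, tables = tables, posteriors = posteriors, R = R,
       counts = c(input = n_in, after_min_n = nrow(records),
                  promising = length(idx), kept = sum(res$kept)))
}

#' Write scan results
#'
#' @param scan result of [runScan()].
#' @param path output TSV path.
#' @export
writeScanResults <- function(scan, path) {
  write.table(scan$results, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Single-variant report from raw data
#'
#' Computes the full Bayes-factor table and posterior summary for one variant
#' from raw phenotypes and genotypes (missing phenotype entries handled by
#' pairwise-complete statistics).
#'
#' @param Y phenotype matrix.
#' @param g genotype vector.
#' @param prior optional [PartitionPrior-class].
#' @param sigma_grid,sigma_weights effect-size grid and weights.
#' @param pi0 prior null probability.
#' @param snp_id variant identifier.
#' @return list with `table` (a [BFTable-class]) and `posterior`
#'   (a [PosteriorSummary-class]).
#' @export
singleVariantReport <- function(Y, g, prior = NULL,
                                sigma_grid = defaultSigmaGrid(),
                                sigma_weights = NULL, pi0 = 0.5,
                                snp_id = "snp") {
  Y <- as.matrix(Y)
  d <- ncol(Y)
  if (is.null(prior)) prior <- partitionPrior(d, pi0 = pi0)
  if (is.null(sigma_weights))
    sigma_weights <- rep(1 / length(sigma_grid), length(sigma_grid))
  stats <- if (anyNA(Y) || anyNA(g)) handleMissing(Y, g)$stats
           else sufficientFromRaw(Y, g)
  tb <- computeBFTable(stats, prior, sigma_grid, sigma_weights, snp_id)
  list(table = tb,
       posterior = posteriorPartitions(tb@bf, prior, sigma_weights))
}
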