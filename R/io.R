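#' @importFrom utils read.delim write.table head
NULL

# All tabular I/O uses one dialect: tab-separated, header row, UTF-8,
# "NA" for missing, 1-based positions, chromosome as character.

#' Read / write a phenotype table
#'
#' Phenotype files have one header row of trait names and one row per
#' individual; missing values are `NA`.
#'
#' @param path file path.
#' @return `readPhenotypes` returns a numeric matrix with column names.
#' @export
readPhenotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (ncol(df) < 1) stop("phenotype file has no columns")
  as.matrix(df)
}

#' @rdname readPhenotypes
#' @param Y phenotype matrix.
#' @export
writePhenotypes <- function(Y, path) {
  write.table(as.data.frame(Y), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a genotype table
#'
#' Genotype files have one row per variant: a `snp_id` column followed by one
#' column per individual holding allele counts or dosages.
#'
#' @param path file path.
#' @return `readGenotypes` returns a numeric matrix, variants in rows
#'   (rownames are variant ids), individuals in columns.
#' @export
readGenotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (!"snp_id" %in% names(df)) stop("genotype file needs an snp_id column")
  m <- as.matrix(df[, setdiff(names(df), "snp_id"), drop = FALSE])
  rownames(m) <- df$snp_id
  m
}

#' @rdname readGenotypes
#' @param G genotype matrix (variants x individuals, rownames = ids).
#' @export
writeGenotypes <- function(G, path) {
  df <- data.frame(snp_id = rownames(G) %||% sprintf("snp%04d", seq_len(nrow(G))),
                   as.data.frame(G), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a GWAS summary-statistic table
#'
#' Expects tab-separated columns `snp_id`, `chrom`, `pos`, `maf`, `n` and one
#' `z_<trait>` column per trait. Allele frequencies above 0.5 are folded to
#' the minor allele (`maf <- 1 - maf`) with the corresponding Z-score signs
#' flipped, so downstream Z-scores are always signed with respect to the
#' minor allele. Malformed rows raise errors naming the offending line.
#'
#' @param path file path.
#' @param min_n exclude variants with sample size below this cutoff
#'   (default 0: keep all).
#' @return data.frame with validated columns; attribute `"traits"` holds the
#'   trait names.
#' @export
readSummaryStats <- function(path, min_n = 0) {
  df <- read.delim(path, check.names = FALSE,
                   colClasses = c(chrom = "character"))
  need <- c("snp_id", "chrom", "pos", "maf", "n")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("summary file lacks column(s): ", paste(miss, collapse = ", "))
  zcols <- grep("^z_", names(df), value = TRUE)
  if (!length(zcols)) stop("summary file has no z_<trait> columns")
  bad <- which(!is.finite(as.matrix(df[zcols])) |
                 is.na(df$maf) | df$maf <= 0 | df$maf >= 1 |
                 is.na(df$n) | df$n < 1 | is.na(df$pos), arr.ind = TRUE)
  if (length(bad))
    stop("malformed summary row(s) at line(s): ",
         paste(head(unique(sort(if (is.matrix(bad)) bad[, 1] else bad)), 5) + 1,
               collapse = ", "))
  flip <- df$maf > 0.5
  if (any(flip)) {
    df$maf[flip] <- 1 - df$maf[flip]
    df[flip, zcols] <- -df[flip, zcols]
  }
  df <- df[df$n >= min_n, , drop = FALSE]
  attr(df, "traits") <- sub("^z_", "", zcols)
  df
}

#' @rdname readSummaryStats
#' @param records summary data.frame as produced by
#'   [simulateSummaryRecords()] or [readSummaryStats()].
#' @export
writeSummaryStats <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read / write empirical-Bayes weights
#'
#' Weights tables have columns `partition` (string serialization), `sigma_a`
#' and `weight`.
#'
#' @param eb an [EBWeights-class] whose component names have the form
#'   `"<partition>@<sigma_a>"`, as produced by the scan tooling, or a
#'   data.frame with the three columns.
#' @param path file path.
#' @export
writeWeights <- function(eb, path) {
  if (is(eb, "EBWeights")) {
    nm <- names(eb@weights)
    parts <- sub("@[^@]*$", "", nm)
    sig <- as.numeric(sub("^.*@", "", nm))
    df <- data.frame(partition = parts, sigma_a = sig, weight = eb@weights)
  } else df <- eb
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWeights
#' @return `readWeights` returns a data.frame with columns `partition`,
#'   `sigma_a`, `weight`.
#' @export
readWeights <- function(path) {
  df <- read.delim(path)
  if (!all(c("partition", "sigma_a", "weight") %in% names(df)))
    stop("weights file needs partition, sigma_a, weight columns")
  df
}

#' Read / write a flat key: value configuration file
#'
#' One `key: value` pair per line; blank lines and lines starting with `#`
#' are ignored. Values that parse as numbers become numeric; comma-separated
#' numeric lists become vectors.
#'
#' @param path file path.
#' @return named list of values.
#' @export
readConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    pieces <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(pieces))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

#' @rdname readConfig
#' @param config named list.
#' @export
writeConfig <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, ": ", paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}
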