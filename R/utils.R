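## Internal helpers shared across modules.

#' Row-wise z-scores of an expression matrix
#'
#' Centers and scales each gene (row) across samples. Genes with zero
#' standard deviation are mapped to all-zero rows rather than NaN, so a
#' constant gene contributes nothing to downstream signature scores.
#'
#' @param x numeric matrix, genes as rows.
#' @return matrix of the same dimension with per-row mean 0 and sd 1
#'   (or all zeros for constant rows).
#' @export
zscore_rows <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  m <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  z <- (x - m) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 = identical partitions (up to label names), ~0 = agreement at chance.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

## stop() with a consistent prefix, no call noise
abort <- function(...) stop(..., call. = FALSE)

assert_finite_matrix <- function(x, what = "matrix") {
  if (any(!is.finite(x))) {
    abort(what, " contains non-finite values; reject or impute before use")
  }
  invisible(x)
}

## Fan a single pipeline seed out to per-stage streams. Offsets are fixed
## so stages can be re-run independently yet reproducibly; the sum stays
## far below .Machine$integer.max for any sane user seed.
stage_seed <- function(seed, stage) {
  offsets <- c(
    screen = 101L, expression = 211L, training = 307L,
    survival = 401L, mutation = 503L, transfer = 601L, misc = 701L
  )
  if (!stage %in% names(offsets)) abort("unknown stage: ", stage)
  as.integer((as.numeric(seed) + offsets[[stage]]) %% .Machine$integer.max)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

## Write a numeric matrix with a leading id column (genes or samples as rows).
write_matrix_tsv <- function(mat, path, id_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "double"
  mat
}
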