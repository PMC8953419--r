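#' Filter lowly expressed genes from a count matrix
#'
#' A gene is retained iff it has at least `min_count` reads in *more than*
#' `min_fraction` of the samples (strict inequality), the standard low-count
#' filter for bulk RNA-seq cohorts.
#'
#' @param counts an [ExpressionMatrix()] on the counts scale.
#' @param min_count minimum read count per sample (default 3).
#' @param min_fraction fraction of samples that must exceed it (default 1/3).
#' @return a filtered counts-scale [ExpressionMatrix()].
#' @export
filter_low_count <- function(counts, min_count = 3, min_fraction = 1 / 3) {
  if (counts$scale != "counts")
    stop("filter_low_count expects a counts-scale matrix, got ", counts$scale)
  v <- em_values(counts)
  n <- ncol(v)
  keep <- rowSums(v >= min_count) > min_fraction * n
  out <- counts
  out$values <- v[keep, , drop = FALSE]
  out
}

#' Library-size normalization to log2 counts-per-million
#'
#' Scales each sample to counts-per-million and applies `log2(x + 1)`.
#' Stands in for upstream TPM when gene lengths are unavailable.
#'
#' @param counts an [ExpressionMatrix()] on the counts scale.
#' @return a log2-scale [ExpressionMatrix()].
#' @export
normalize_log <- function(counts) {
  if (counts$scale != "counts")
    stop("normalize_log expects a counts-scale matrix, got ", counts$scale)
  v <- em_values(counts)
  libs <- colSums(v)
  if (any(libs == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(v)[libs == 0], collapse = ", "))
  cpm <- sweep(v, 2, libs / 1e6, "/")
  ExpressionMatrix(log2(cpm + 1), scale = "log2")
}

#' Row-wise z-scoring of an expression matrix
#'
#' Standardizes each gene to mean 0, sample standard deviation 1 (n - 1
#' denominator). Constant genes are dropped with a warning. The per-gene
#' centers and sds are stored in the `center` and `sd` fields so a fitted
#' standardization can be reapplied ("frozen") to new cohorts.
#'
#' @param expr an [ExpressionMatrix()] on the normalized or log2 scale.
#' @return a zscore-scale [ExpressionMatrix()] with `center`/`sd` fields.
#' @export
gene_zscore <- function(expr) {
  if (!expr$scale %in% c("normalized", "log2"))
    stop("gene_zscore expects normalized or log2 scale, got ", expr$scale)
  v <- em_values(expr)
  if (ncol(v) < 2) stop("gene_zscore requires at least 2 samples")
  mu <- rowMeans(v)
  sdv <- matrixStats::rowSds(v)
  const <- sdv == 0
  if (any(const)) {
    warning(sprintf("gene_zscore: dropped %d constant gene(s)", sum(const)))
    v <- v[!const, , drop = FALSE]
    mu <- mu[!const]
    sdv <- sdv[!const]
  }
  if (nrow(v) == 0) stop("no non-constant genes to z-score")
  z <- (v - mu) / sdv
  out <- ExpressionMatrix(z, scale = "zscore")
  out$center <- setNames(mu, rownames(v))
  out$sd <- setNames(sdv, rownames(v))
  out
}
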