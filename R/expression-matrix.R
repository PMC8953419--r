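#' ExpressionMatrix: a gene-by-sample matrix with a declared scale
#'
#' Thin S3 container used throughout the package: a numeric matrix with unique
#' gene row names and sample column names, plus a `scale` tag recording what
#' the numbers mean (`"counts"`, `"normalized"`, `"log2"` or `"zscore"`).
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   dimnames set.
#' @param scale one of `"counts"`, `"normalized"`, `"log2"`, `"zscore"`.
#' @return an `ExpressionMatrix` object.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' em <- ExpressionMatrix(m, "counts")
#' dim(em)
#' @export
ExpressionMatrix <- function(values,
                             scale = c("counts", "normalized", "log2", "zscore")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in ExpressionMatrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in ExpressionMatrix")
  if (!all(is.finite(values)))
    stop("ExpressionMatrix values must all be finite")
  if (scale == "counts" && any(values < 0))
    stop("counts-scale ExpressionMatrix must be non-negative")
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (scale: %s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Gene ids of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of gene symbols.
#' @export
em_genes <- function(x) rownames(x$values)

#' Sample ids of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of sample ids.
#' @export
em_samples <- function(x) colnames(x$values)

#' Numeric values of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return the underlying numeric matrix.
#' @export
em_values <- function(x) x$values

#' Subset an ExpressionMatrix by gene and/or sample ids
#'
#' @param x an `ExpressionMatrix`.
#' @param genes,samples character vectors of ids to keep (default: all).
#' @return an `ExpressionMatrix` restricted to the requested ids.
#' @export
em_subset <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  out <- x
  out$values <- v
  out
}

# Case-insensitive intersection of a requested gene list with the matrix rows;
# returns the matrix's own spelling. Missing genes are reported via m6a_log.
match_genes <- function(x, genes, what = "gene list") {
  idx <- match(toupper(genes), toupper(em_genes(x)))
  missing <- genes[is.na(idx)]
  if (length(missing) > 0)
    m6a_log("%s: %d of %d genes absent from matrix, dropped",
            what, length(missing), length(genes))
  em_genes(x)[idx[!is.na(idx)]]
}
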