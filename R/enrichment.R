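#' Single-sample gene-set enrichment score
#'
#' Rank-based running-sum statistic for one sample: genes are ordered by
#' decreasing expression and the score is the summed difference between the
#' cumulative rank-weighted mass of in-set genes (weight `rank^alpha`, where
#' the top gene has rank N) and the cumulative uniform mass of out-of-set
#' genes. Ties are broken by a seeded stable shuffle of gene order so the
#' score is deterministic.
#'
#' @param expr_sample named numeric vector: one sample's expression.
#' @param gene_set character vector of member symbols (case-insensitive).
#' @param alpha rank-weight exponent (default 0.25; 0 = unweighted).
#' @param tie_seed seed for the tie-breaking shuffle (default 1).
#' @return scalar enrichment score, or `NA` (with a warning) when fewer than
#'   2 set members are present.
#' @export
ssgsea_score <- function(expr_sample, gene_set, alpha = 0.25, tie_seed = 1) {
  stopifnot(!is.null(names(expr_sample)))
  ord <- ssgsea_order(expr_sample, tie_seed)
  ssgsea_core(names(expr_sample)[ord], gene_set, alpha)
}

# Decreasing-expression ordering with seeded stable tie-breaking.
ssgsea_order <- function(x, tie_seed) {
  n <- length(x)
  perm <- with_seed(tie_seed, sample.int(n))
  perm[order(x[perm], decreasing = TRUE, method = "radix")]
}

# Running-sum evaluation given the ordered gene names.
ssgsea_core <- function(ordered_genes, gene_set, alpha) {
  n <- length(ordered_genes)
  ind <- toupper(ordered_genes) %in% unique(toupper(gene_set))
  n_in <- sum(ind)
  if (n_in < 2) {
    warning("ssgsea_score: fewer than 2 set members present; score undefined")
    return(NA_real_)
  }
  if (n_in == n) stop("gene set covers the whole matrix; score undefined")
  w <- (n - seq_len(n) + 1)^alpha
  p_in <- cumsum(w * ind) / sum(w * ind)
  p_out <- cumsum(!ind) / (n - n_in)
  sum(p_in - p_out)
}

#' Score a gene-set collection across all samples
#'
#' Applies [ssgsea_score()] to every (signature, sample) pair; signatures
#' with fewer than 2 members present are skipped with a warning. Row
#' z-scoring across samples (optional, on by default) eases cross-signature
#' display and group comparison.
#'
#' @param expr an [ExpressionMatrix()] on the normalized or log2 scale.
#' @param collection named list of gene sets.
#' @param alpha rank-weight exponent (default 0.25).
#' @param zscore_rows z-score each signature across samples (default TRUE).
#' @param tie_seed seed for tie-breaking (default 1).
#' @return a signature-by-sample numeric matrix of class `EnrichmentMatrix`
#'   with attributes `alpha` and `zscored`.
#' @export
enrich_collection <- function(expr, collection, alpha = 0.25,
                              zscore_rows = TRUE, tie_seed = 1) {
  if (length(collection) == 0) stop("empty gene-set collection")
  if (!expr$scale %in% c("normalized", "log2"))
    stop("enrich_collection expects normalized or log2 scale, got ", expr$scale)
  v <- em_values(expr)
  genes_up <- toupper(rownames(v))
  present <- vapply(collection,
                    function(s) sum(unique(toupper(s)) %in% genes_up),
                    numeric(1))
  skip <- present < 2
  if (any(skip)) {
    warning(sprintf("skipping %d signature(s) with <2 members present: %s",
                    sum(skip), paste(names(collection)[skip], collapse = ", ")))
    collection <- collection[!skip]
  }
  if (length(collection) == 0) stop("no scoreable signatures in collection")
  scores <- matrix(NA_real_, length(collection), ncol(v),
                   dimnames = list(names(collection), colnames(v)))
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    names(x) <- rownames(v)
    ordered <- names(x)[ssgsea_order(x, tie_seed)]
    for (i in seq_along(collection))
      scores[i, j] <- ssgsea_core(ordered, collection[[i]], alpha)
  }
  if (zscore_rows && ncol(scores) >= 2) {
    sds <- matrixStats::rowSds(scores)
    sds[sds == 0] <- 1  # constant signatures stay at 0 rather than NaN
    scores <- (scores - rowMeans(scores)) / sds
  }
  structure(scores, alpha = alpha, zscored = zscore_rows,
            class = c("EnrichmentMatrix", "matrix", "array"))
}

#' Relative abundance of 28 tumor-infiltrating lymphocyte subpopulations
#'
#' [enrich_collection()] restricted to a 28-signature TIL compendium.
#'
#' @param expr an [ExpressionMatrix()] (normalized or log2).
#' @param til_collection_28 named list of exactly 28 gene sets.
#' @param ... passed to [enrich_collection()].
#' @return an `EnrichmentMatrix` (28 x n_samples).
#' @export
til_abundance <- function(expr, til_collection_28, ...) {
  if (length(til_collection_28) != 28)
    stop("TIL collection must contain exactly 28 signatures, got ",
         length(til_collection_28))
  enrich_collection(expr, til_collection_28, ...)
}

#' ImmuneScore and StromaScore of the tumor microenvironment
#'
#' Per-sample single-sample enrichment of user-supplied immune and stromal
#' signature sets (ESTIMATE-style naming; the published ESTIMATE coefficients
#' are not reproduced).
#'
#' @param expr an [ExpressionMatrix()] (normalized or log2).
#' @param immune_set,stromal_set character vectors of signature genes.
#' @param alpha rank-weight exponent (default 0.25).
#' @param tie_seed seed for tie-breaking (default 1).
#' @return a 2 x n_samples matrix with rows `ImmuneScore`, `StromaScore`.
#' @export
tme_scores <- function(expr, immune_set, stromal_set, alpha = 0.25,
                       tie_seed = 1) {
  enr <- enrich_collection(
    expr, list(ImmuneScore = immune_set, StromaScore = stromal_set),
    alpha = alpha, zscore_rows = FALSE, tie_seed = tie_seed)
  enr[c("ImmuneScore", "StromaScore"), , drop = FALSE]
}

#' Group-difference tests for signature scores
#'
#' Per signature: Wilcoxon rank-sum for two groups, Kruskal-Wallis for more,
#' with BH adjustment across signatures.
#'
#' @param enrichment a signature-by-sample matrix.
#' @param labels per-sample group labels (named by sample id or aligned).
#' @return data.frame with signature, p, q.
#' @export
groupwise_signature_test <- function(enrichment, labels) {
  if (!is.null(names(labels))) labels <- labels[colnames(enrichment)]
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 groups")
  if (any(table(labels) == 0)) stop("empty group in labels")
  p <- apply(enrichment, 1, function(x) {
    if (nlevels(labels) == 2) {
      suppressWarnings(
        wilcox.test(x[labels == levels(labels)[1]],
                    x[labels == levels(labels)[2]], exact = FALSE)$p.value)
    } else {
      kruskal.test(x, labels)$p.value
    }
  })
  p[is.na(p)] <- 1
  data.frame(signature = rownames(enrichment), p = p, q = bh_fdr(p),
             row.names = NULL, stringsAsFactors = FALSE)
}
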