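#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1, with
#' monotonicity enforced by the running minimum.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p_values)
  if (n == 0) return(numeric(0))
  o <- order(p_values)
  q <- p_values[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Pairwise differential expression between two clusters
#'
#' Per-gene two-sided Wilcoxon rank-sum test on log2-normalized values; fold
#' change is the ratio of linear-scale group means with pseudocount 1;
#' BH adjustment across tested genes. A gene is significant iff
#' `q < fdr_max` and `max(FC, 1/FC) > fc_min`.
#'
#' @param expr an [ExpressionMatrix()] on the log2 (or normalized) scale.
#' @param labels per-sample group labels, named by sample id or aligned with
#'   the matrix columns.
#' @param groupA,groupB the two labels to contrast. Direction and fold change
#'   are reported for `groupB` relative to `groupA`.
#' @param fdr_max FDR cutoff (default 0.05).
#' @param fc_min linear fold-change cutoff, strict (default 2).
#' @return a `data.frame` of class `DEGTable`: gene, log2fc, fc, p, q,
#'   direction (`"up"`/`"down"` in `groupB`), significant.
#' @export
pairwise_deg <- function(expr, labels, groupA, groupB,
                         fdr_max = 0.05, fc_min = 2) {
  if (!expr$scale %in% c("log2", "normalized"))
    stop("pairwise_deg expects log2 or normalized scale, got ", expr$scale)
  v <- em_values(expr)
  if (!is.null(names(labels))) labels <- labels[colnames(v)]
  ia <- which(labels == groupA)
  ib <- which(labels == groupB)
  if (length(ia) < 3 || length(ib) < 3)
    stop("both groups need >= 3 samples")
  lin <- if (expr$scale == "log2") 2^v - 1 else v
  mA <- rowMeans(lin[, ia, drop = FALSE])
  mB <- rowMeans(lin[, ib, drop = FALSE])
  fc <- (mB + 1) / (mA + 1)
  p <- vapply(seq_len(nrow(v)), function(g) {
    suppressWarnings(
      wilcox.test(v[g, ib], v[g, ia], exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1  # all-tied genes carry no evidence
  q <- bh_fdr(p)
  out <- data.frame(
    gene = rownames(v),
    log2fc = log2(fc),
    fc = fc,
    p = p,
    q = q,
    direction = ifelse(fc >= 1, "up", "down"),
    significant = q < fdr_max & pmax(fc, 1 / fc) > fc_min,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "contrast") <- c(groupA = groupA, groupB = groupB)
  class(out) <- c("DEGTable", "data.frame")
  out
}

#' Core differentially expressed genes across pairwise contrasts
#'
#' Genes significant in at least `min_contrasts` of the supplied pairwise
#' cluster contrasts, regardless of direction.
#'
#' @param deg_tables list of `DEGTable` objects (one per contrast; all three
#'   pairwise contrasts for a 3-cluster cohort).
#' @param min_contrasts minimum number of contrasts (default 2).
#' @return a list with `genes` (character) and `counts` (named integer vector
#'   of per-gene significant-contrast counts, core genes only).
#' @export
core_degs <- function(deg_tables, min_contrasts = 2) {
  if (length(deg_tables) < 3)
    stop("core_degs expects all three pairwise contrasts")
  sig <- unlist(lapply(deg_tables, function(d) d$gene[d$significant]))
  counts <- table(sig)
  keep <- counts[counts >= min_contrasts]
  list(genes = names(keep),
       counts = setNames(as.integer(keep), names(keep)))
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability `P(X >= overlap)` of the observed overlap when
#' `|query|` genes are drawn without replacement from a universe containing
#' `|target|` marked genes.
#'
#' @param query_set,target_set character vectors of gene symbols
#'   (case-insensitive).
#' @param universe_size size of the gene universe both sets live in.
#' @return a list with `overlap` and `p`.
#' @export
hypergeometric_overlap <- function(query_set, target_set, universe_size) {
  query_set <- unique(toupper(query_set))
  target_set <- unique(toupper(target_set))
  if (length(query_set) > universe_size || length(target_set) > universe_size)
    stop("sets cannot exceed the universe size")
  ov <- length(intersect(query_set, target_set))
  p <- phyper(ov - 1, length(target_set),
              universe_size - length(target_set),
              length(query_set), lower.tail = FALSE)
  list(overlap = ov, p = p)
}

#' Filter a target list by per-gene evidence count
#'
#' Generic stand-in for "predicted by at least two strategies" target
#' filtering: keeps genes whose evidence count meets `min_evidence`.
#'
#' @param targets data.frame with columns `gene` and `n_evidence`.
#' @param min_evidence minimum evidence count (default 2).
#' @return character vector of retained gene symbols (uppercased).
#' @export
filter_targets_by_evidence <- function(targets, min_evidence = 2) {
  stopifnot(all(c("gene", "n_evidence") %in% names(targets)))
  unique(toupper(targets$gene[targets$n_evidence >= min_evidence]))
}
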