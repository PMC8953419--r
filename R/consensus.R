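#' Resampling consensus clustering
#'
#' Repeatedly subsamples the cohort, clusters each subsample by Ward
#' agglomerative clustering (Euclidean distance on the selected z-scored
#' features), and records, for every sample pair, the fraction of co-sampled
#' resamples in which the pair co-clustered. Final assignments come from
#' agglomerative clustering of `1 - consensus`; pairs never co-sampled get
#' consensus 0.
#'
#' @param z_matrix an [ExpressionMatrix()] on the zscore scale.
#' @param features character vector of feature genes (matched
#'   case-insensitively); `NULL` uses all rows.
#' @param k number of clusters (>= 2).
#' @param n_resamples number of subsampling iterations (default 1000).
#' @param subsample_fraction fraction of samples drawn per iteration,
#'   without replacement (default 0.8).
#' @param seed integer RNG seed.
#' @param severity optional named per-sample score; cluster labels are
#'   renumbered so cluster 1 has the lowest mean severity.
#' @return a `ConsensusResult` list: `k`, `consensus_matrix`, `assignments`
#'   (named integer vector), `co_sample_counts`, `pac`.
#' @export
consensus_cluster <- function(z_matrix, features = NULL, k,
                              n_resamples = 1000, subsample_fraction = 0.8,
                              seed = 1, severity = NULL) {
  if (k < 2) stop("k must be >= 2")
  feats <- if (is.null(features)) em_genes(z_matrix)
           else match_genes(z_matrix, features, "consensus features")
  if (length(feats) == 0) stop("no clustering features present in matrix")
  X <- t(em_values(z_matrix)[feats, , drop = FALSE])  # samples x features
  n <- nrow(X)
  if (k > nrow(unique(X))) stop("k exceeds the number of distinct samples")
  m <- ceiling(subsample_fraction * n)
  co_clust <- matrix(0, n, n)
  co_samp <- matrix(0L, n, n)
  with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      idx <- sort(sample.int(n, m))
      cl <- cutree(hclust(dist(X[idx, , drop = FALSE]), method = "ward.D2"), k)
      same <- outer(cl, cl, "==")
      co_clust[idx, idx] <- co_clust[idx, idx] + same
      co_samp[idx, idx] <- co_samp[idx, idx] + 1L
    }
  })
  cons <- ifelse(co_samp > 0, co_clust / pmax(co_samp, 1L), 0)
  diag(cons) <- 1
  dimnames(cons) <- list(rownames(X), rownames(X))
  dimnames(co_samp) <- dimnames(cons)
  assign <- cutree(hclust(as.dist(1 - cons), method = "ward.D2"), k)
  names(assign) <- rownames(X)
  if (!is.null(severity)) {
    sev <- severity[names(assign)]
    ord <- order(vapply(seq_len(k), function(cc) mean(sev[assign == cc]),
                        numeric(1)))
    assign <- setNames(match(assign, ord), names(assign))
  }
  structure(list(k = k, consensus_matrix = cons, assignments = assign,
                 co_sample_counts = co_samp, pac = pac_score(cons),
                 cdf_area = consensus_cdf_area(cons)),
            class = "ConsensusResult")
}

#' Area under the consensus CDF
#'
#' Area under the empirical CDF of the off-diagonal consensus entries over
#' `[0, 1]`. Larger areas mean more pairs sit at low consensus; the gain in
#' area from k to k+1 measures how much genuine splitting another cluster
#' buys (Monti's consensus-clustering diagnostic).
#'
#' @param consensus_matrix symmetric matrix of co-clustering fractions.
#' @return a scalar in `[0, 1]`.
#' @export
consensus_cdf_area <- function(consensus_matrix) {
  x <- sort(consensus_matrix[upper.tri(consensus_matrix)])
  n <- length(x)
  sum(diff(c(x, 1)) * seq_len(n) / n)
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of off-diagonal consensus entries strictly inside
#' `(lower, upper)`; lower PAC means cleaner clustering.
#'
#' @param consensus_matrix symmetric matrix of co-clustering fractions.
#' @param lower,upper ambiguity window bounds (defaults 0.1 and 0.9).
#' @return a scalar in `[0, 1]`.
#' @export
pac_score <- function(consensus_matrix, lower = 0.1, upper = 0.9) {
  off <- consensus_matrix[upper.tri(consensus_matrix)]
  mean(off > lower & off < upper)
}

#' Choose the number of clusters from consensus diagnostics
#'
#' Stability alone cannot prefer the true K over smaller k: when clusters are
#' well separated, every k <= K partition is perfectly stable, so the minimum
#' of PAC degenerates to the smallest candidate. `select_k` therefore scans k
#' in ascending order and accepts a larger k while (a) the gain in consensus
#' CDF area over the previous k is appreciable (`delta_min`, Monti's
#' elbow criterion) and (b) the k-cluster solution is itself clean
#' (`PAC <= pac_max`); it stops at the first k failing either condition.
#' When even the smallest candidate is unclean there is little structure:
#' the argmin-PAC k is returned (ties to the smaller k) with a
#' low-confidence warning.
#'
#' @param results a list of `ConsensusResult` objects for consecutive
#'   candidate k values.
#' @param delta_min minimum relative CDF-area gain to accept a larger k
#'   (default 0.1).
#' @param pac_max maximum PAC for a solution to count as clean (default 0.1,
#'   the lower edge of the PAC ambiguity window).
#' @return the selected k (integer).
#' @export
select_k <- function(results, delta_min = 0.1, pac_max = 0.1) {
  if (length(results) < 2) stop("select_k needs results for >= 2 candidate k")
  ks <- vapply(results, function(r) r$k, numeric(1))
  ord <- order(ks)
  ks <- ks[ord]
  pacs <- vapply(results, function(r) r$pac, numeric(1))[ord]
  areas <- vapply(results, function(r) r$cdf_area, numeric(1))[ord]
  if (pacs[1] > pac_max) {
    best <- ks[which.min(pacs)]  # which.min: first index = smallest k on ties
    if (min(pacs) > 0.5)
      warning(sprintf(
        "low-confidence k selection: minimum PAC %.3f > 0.5 (little structure)",
        min(pacs)))
    return(as.integer(best))
  }
  best <- ks[1]
  for (i in 2:length(ks)) {
    delta <- (areas[i] - areas[i - 1]) / areas[i - 1]
    if (delta < delta_min || pacs[i] > pac_max) break
    best <- ks[i]
  }
  as.integer(best)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b integer/factor vectors of equal length.
#' @return the adjusted Rand index (1 = identical up to relabeling).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
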