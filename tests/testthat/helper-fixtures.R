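# Shared fixtures, built in code. A small cohort is simulated once per test
# session; individual tests use it read-only.

toy_matrix <- function(n_genes = 5, n_samples = 4, seed = 1, scale = "counts") {
  set.seed(seed)
  v <- matrix(rpois(n_genes * n_samples, 50), n_genes, n_samples,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  ExpressionMatrix(v + 0, scale = scale)
}

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(simulation_params(n_samples = 120, seed = 42))
    cache
  }
})

# brute-force ssGSEA: literal double loop over the running-sum definition
ssgsea_naive <- function(ordered_genes, gene_set, alpha) {
  n <- length(ordered_genes)
  inset <- toupper(ordered_genes) %in% toupper(gene_set)
  denom_in <- 0
  for (i in seq_len(n)) if (inset[i]) denom_in <- denom_in + (n - i + 1)^alpha
  denom_out <- n - sum(inset)
  es <- 0
  for (i in seq_len(n)) {
    p_in <- 0; p_out <- 0
    for (j in seq_len(i)) {
      if (inset[j]) p_in <- p_in + (n - j + 1)^alpha
      else p_out <- p_out + 1
    }
    es <- es + p_in / denom_in - p_out / denom_out
  }
  es
}

# exhaustive hypergeometric upper tail by enumerating draw compositions
hyper_enum <- function(overlap, n_target, n_query, universe) {
  ks <- max(0, n_query - (universe - n_target)):min(n_query, n_target)
  probs <- vapply(ks, function(k)
    choose(n_target, k) * choose(universe - n_target, n_query - k) /
      choose(universe, n_query), numeric(1))
  sum(probs[ks >= overlap])
}

# 1-D partial likelihood (Efron ties), maximized by a coarse-then-fine grid
cox_grid_oracle <- function(x, time, event) {
  loglik <- function(beta) {
    eta <- beta * x
    ll <- 0
    for (t in unique(sort(time[event == 1]))) {
      D <- which(event == 1 & time == t)
      R <- which(time >= t)
      d <- length(D)
      sumD <- sum(exp(eta[D]))
      sumR <- sum(exp(eta[R]))
      ll <- ll + sum(eta[D])
      for (l in seq_len(d) - 1)
        ll <- ll - log(sumR - l / d * sumD)
    }
    ll
  }
  coarse <- seq(-5, 5, by = 0.01)
  b0 <- coarse[which.max(vapply(coarse, loglik, numeric(1)))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  fine[which.max(vapply(fine, loglik, numeric(1)))]
}

# exhaustive maxstat scan with survdiff as the statistic engine
maxstat_oracle <- function(score, time, event, min_group_fraction = 0.1) {
  us <- sort(unique(score))
  cands <- (us[-length(us)] + us[-1]) / 2
  n <- length(score)
  best_cut <- NA_real_
  best_stat <- -Inf
  for (cut in cands) {
    high <- score > cut
    if (sum(high) < min_group_fraction * n) next
    if (sum(!high) < min_group_fraction * n) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ high)
    z <- sqrt(sd$chisq)
    if (is.nan(z)) next
    if (z > best_stat + 1e-12) {
      best_stat <- z
      best_cut <- cut
    }
  }
  list(cutoff = best_cut, statistic = best_stat)
}
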