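make_blobs <- function(n_per, centers, sd = 1, p = 5, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(centers, function(m)
    matrix(rnorm(n_per * p, m, sd), n_per, p)))
  dimnames(X) <- list(sprintf("s%03d", seq_len(nrow(X))),
                      sprintf("g%d", seq_len(p)))
  list(em = ExpressionMatrix(t(X), "zscore"),
       truth = rep(seq_along(centers), each = n_per))
}

test_that("duplicate groups give a perfect 0/1 consensus matrix", {
  X <- rbind(matrix(rep(c(5, 5, 0, 0), each = 10), 10, 4),
             matrix(rep(c(0, 0, 5, 5), each = 10), 10, 4)) +
    matrix(rnorm(80, 0, 1e-8), 20, 4)
  dimnames(X) <- list(paste0("s", 1:20), paste0("g", 1:4))
  cc <- consensus_cluster(ExpressionMatrix(t(X), "zscore"), NULL, k = 2,
                          n_resamples = 50, seed = 4)
  truth <- rep(1:2, each = 10)
  within <- outer(truth, truth, "==")
  expect_true(all(cc$consensus_matrix[within] == 1))
  expect_true(all(cc$consensus_matrix[!within] == 0))
  expect_equal(cc$pac, 0)
})

test_that("full sampling with a deterministic base gives binary consensus", {
  b <- make_blobs(8, c(0, 6), seed = 2)
  cc <- consensus_cluster(b$em, NULL, k = 2, n_resamples = 25,
                          subsample_fraction = 1, seed = 9)
  expect_true(all(cc$consensus_matrix %in% c(0, 1)))
  expect_equal(diag(cc$consensus_matrix), rep(1, 16), ignore_attr = TRUE)
})

test_that("consensus matrix invariants hold on noisy data", {
  b <- make_blobs(15, c(0, 2.5, 5), sd = 1.5, seed = 6)
  cc <- consensus_cluster(b$em, NULL, k = 3, n_resamples = 60, seed = 1)
  cm <- cc$consensus_matrix
  expect_equal(cm, t(cm))
  expect_true(all(cm >= 0 & cm <= 1))
  expect_equal(unname(diag(cm)), rep(1, nrow(cm)))
  # every entry is the stated ratio of the two count matrices
  off <- upper.tri(cm)
  cs <- cc$co_sample_counts
  expect_true(all(cm[off][cs[off] == 0] == 0))
  expect_gte(min(cm[off] * cs[off] - floor(cm[off] * cs[off] + 0.5) + 0.5),
             0.5 - 1e-9)  # co-cluster counts are integers
  expect_true(cc$pac >= 0 && cc$pac <= 1)
})

test_that("3 well-separated blobs are recovered exactly (ARI = 1)", {
  b <- make_blobs(30, c(0, 5, 10), sd = 1, seed = 11)
  cc <- consensus_cluster(b$em, NULL, k = 3, n_resamples = 100, seed = 3)
  expect_equal(adjusted_rand_index(cc$assignments, b$truth), 1.0)
})

test_that("full-sampling consensus is invariant to sample order", {
  b <- make_blobs(10, c(0, 4), seed = 8)
  cc1 <- consensus_cluster(b$em, NULL, k = 2, n_resamples = 20,
                           subsample_fraction = 1, seed = 5)
  perm <- sample(em_samples(b$em))
  em2 <- em_subset(b$em, samples = perm)
  cc2 <- consensus_cluster(em2, NULL, k = 2, n_resamples = 20,
                           subsample_fraction = 1, seed = 5)
  ids <- em_samples(b$em)
  expect_equal(cc1$consensus_matrix[ids, ids],
               cc2$consensus_matrix[ids, ids])
})

test_that("k=2 full-sampling assignments match exhaustive WSS minimization", {
  # separated random instances, n <= 8: Ward cut equals the optimal bipartition
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:8, 1)
    truth <- sample(rep(1:2, length.out = n))
    X <- matrix(rnorm(n * 3), n, 3) + 3 * cbind(truth == 1, 0, truth == 2)
    dimnames(X) <- list(paste0("s", 1:n), paste0("g", 1:3))
    cc <- consensus_cluster(ExpressionMatrix(t(X), "zscore"), NULL, k = 2,
                            n_resamples = 5, subsample_fraction = 1, seed = s)
    # brute force over all bipartitions
    best <- NULL; best_wss <- Inf
    for (mask in 1:(2^(n - 1) - 1)) {
      g <- as.integer(intToBits(mask))[1:n]
      if (min(table(g)) < 1) next
      wss <- sum(vapply(0:1, function(lab) {
        xs <- X[g == lab, , drop = FALSE]
        sum(sweep(xs, 2, colMeans(xs))^2)
      }, numeric(1)))
      if (wss < best_wss) { best_wss <- wss; best <- g }
    }
    expect_equal(adjusted_rand_index(cc$assignments, best), 1.0)
  }
})

test_that("severity ordering renumbers clusters reproducibly", {
  b <- make_blobs(10, c(0, 5, 10), seed = 13)
  sev <- setNames(rev(seq_len(30)), em_samples(b$em))  # blob 1 most severe
  cc <- consensus_cluster(b$em, NULL, k = 3, n_resamples = 30, seed = 2,
                          severity = sev)
  means <- tapply(sev[names(cc$assignments)], cc$assignments, mean)
  expect_true(all(diff(means) > 0))  # cluster 1 lowest severity
})

test_that("select_k picks 3 on 3-blob data and warns on structureless data", {
  b <- make_blobs(25, c(0, 5, 10), seed = 21)
  res <- lapply(2:5, function(k)
    consensus_cluster(b$em, NULL, k, n_resamples = 60, seed = 14))
  expect_equal(select_k(res), 3L)
  expect_error(select_k(res[1]), ">= 2 candidate")

  set.seed(9)
  X <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(paste0("s", 1:60), paste0("g", 1:4)))
  res0 <- lapply(2:4, function(k)
    consensus_cluster(ExpressionMatrix(t(X), "zscore"), NULL, k,
                      n_resamples = 60, seed = 14))
  if (min(vapply(res0, `[[`, numeric(1), "pac")) > 0.5)
    expect_warning(select_k(res0), "low-confidence")
})

test_that("clustering errors on impossible requests", {
  b <- make_blobs(5, c(0, 5), seed = 1)
  expect_error(consensus_cluster(b$em, c("nope1", "nope2"), k = 2),
               "no clustering features")
  expect_error(consensus_cluster(b$em, NULL, k = 1), "k must be >= 2")
})
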