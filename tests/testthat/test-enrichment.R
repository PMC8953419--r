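test_that("ssgsea toy: top-2 set of 4 genes at alpha 0 scores exactly 2", {
  x <- c(a = 4, b = 3, c = 2, d = 1)
  expect_equal(ssgsea_score(x, c("a", "b"), alpha = 0), 2.0)
})

test_that("top placement is extremal and monotone transforms are neutral", {
  set.seed(6)
  x <- setNames(rnorm(20), paste0("g", 1:20))
  set_size <- 5
  top <- names(sort(x, decreasing = TRUE))[1:set_size]
  es_top <- ssgsea_score(x, top)
  # every other placement of a 5-gene set scores lower
  for (i in 1:30) {
    other <- sample(names(x), set_size)
    if (setequal(other, top)) next
    expect_lt(ssgsea_score(x, other), es_top)
  }
  # rank invariance
  expect_equal(ssgsea_score(exp(x), top), es_top)
  expect_equal(ssgsea_score(10 * x + 3, top), es_top)
})

test_that("ssgsea matches the naive double-loop oracle", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    x <- setNames(rnorm(n), paste0("g", 1:n))
    k <- sample(2:(n - 1), 1)
    gs <- sample(names(x), k)
    alpha <- sample(c(0, 0.25, 1), 1)
    ordered <- names(sort(x, decreasing = TRUE))
    expect_equal(ssgsea_score(x, gs, alpha = alpha),
                 ssgsea_naive(ordered, gs, alpha), tolerance = 1e-9)
  }
})

test_that("ssgsea guards degenerate sets", {
  x <- c(a = 3, b = 2, c = 1)
  expect_warning(s <- ssgsea_score(x, "a"), "fewer than 2")
  expect_true(is.na(s))
  expect_error(ssgsea_score(x, c("a", "b", "c")), "whole matrix")
})

test_that("enrich_collection shapes, permutation equivariance, skipping", {
  set.seed(10)
  v <- matrix(rnorm(50 * 6, 8), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  em <- ExpressionMatrix(v, "log2")
  coll <- list(S1 = paste0("g", 1:10), S2 = paste0("g", 11:15),
               BAD = c("nope", "alsono"))
  expect_warning(mat <- enrich_collection(em, coll, zscore_rows = FALSE),
                 "BAD")
  expect_equal(dim(mat), c(2L, 6L))
  # permuting samples permutes columns
  em2 <- em_subset(em, samples = rev(em_samples(em)))
  expect_warning(mat2 <- enrich_collection(em2, coll, zscore_rows = FALSE))
  expect_equal(mat2[, rev(colnames(mat))], mat[, rev(colnames(mat))])
  # duplicated sample column gives identical scores
  v3 <- cbind(v, s7 = v[, 1])
  expect_warning(mat3 <- enrich_collection(ExpressionMatrix(v3, "log2"), coll,
                                           zscore_rows = FALSE))
  expect_equal(unname(mat3[, "s7"]), unname(mat3[, "s1"]))
  expect_error(enrich_collection(em, list()), "empty")
})

test_that("til_abundance insists on 28 signatures and scores them all", {
  sim <- small_cohort()
  lg <- normalize_log(filter_low_count(sim$counts))
  gs <- suppressWarnings(fixture_gene_sets(sim$truth$genes, seed = 1))
  til <- gs[grep("^TIL_", names(gs))]
  mat <- til_abundance(lg, til, zscore_rows = FALSE)
  expect_equal(dim(mat), c(28L, 120L))
  expect_true(all(is.finite(mat)))
  expect_error(til_abundance(lg, til[1:5]), "exactly 28")
})

test_that("immune signatures score higher in the indolent cluster", {
  sim <- small_cohort()
  lg <- normalize_log(filter_low_count(sim$counts))
  gs <- suppressWarnings(fixture_gene_sets(sim$truth$genes, seed = 1))
  mat <- enrich_collection(lg, gs["role_immune"], zscore_rows = FALSE)
  cl <- sim$truth$samples$cluster
  p <- wilcox.test(mat[1, cl == 1], mat[1, cl == 3],
                   alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("tme_scores behave at extremes and under constant input", {
  set.seed(15)
  v <- matrix(rnorm(40 * 5, 8), 40, 5,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
  stromal <- paste0("g", 1:6)
  v[stromal, "s3"] <- v[stromal, "s3"] + 50  # planted stromal-high sample
  em <- ExpressionMatrix(v, "log2")
  sc <- tme_scores(em, immune_set = paste0("g", 20:26), stromal_set = stromal)
  expect_equal(rownames(sc), c("ImmuneScore", "StromaScore"))
  expect_equal(names(which.max(sc["StromaScore", ])), "s3")
  # identical expression for all samples -> constant scores
  vc <- matrix(rep(v[, 1], 5), 40, 5,
               dimnames = dimnames(v))
  scc <- tme_scores(ExpressionMatrix(vc, "log2"), paste0("g", 20:26), stromal)
  expect_equal(max(apply(scc, 1, sd)), 0)
})

test_that("groupwise tests reduce to Wilcoxon for 2 groups, detect shifts", {
  set.seed(20)
  m <- matrix(rnorm(3 * 60), 3, 60,
              dimnames = list(paste0("sig", 1:3), paste0("s", 1:60)))
  lab2 <- rep(c("a", "b"), each = 30)
  res <- groupwise_signature_test(m, lab2)
  direct <- apply(m, 1, function(x)
    wilcox.test(x[lab2 == "a"], x[lab2 == "b"], exact = FALSE)$p.value)
  expect_equal(res$p, unname(direct), tolerance = 1e-12)
  # 3 groups, planted shift of 1 sd in one group
  m3 <- matrix(rnorm(2 * 150), 2, 150,
               dimnames = list(c("shifted", "null"), paste0("s", 1:150)))
  lab3 <- rep(c("a", "b", "c"), each = 50)
  m3["shifted", lab3 == "c"] <- m3["shifted", lab3 == "c"] + 1
  res3 <- groupwise_signature_test(m3, lab3)
  expect_lt(res3$p[res3$signature == "shifted"], 0.01)
  expect_gt(res3$p[res3$signature == "null"], 0.01)
  expect_error(groupwise_signature_test(m, rep("a", 60)), ">= 2 groups")
})
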