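test_that("the shipped panel is 9 writers, 2 erasers, 13 readers, 4 negative", {
  panel <- regulator_panel()
  expect_equal(nrow(panel), 24)
  expect_equal(as.integer(table(panel$role)[c("writer", "eraser", "reader")]),
               c(9L, 2L, 13L))
  expect_setequal(panel$gene[panel$weight_sign == -1],
                  c("ALKBH5", "FTO", "ZC3H13", "IGF2BP2"))
})

test_that("weighted regulator signature is the signed z-score sum", {
  panel <- regulator_panel()
  z <- matrix(0, 24, 3, dimnames = list(panel$gene, c("s1", "s2", "s3")))
  z["METTL3", "s2"] <- 2    # +1 weight
  z["FTO", "s2"] <- 1       # -1 weight
  z[, "s3"] <- 1            # all 24 at z=1: 20 - 4 = 16
  em <- ExpressionMatrix(z, "zscore")
  sc <- weighted_regulator_signature(em, panel)
  expect_equal(unname(sc), c(0, 2 - 1, 16))
  # linearity: raising the 20 positive genes by +1 adds 20
  z2 <- z
  pos <- panel$gene[panel$weight_sign == 1]
  z2[pos, ] <- z2[pos, ] + 1
  sc2 <- weighted_regulator_signature(ExpressionMatrix(z2, "zscore"), panel)
  expect_equal(unname(sc2 - sc), rep(20, 3))
})

test_that("signature drops missing panel genes and errors when none left", {
  panel <- regulator_panel()
  z <- matrix(rnorm(4 * 2), 4, 2,
              dimnames = list(c("METTL3", "FTO", "OTHER1", "OTHER2"),
                              c("s1", "s2")))
  em <- ExpressionMatrix(z, "zscore")
  suppressMessages(sc <- weighted_regulator_signature(em, panel))
  expect_equal(unname(sc), unname(z["METTL3", ] - z["FTO", ]))
  em2 <- ExpressionMatrix(matrix(rnorm(2), 1, 2,
                                 dimnames = list("XYZ", c("s1", "s2"))),
                          "zscore")
  expect_error(suppressMessages(weighted_regulator_signature(em2, panel)),
               "no panel genes")
})

test_that("apply_m6avalue computes sum(z risk) - sum(z protective)", {
  model <- structure(list(risk_genes = "g1", protective_genes = "g2",
                          center = c(g1 = 0, g2 = 0), sd = c(g1 = 1, g2 = 1)),
                     class = "M6AvalueModel")
  v <- rbind(g1 = c(-1, 0, 1), g2 = c(0.5, 0, -0.5))
  colnames(v) <- paste0("s", 1:3)
  em <- ExpressionMatrix(v, "log2")
  st <- apply_m6avalue(model, em, standardization = "frozen")
  expect_equal(st$m6avalue, v["g1", ] - v["g2", ], ignore_attr = TRUE)
  # moving a gene from risk to protective changes scores by -2 z(gene)
  model2 <- model
  model2$risk_genes <- character(0)
  model2$protective_genes <- c("g1", "g2")
  st2 <- apply_m6avalue(model2, em, standardization = "frozen")
  expect_equal(st2$m6avalue - st$m6avalue, -2 * v["g1", ],
               ignore_attr = TRUE)
})

test_that("refit m6Avalue has mean zero and is affine invariant", {
  sim <- small_cohort()
  lg <- normalize_log(filter_low_count(sim$counts))
  suppressMessages(model <- build_m6avalue_model(
    lg, setNames(sim$truth$samples$cluster, sim$truth$samples$sample_id),
    sim$clinical$time_months, sim$clinical$event))
  sc <- apply_m6avalue(model, lg)
  expect_lt(abs(mean(sc$m6avalue)), 1e-9)
  # per-gene affine transform of expression leaves refit scores unchanged
  v <- em_values(lg)
  v2 <- v * runif(nrow(v), 0.5, 2) + rnorm(nrow(v))
  sc2 <- apply_m6avalue(model, ExpressionMatrix(v2, "log2"))
  expect_equal(sc2$m6avalue, sc$m6avalue, tolerance = 1e-9)
})

test_that("model recovery: planted prognostic genes enter with correct sign", {
  sim <- small_cohort()
  lg <- normalize_log(filter_low_count(sim$counts))
  labels <- setNames(sim$truth$samples$cluster, sim$truth$samples$sample_id)
  suppressMessages(model <- build_m6avalue_model(
    lg, labels, sim$clinical$time_months, sim$clinical$event))
  expect_s3_class(model, "M6AvalueModel")
  expect_gt(model$n_core_degs, 0)
  # no planted risk gene may appear protective, and vice versa
  expect_length(intersect(model$risk_genes, sprintf("PROT%03d", 1:30)), 0)
  planted_risk_in <- intersect(model$risk_genes, sprintf("RISK%03d", 1:50))
  expect_gt(length(planted_risk_in), 0)
  # score tracks planted aggressiveness
  sc <- apply_m6avalue(model, lg)
  rho <- cor(sc$m6avalue, sim$truth$samples$score, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("build_m6avalue_model rejects degenerate inputs", {
  sim <- small_cohort()
  lg <- normalize_log(filter_low_count(sim$counts))
  labels <- setNames(rep(1:2, length.out = 120),
                     sim$truth$samples$sample_id)
  expect_error(build_m6avalue_model(lg, labels, sim$clinical$time_months,
                                    sim$clinical$event), ">= 3 clusters")
})

test_that("stratification labels, KM separation and multivariate Cox", {
  sim <- small_cohort()
  lg <- normalize_log(filter_low_count(sim$counts))
  labels <- setNames(sim$truth$samples$cluster, sim$truth$samples$sample_id)
  suppressMessages(model <- build_m6avalue_model(
    lg, labels, sim$clinical$time_months, sim$clinical$event))
  sc <- apply_m6avalue(model, lg)
  st <- stratify_by_cutpoint(sc, sim$clinical$time_months,
                             sim$clinical$event, clinical = sim$clinical)
  expect_setequal(unique(st$scores$group), c("high", "low"))
  expect_true(all((st$scores$m6avalue > st$cutpoint$cutoff) ==
                  (st$scores$group == "high")))
  expect_lt(st$km$p, 0.01)
  expect_gt(st$auc, 0.5)
  expect_s3_class(st$cox_multivariate, "CoxFit")
  expect_equal(nrow(st$cox_multivariate), 3)  # group + grade + stage
})

test_that("drug screen: monotone, exact small-n p, and the joint rule", {
  s <- setNames(seq_len(20) + 0, paste0("c", 1:20))
  up <- data.frame(cell_line_id = names(s), compound = "mono",
                   ic50 = as.numeric(1:20))
  tab <- drug_sensitivity_screen(s, up)
  expect_equal(tab$spearman_r, 1)
  expect_true(tab$retained)
  expect_equal(tab$label, "resistant")
  # perfectly anti-monotone but n = 4: exact p = 2/24 -> not retained
  s4 <- setNames(c(1, 2, 3, 4), paste0("c", 1:4))
  anti <- data.frame(cell_line_id = names(s4), compound = "anti",
                     ic50 = c(4, 3, 2, 1))
  # pad with a 5th line lacking IC50 so the pair count is 4 after NA removal
  anti <- rbind(anti, data.frame(cell_line_id = "c5", compound = "anti",
                                 ic50 = NA))
  s5 <- c(s4, c5 = 5)
  tab4 <- suppressMessages(drug_sensitivity_screen(s5, anti))
  expect_equal(nrow(tab4), 0)  # < 5 pairs -> skipped entirely
  anti5 <- data.frame(cell_line_id = paste0("c", 1:5), compound = "anti",
                      ic50 = c(5, 4, 3, 2, 1))
  tab5 <- drug_sensitivity_screen(s5, anti5)
  expect_equal(tab5$spearman_r, -1)
  expect_equal(tab5$label, "sensitive")
  expect_equal(tab5$p, 2 / factorial(5) * 1, tolerance = 1e-9)
})

test_that("null drug screen retains about the joint false-positive level", {
  set.seed(77)
  n <- 60
  s <- setNames(rnorm(n), paste0("c", 1:n))
  tab <- do.call(rbind, lapply(1:200, function(i)
    drug_sensitivity_screen(
      s, data.frame(cell_line_id = names(s), compound = paste0("d", i),
                    ic50 = rnorm(n)))))
  expect_lt(mean(tab$retained), 0.08)  # p<0.05 & |r|>0.1 jointly
})
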