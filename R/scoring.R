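#' The default 24-gene m6A regulator panel
#'
#' Nine writers, two erasers and thirteen readers, with a fixed signature
#' weight sign: the four genes typically downregulated in tumors (ALKBH5,
#' FTO, ZC3H13, IGF2BP2) carry weight -1, the remaining twenty carry +1.
#' Shipped as an editable TSV (`inst/extdata/m6a_regulator_panel.tsv`).
#'
#' @param path optional path to an alternative panel TSV with columns
#'   `gene`, `role`, `weight_sign`.
#' @return a `data.frame` of class `RegulatorPanel`.
#' @export
regulator_panel <- function(path = NULL) {
  path <- path %||% system.file("extdata", "m6a_regulator_panel.tsv",
                                package = "m6Ascore", mustWork = TRUE)
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  stopifnot(all(c("gene", "role", "weight_sign") %in% names(df)))
  if (!all(df$role %in% c("writer", "eraser", "reader")))
    stop("panel roles must be writer/eraser/reader")
  if (!all(df$weight_sign %in% c(-1, 1)))
    stop("panel weight_sign must be +1 or -1")
  if (anyDuplicated(toupper(df$gene))) stop("duplicate genes in panel")
  class(df) <- c("RegulatorPanel", "data.frame")
  df
}

#' Weighted m6A regulator signature
#'
#' Per-sample linear z-score combination of the regulator panel:
#' `sum z(positively weighted genes) - sum z(negatively weighted genes)`.
#' Panel genes absent from the matrix are dropped with a logged count.
#'
#' @param zscore_matrix a zscore-scale [ExpressionMatrix()].
#' @param panel a `RegulatorPanel` (default: the shipped 24-gene panel).
#' @return named numeric vector of per-sample signature scores.
#' @export
weighted_regulator_signature <- function(zscore_matrix,
                                         panel = regulator_panel()) {
  present <- match_genes(zscore_matrix, panel$gene, "regulator panel")
  if (length(present) == 0) stop("no panel genes present in matrix")
  sign_by_gene <- setNames(panel$weight_sign, toupper(panel$gene))
  z <- em_values(zscore_matrix)[present, , drop = FALSE]
  as.vector(sign_by_gene[toupper(present)] %*% z) |>
    setNames(colnames(z))
}

#' Build an m6Avalue model from cluster labels and survival
#'
#' The construction pipeline: pairwise differential expression over all
#' cluster pairs, core-DEG extraction (significant in >= 2 contrasts),
#' univariate Cox screen of each core DEG on its z-scored expression, and
#' partition of the significant genes by hazard-ratio sign into risk
#' (HR > 1) and protective (HR < 1) lists. The training-cohort per-gene
#' means/sds are stored so the model can be applied frozen.
#'
#' @param expr a log2-scale [ExpressionMatrix()] (see [normalize_log()]).
#' @param cluster_labels per-sample cluster labels (>= 3 clusters), named by
#'   sample id or aligned with the matrix columns.
#' @param time,event survival data aligned with the matrix columns.
#' @param p_max Cox screen p-value cutoff (default 0.05).
#' @param fdr_max,fc_min DEG cutoffs (defaults 0.05 and 2).
#' @return list of class `M6AvalueModel`: `risk_genes`, `protective_genes`,
#'   `screen` (per-gene Cox table), `n_all_degs`, `n_core_degs`, `center`,
#'   `sd` (training standardization of the model genes).
#' @export
build_m6avalue_model <- function(expr, cluster_labels, time, event,
                                 p_max = 0.05, fdr_max = 0.05, fc_min = 2) {
  if (!is.null(names(cluster_labels)))
    cluster_labels <- cluster_labels[em_samples(expr)]
  cl <- sort(unique(cluster_labels))
  if (length(cl) < 3) stop("build_m6avalue_model needs >= 3 clusters")
  pairs <- utils::combn(cl, 2, simplify = FALSE)
  degs <- lapply(pairs, function(pr)
    pairwise_deg(expr, cluster_labels, pr[1], pr[2],
                 fdr_max = fdr_max, fc_min = fc_min))
  all_degs <- unique(unlist(lapply(degs, function(d) d$gene[d$significant])))
  core <- core_degs(degs)
  if (length(core$genes) == 0) stop("empty core-DEG set")
  m6a_log("build_m6avalue_model: %d DEGs overall, %d core DEGs",
          length(all_degs), length(core$genes))
  zm <- gene_zscore(expr)
  screen <- univariate_screen(zm, core$genes, time, event, p_max = p_max)
  model_genes <- c(screen$risk_genes, screen$protective_genes)
  if (length(model_genes) == 0) stop("no genes survive the prognostic screen")
  m6a_log("build_m6avalue_model: %d model genes (%d risk, %d protective)",
          length(model_genes), length(screen$risk_genes),
          length(screen$protective_genes))
  structure(list(
    risk_genes = screen$risk_genes,
    protective_genes = screen$protective_genes,
    screen = screen$fits,
    core_deg_counts = core$counts,
    n_all_degs = length(all_degs),
    n_core_degs = length(core$genes),
    center = zm$center[model_genes],
    sd = zm$sd[model_genes]
  ), class = "M6AvalueModel")
}

#' @export
print.M6AvalueModel <- function(x, ...) {
  cat(sprintf(
    "M6AvalueModel: %d risk + %d protective genes (from %d core DEGs)\n",
    length(x$risk_genes), length(x$protective_genes), x$n_core_degs))
  invisible(x)
}

#' Compute per-sample m6Avalue scores from a model
#'
#' `m6Avalue = sum z(risk genes) - sum z(protective genes)`. With `"refit"`
#' standardization the model genes are re-z-scored on the scored cohort
#' (appropriate for independent cohorts); `"frozen"` reuses the training
#' means/sds (strict train/test hygiene).
#'
#' @param model an `M6AvalueModel`.
#' @param expr a log2-scale (or normalized) [ExpressionMatrix()].
#' @param standardization `"refit"` (default) or `"frozen"`.
#' @return a `data.frame` of class `ScoreTable` with columns `sample_id`,
#'   `m6avalue`.
#' @export
apply_m6avalue <- function(model, expr,
                           standardization = c("refit", "frozen")) {
  standardization <- match.arg(standardization)
  model_genes <- c(model$risk_genes, model$protective_genes)
  present <- match_genes(expr, model_genes, "m6Avalue model")
  if (length(present) == 0) stop("no model genes present in matrix")
  v <- em_values(expr)[present, , drop = FALSE]
  if (standardization == "refit") {
    mu <- rowMeans(v)
    sdv <- matrixStats::rowSds(v)
    keep <- sdv > 0
    if (!all(keep)) {
      m6a_log("apply_m6avalue: %d constant model gene(s) dropped", sum(!keep))
      v <- v[keep, , drop = FALSE]; mu <- mu[keep]; sdv <- sdv[keep]
      present <- present[keep]
    }
  } else {
    mu <- model$center[present]
    sdv <- model$sd[present]
  }
  z <- (v - mu) / sdv
  w <- ifelse(toupper(present) %in% toupper(model$risk_genes), 1, -1)
  score <- as.vector(w %*% z)
  out <- data.frame(sample_id = colnames(z), m6avalue = score,
                    stringsAsFactors = FALSE)
  class(out) <- c("ScoreTable", "data.frame")
  out
}

#' Stratify a cohort by the optimal m6Avalue cutpoint
#'
#' Dichotomizes the score at the maximally selected rank-statistic cutoff,
#' then reports Kaplan-Meier curves with the log-rank test, the score's AUC
#' against the event indicator, and (when grade/stage are supplied) a
#' multivariate Cox fit of group + grade + stage. The reported log-rank p is
#' not corrected for the cutoff selection (a known optimism source).
#'
#' @param scores a `ScoreTable` from [apply_m6avalue()].
#' @param time,event survival data aligned with `scores$sample_id`.
#' @param clinical optional `ClinicalTable` with `grade` and `stage`.
#' @param min_group_fraction passed to [maxstat_cutpoint()].
#' @return list: `scores` (with a `group` column, `"high"`/`"low"`),
#'   `cutpoint`, `km`, `auc`, `cox_multivariate` (or `NULL`).
#' @export
stratify_by_cutpoint <- function(scores, time, event, clinical = NULL,
                                 min_group_fraction = 0.1) {
  cp <- maxstat_cutpoint(scores$m6avalue, time, event,
                         min_group_fraction = min_group_fraction)
  scores$group <- ifelse(scores$m6avalue > cp$cutoff, "high", "low")
  km <- km_logrank(scores$group, time, event)
  auc <- roc_auc(scores$m6avalue, event)
  cox_mv <- NULL
  if (!is.null(clinical)) {
    idx <- match(scores$sample_id, clinical$sample_id)
    covs <- data.frame(high = as.integer(scores$group == "high"),
                       grade = as.numeric(clinical$grade[idx]),
                       stage = as.numeric(clinical$stage[idx]))
    cox_mv <- cox_fit(covs, time, event)
  }
  list(scores = scores, cutpoint = cp, km = km, auc = auc,
       cox_multivariate = cox_mv)
}

#' Spearman drug-sensitivity screen against cell-line m6Avalue
#'
#' Correlates per-cell-line scores with IC50 per compound on
#' pairwise-complete data. A compound is retained iff `|r| > r_min` and
#' `p < p_max`; positive correlations (higher score, higher IC50) are labeled
#' `"resistant"`, negative ones `"sensitive"`. Compounds with fewer than 5
#' paired observations are skipped and logged.
#'
#' @param scores named numeric vector of per-cell-line scores.
#' @param drug_table a `DrugResponseTable`.
#' @param r_min absolute Spearman correlation cutoff, strict (default 0.1).
#' @param p_max p-value cutoff (default 0.05).
#' @return data.frame: compound, n, spearman_r, p, retained, label.
#' @export
drug_sensitivity_screen <- function(scores, drug_table,
                                    r_min = 0.1, p_max = 0.05) {
  stopifnot(!is.null(names(scores)))
  rows <- lapply(split(drug_table, drug_table$compound), function(d) {
    s <- scores[as.character(d$cell_line_id)]
    ok <- !is.na(s) & !is.na(d$ic50)
    if (sum(ok) < 5) {
      m6a_log("drug screen: compound %s skipped (<5 paired observations)",
              d$compound[1])
      return(NULL)
    }
    ct <- suppressWarnings(
      cor.test(s[ok], d$ic50[ok], method = "spearman"))
    r <- unname(ct$estimate)
    data.frame(compound = d$compound[1], n = sum(ok),
               spearman_r = r, p = ct$p.value,
               retained = abs(r) > r_min & ct$p.value < p_max,
               label = ifelse(r > 0, "resistant", "sensitive"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(compound = character(0), n = integer(0),
                      spearman_r = numeric(0), p = numeric(0),
                      retained = logical(0), label = character(0))
  rownames(out) <- NULL
  out
}
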