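write_tsv <- function(df, path) {
  data.table::fwrite(as.data.frame(df), path, sep = "\t")
  path
}

run_stage <- function(name, timings, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  res
}

#' Run the full m6A-pattern analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> consensus cluster ->
#' pairwise DEG + core DEGs -> m6Avalue model + scores -> survival
#' stratification -> signature enrichment -> drug screen, writing fixed-name
#' TSV outputs plus a JSON manifest with per-file MD5 hashes. A single global
#' seed is fanned out to per-stage sub-seeds (see [stage_seed()]).
#'
#' @param config a `RunConfig` (see [read_run_config()]), a path to a
#'   JSON/YAML config file, or `NULL` for defaults.
#' @param out_dir run directory (created if needed).
#' @return the run manifest, invisibly (list of class `RunManifest`).
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- if (is.character(config)) read_run_config(config)
         else if (is.null(config)) read_run_config()
         else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m6a_log_file(file.path(out_dir, "run.log"))
  on.exit(m6a_log_file(NULL))
  timings <- new.env(parent = emptyenv())
  seed <- as.integer(cfg$seed)

  # -- inputs -----------------------------------------------------------
  sim <- NULL
  if (isTRUE(cfg$simulate)) {
    inp <- run_stage("simulate", timings, function() {
      sp <- do.call(simulation_params,
                    utils::modifyList(cfg$sim %||% list(),
                                      list(seed = stage_seed(seed, 0))))
      simulate_cohort(sp)
    })
    sim <- inp
    counts <- inp$counts
    clinical <- inp$clinical
    write_expression(counts, file.path(out_dir, "counts.tsv"))
    write_tsv(clinical, file.path(out_dir, "clinical.tsv"))
    write_tsv(merge(inp$truth$samples, data.frame(), all = TRUE),
              file.path(out_dir, "truth_samples.tsv"))
    write_tsv(inp$truth$genes, file.path(out_dir, "truth_genes.tsv"))
  } else {
    counts <- read_expression(cfg$expression_path, scale = cfg$scale %||% "counts")
    clinical <- read_clinical(cfg$clinical_path)
  }

  # -- preprocess -------------------------------------------------------
  pp <- run_stage("preprocess", timings, function() {
    filtered <- filter_low_count(counts, cfg$min_count, cfg$min_fraction)
    logm <- normalize_log(filtered)
    list(log = logm, z = gene_zscore(logm))
  })

  # -- consensus clustering on the regulator panel ----------------------
  panel <- regulator_panel(cfg$panel_path %||% NULL)
  clust <- run_stage("cluster", timings, function() {
    sev <- weighted_regulator_signature(pp$z, panel)
    res <- lapply(cfg$k_range, function(k)
      consensus_cluster(pp$z, panel$gene, k,
                        n_resamples = cfg$n_resamples,
                        subsample_fraction = cfg$subsample_fraction,
                        seed = stage_seed(seed, 2), severity = sev))
    names(res) <- paste0("k", cfg$k_range)
    k_best <- select_k(res)
    best <- res[[paste0("k", k_best)]]
    write_tsv(data.frame(sample_id = names(best$assignments),
                         cluster = unname(best$assignments),
                         regulator_signature = unname(sev[names(best$assignments)])),
              file.path(out_dir, "clusters.tsv"))
    for (k in cfg$k_range)
      write_tsv(data.frame(sample_id = rownames(res[[paste0("k", k)]]$consensus_matrix),
                           res[[paste0("k", k)]]$consensus_matrix),
                file.path(out_dir, sprintf("consensus_k%d.tsv", k)))
    list(k = k_best, result = best,
         pac = vapply(res, function(r) r$pac, numeric(1)))
  })
  labels <- clust$result$assignments

  # -- differential expression ------------------------------------------
  degres <- run_stage("deg", timings, function() {
    cl <- sort(unique(labels))
    pairs <- utils::combn(cl, 2, simplify = FALSE)
    tabs <- lapply(pairs, function(pr)
      pairwise_deg(pp$log, labels, pr[1], pr[2],
                   fdr_max = cfg$deg_fdr, fc_min = cfg$deg_fc))
    all_tab <- do.call(rbind, lapply(seq_along(tabs), function(i) {
      d <- tabs[[i]]
      d$contrast <- paste(pairs[[i]], collapse = "_vs_")
      d
    }))
    write_tsv(all_tab, file.path(out_dir, "degs.tsv"))
    core <- if (length(tabs) >= 3) core_degs(tabs) else
      list(genes = character(0), counts = integer(0))
    writeLines(core$genes, file.path(out_dir, "core_degs.txt"))
    list(tables = tabs, core = core)
  })

  # -- m6Avalue model + scores ------------------------------------------
  surv_ok <- clinical$survival_ok
  time <- clinical$time_months[surv_ok]
  event <- clinical$event[surv_ok]
  sc <- run_stage("score", timings, function() {
    model <- build_m6avalue_model(pp$log, labels,
                                  clinical$time_months, clinical$event,
                                  p_max = cfg$cox_p, fdr_max = cfg$deg_fdr,
                                  fc_min = cfg$deg_fc)
    scores <- apply_m6avalue(model, pp$log, standardization = "refit")
    write_tsv(data.frame(
      gene = c(model$risk_genes, model$protective_genes),
      weight_sign = c(rep(1L, length(model$risk_genes)),
                      rep(-1L, length(model$protective_genes)))),
      file.path(out_dir, "model.tsv"))
    write_tsv(scores, file.path(out_dir, "scores.tsv"))
    list(model = model, scores = scores)
  })

  # -- survival stratification ------------------------------------------
  strat <- run_stage("survival", timings, function() {
    s <- stratify_by_cutpoint(sc$scores, clinical$time_months,
                              clinical$event, clinical = clinical)
    write_tsv(data.frame(sample_id = s$scores$sample_id,
                         m6avalue = s$scores$m6avalue, group = s$scores$group),
              file.path(out_dir, "survival.tsv"))
    write_tsv(s$km$curves, file.path(out_dir, "km.tsv"))
    writeLines(sprintf("cutoff\t%.6g\nstatistic\t%.6g\nlogrank_p\t%.6g\nauc\t%.6g",
                       s$cutpoint$cutoff, s$cutpoint$statistic, s$km$p, s$auc),
               file.path(out_dir, "cutpoint.txt"))
    s
  })

  # -- enrichment -------------------------------------------------------
  enr <- run_stage("enrich", timings, function() {
    collection <- if (!is.null(cfg$gmt_path)) read_gmt(cfg$gmt_path)
                  else if (!is.null(sim)) fixture_gene_sets(sim$truth$genes,
                                                            seed = stage_seed(seed, 6))
                  else NULL
    if (is.null(collection)) return(NULL)
    mat <- suppressWarnings(enrich_collection(pp$log, collection))
    write_tsv(data.frame(signature = rownames(mat), mat),
              file.path(out_dir, "enrichment.tsv"))
    mat
  })

  # -- drug screen ------------------------------------------------------
  drugs <- run_stage("drugs", timings, function() {
    if (isTRUE(cfg$simulate)) {
      cl_sim <- simulate_cell_lines(seed = stage_seed(seed, 7))
      cl_expr <- normalize_log(cl_sim$expr)
      cl_scores <- apply_m6avalue(sc$model, cl_expr, "refit")
      tab <- drug_sensitivity_screen(
        setNames(cl_scores$m6avalue, cl_scores$sample_id),
        cl_sim$drugs, r_min = cfg$drug_r, p_max = cfg$drug_p)
    } else if (!is.null(cfg$drug_expression_path) && !is.null(cfg$drug_path)) {
      cl_expr <- normalize_log(read_expression(cfg$drug_expression_path))
      cl_scores <- apply_m6avalue(sc$model, cl_expr, "refit")
      tab <- drug_sensitivity_screen(
        setNames(cl_scores$m6avalue, cl_scores$sample_id),
        read_drug_table(cfg$drug_path),
        r_min = cfg$drug_r, p_max = cfg$drug_p)
    } else return(NULL)
    write_tsv(tab, file.path(out_dir, "drugs.tsv"))
    tab
  })

  # -- manifest ---------------------------------------------------------
  files <- list.files(out_dir, pattern = "\\.(tsv|txt)$")
  hashes <- tools::md5sum(file.path(out_dir, files))
  names(hashes) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("m6Ascore")),
    seed = seed,
    config = cfg[setdiff(names(cfg), "sim")],
    k_selected = clust$k,
    pac = as.list(clust$pac),
    n_core_degs = length(degres$core$genes),
    model_size = length(sc$model$risk_genes) + length(sc$model$protective_genes),
    stage_timings = as.list(timings),
    file_hashes = as.list(hashes)
  )
  class(manifest) <- c("RunManifest", "list")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @return the report text, invisibly; also written to `summary.txt`.
#' @export
summarize_run <- function(run_dir) {
  mpath <- file.path(run_dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", run_dir)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  lines <- c(
    "m6Ascore run summary",
    "====================",
    sprintf("package version : %s", man$package_version),
    sprintf("seed            : %s", man$seed),
    sprintf("selected k      : %s", man$k_selected),
    sprintf("PAC by k        : %s",
            paste(sprintf("%s=%.3f", names(man$pac), unlist(man$pac)),
                  collapse = ", ")))
  cl <- file.path(run_dir, "clusters.tsv")
  if (file.exists(cl)) {
    cls <- data.table::fread(cl)
    lines <- c(lines, sprintf("cluster sizes   : %s",
                              paste(table(cls$cluster), collapse = "/")))
  }
  lines <- c(lines,
             sprintf("core DEGs       : %s", man$n_core_degs),
             sprintf("model size      : %s", man$model_size))
  cp <- file.path(run_dir, "cutpoint.txt")
  if (file.exists(cp))
    lines <- c(lines, "cutpoint/survival:",
               paste0("  ", readLines(cp)))
  dr <- file.path(run_dir, "drugs.tsv")
  if (file.exists(dr)) {
    d <- data.table::fread(dr)
    lines <- c(lines, sprintf(
      "drug screen     : %d/%d compounds retained (%d resistant, %d sensitive)",
      sum(d$retained), nrow(d),
      sum(d$retained & d$label == "resistant"),
      sum(d$retained & d$label == "sensitive")))
  } else {
    lines <- c(lines, "drug screen     : skipped")
  }
  txt <- paste(lines, collapse = "\n")
  writeLines(txt, file.path(run_dir, "summary.txt"))
  invisible(txt)
}
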