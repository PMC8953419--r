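#' Read a gene-by-sample expression table
#'
#' Expects a tab-separated file whose first column holds gene symbols and
#' whose header row holds sample ids. Duplicate gene symbols are collapsed to
#' the row with the highest mean expression (logged).
#'
#' @param path path to a TSV file.
#' @param scale declared scale of the values (see [ExpressionMatrix()]).
#' @return an [ExpressionMatrix()].
#' @export
read_expression <- function(path, scale = "counts") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0 || ncol(dt) < 2)
    stop("empty or malformed expression file: ", path)
  genes <- dt[[1]]
  vals <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(dt[, -1, with = FALSE], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(dt[[bad + 1]]))))[1]
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 genes[badrow %||% 1], names(dt)[bad + 1]))
  }
  rownames(vals) <- genes
  if (anyDuplicated(genes)) {
    means <- rowMeans(vals)
    keep <- unlist(lapply(split(seq_along(genes), genes),
                          function(ix) ix[which.max(means[ix])]))
    n_dropped <- length(genes) - length(keep)
    m6a_log("read_expression: collapsed %d duplicate gene rows by max mean",
            n_dropped)
    vals <- vals[sort(keep), , drop = FALSE]
  }
  ExpressionMatrix(vals, scale = scale)
}

#' Write an ExpressionMatrix to a tab-separated file
#'
#' @param em an [ExpressionMatrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  dt <- data.table::data.table(gene = em_genes(em), em_values(em))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member symbols. Symbols are uppercased and
#' deduplicated; descriptions are kept in the `"descriptions"` attribute.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors of class `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nms[i] <- f[1]
    desc[i] <- f[2]
    sets[[i]] <- unique(toupper(f[-(1:2)]))
  }
  names(sets) <- nms
  structure(sets, descriptions = setNames(desc, nms),
            class = c("GeneSetCollection", "list"))
}

#' Write a gene-set collection to GMT
#'
#' @param collection named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  descriptions <- descriptions %||%
    attr(collection, "descriptions") %||%
    setNames(rep("na", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", collection[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' Tab-separated with required columns `sample_id`, `time_months`, `event`,
#' `grade`, `stage`. Rows with missing time or event are retained but flagged
#' unusable for survival analysis via the logical `survival_ok` column.
#'
#' @param path path to a TSV file.
#' @return a `data.frame` of class `ClinicalTable`.
#' @export
read_clinical <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  req <- c("sample_id", "time_months", "event", "grade", "stage")
  miss <- setdiff(req, names(dt))
  if (length(miss) > 0)
    stop("clinical table missing required columns: ",
         paste(miss, collapse = ", "))
  df <- as.data.frame(dt)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table")
  bad_ev <- !is.na(df$event) & !(df$event %in% c(0, 1))
  if (any(bad_ev))
    stop("event must be 0 or 1; offending sample(s): ",
         paste(df$sample_id[bad_ev], collapse = ", "))
  bad_t <- !is.na(df$time_months) & df$time_months <= 0
  if (any(bad_t))
    stop("time_months must be > 0; offending sample(s): ",
         paste(df$sample_id[bad_t], collapse = ", "))
  df$survival_ok <- !is.na(df$time_months) & !is.na(df$event)
  n_bad <- sum(!df$survival_ok)
  if (n_bad > 0)
    m6a_log("read_clinical: %d rows lack time/event, excluded from survival ops",
            n_bad)
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Read a long-format drug response table
#'
#' Tab-separated with columns `cell_line_id`, `compound`, `ic50`
#' (missing IC50 permitted; `(cell_line, compound)` pairs must be unique).
#'
#' @param path path to a TSV file.
#' @return a `data.frame` of class `DrugResponseTable`.
#' @export
read_drug_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  req <- c("cell_line_id", "compound", "ic50")
  miss <- setdiff(req, names(dt))
  if (length(miss) > 0)
    stop("drug table missing required columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(dt)
  if (anyDuplicated(df[, c("cell_line_id", "compound")]))
    stop("duplicate (cell_line_id, compound) pairs in drug table")
  class(df) <- c("DrugResponseTable", "data.frame")
  df
}

#' Read a run configuration (JSON or YAML)
#'
#' Fills defaults for thresholds, clustering parameters and the seed, and
#' validates ranges. JSON is read with jsonlite; `.yml`/`.yaml` files require
#' the yaml package.
#'
#' @param path path to a config file, or `NULL` for all defaults.
#' @param overrides optional named list merged over the file contents.
#' @return a validated named list of class `RunConfig`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    cfg <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required for YAML configs; use JSON instead")
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  defaults <- list(
    seed = 1L,
    deg_fdr = 0.05, deg_fc = 2, cox_p = 0.05,
    drug_r = 0.1, drug_p = 0.05,
    k_range = 2:6, n_resamples = 1000, subsample_fraction = 0.8,
    min_count = 3, min_fraction = 1 / 3,
    simulate = TRUE, sim = list()
  )
  cfg <- utils::modifyList(defaults, cfg)
  cfg <- utils::modifyList(cfg, overrides)
  for (p in c("deg_fdr", "cox_p", "drug_p")) {
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1)
      stop(p, " must lie in (0, 1)")
  }
  if (cfg$n_resamples < 1) stop("n_resamples must be >= 1")
  if (cfg$subsample_fraction <= 0 || cfg$subsample_fraction > 1)
    stop("subsample_fraction must lie in (0, 1]")
  cfg$k_range <- as.integer(cfg$k_range)
  class(cfg) <- c("RunConfig", "list")
  cfg
}
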