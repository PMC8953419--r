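#' Simulation parameters for a synthetic m6A cohort
#'
#' The defaults describe the cohort structure the pipeline assumes: three
#' latent clusters (proportions mirroring a 139/39/155-style split) driven by
#' the 24-gene regulator panel, a planted per-sample aggressiveness score
#' increasing from cluster 1 to cluster 3, phenotype genes whose means rise
#' (risk) or fall (protective, immune, stroma) with that score,
#' negative-binomial counts with log-normal library sizes, and exponential
#' proportional-hazards survival with administrative censoring.
#'
#' @param n_samples cohort size (default 300).
#' @param cluster_proportions length-3 proportions summing to 1.
#' @param n_risk,n_protective,n_immune,n_stroma,n_noise planted gene counts
#'   per role (defaults 50/30/84/40/1000).
#' @param effect_regulator log2 shift of regulator means per cluster step
#'   (default 1.0).
#' @param effect_phenotype log2 shift of phenotype-gene means per unit of
#'   planted score (default 1.0).
#' @param cluster_offsets cluster means of the planted score
#'   (default -1.5, 0, 1.5).
#' @param score_sd within-cluster sd of the planted score (default 0.3).
#' @param dispersion negative-binomial dispersion phi, var = mu + phi mu^2
#'   (default 0.2).
#' @param hazard_coefficient log-hazard per unit of planted score
#'   (default 0.5).
#' @param censoring_fraction fraction censored administratively, in `[0, 1)`
#'   (default 0.5).
#' @param baseline_median_months median survival at score 0 (default 60).
#' @param lib_sigma sd of log-normal library-size factors (default 0.3).
#' @param seed integer RNG seed.
#' @return a validated list of class `SimulationParams`.
#' @export
simulation_params <- function(n_samples = 300,
                              cluster_proportions = c(0.42, 0.12, 0.46),
                              n_risk = 50, n_protective = 30,
                              n_immune = 84, n_stroma = 40, n_noise = 1000,
                              effect_regulator = 1.0, effect_phenotype = 1.0,
                              cluster_offsets = c(-1.5, 0, 1.5),
                              score_sd = 0.3, dispersion = 0.2,
                              hazard_coefficient = 0.5,
                              censoring_fraction = 0.5,
                              baseline_median_months = 60,
                              lib_sigma = 0.3, seed = 1) {
  if (abs(sum(cluster_proportions) - 1) > 1e-9)
    stop("cluster_proportions must sum to 1")
  if (length(cluster_proportions) != 3)
    stop("the simulator plants exactly 3 clusters")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop("censoring_fraction must lie in [0, 1)")
  p <- as.list(environment())
  class(p) <- c("SimulationParams", "list")
  p
}

# Per-gene baseline log2 means and role-dependent shifts; shared by the
# cohort and cell-line simulators. Returns counts matrix + truth tables.
simulate_expression <- function(params, cluster, score, sample_ids) {
  panel <- regulator_panel()
  reg_up <- panel$gene[panel$role != "eraser"]
  reg_down <- panel$gene[panel$role == "eraser"]
  roles <- c(setNames(rep("regulator-up", length(reg_up)), reg_up),
             setNames(rep("regulator-down", length(reg_down)), reg_down),
             setNames(rep("risk", params$n_risk),
                      sprintf("RISK%03d", seq_len(params$n_risk))),
             setNames(rep("protective", params$n_protective),
                      sprintf("PROT%03d", seq_len(params$n_protective))),
             setNames(rep("immune", params$n_immune),
                      sprintf("IMM%03d", seq_len(params$n_immune))),
             setNames(rep("stroma", params$n_stroma),
                      sprintf("STR%03d", seq_len(params$n_stroma))),
             setNames(rep("noise", params$n_noise),
                      sprintf("NOISE%04d", seq_len(params$n_noise))))
  genes <- names(roles)
  n_genes <- length(genes)
  n <- length(cluster)
  base <- runif(n_genes, 3, 8)  # log2 expected counts at unit library size
  u <- cluster - 2              # cluster direction -1, 0, +1
  shift <- matrix(0, n_genes, n)
  shift[roles == "regulator-up", ] <-
    matrix(params$effect_regulator * u, sum(roles == "regulator-up"), n,
           byrow = TRUE)
  shift[roles == "regulator-down", ] <-
    matrix(-params$effect_regulator * u, sum(roles == "regulator-down"), n,
           byrow = TRUE)
  for (r in c("risk", "protective", "immune", "stroma")) {
    sgn <- if (r == "risk") 1 else -1
    shift[roles == r, ] <-
      matrix(sgn * params$effect_phenotype * score, sum(roles == r), n,
             byrow = TRUE)
  }
  libf <- exp(rnorm(n, 0, params$lib_sigma))
  mu <- 2^(base + shift) %*% diag(libf)
  counts <- matrix(rnbinom(n_genes * n, mu = mu, size = 1 / params$dispersion),
                   n_genes, n, dimnames = list(genes, sample_ids))
  list(counts = ExpressionMatrix(counts, "counts"),
       gene_truth = data.frame(gene = genes, role = unname(roles),
                               stringsAsFactors = FALSE))
}

#' Simulate a synthetic tumor cohort with planted structure
#'
#' Draws cluster labels, a planted aggressiveness score, negative-binomial
#' counts with cluster-shifted regulator means and score-linked phenotype
#' genes, proportional-hazards exponential survival, administrative
#' censoring, and cluster-correlated ordinal grade/stage.
#'
#' @param params a [simulation_params()] object.
#' @return a list of class `SimulatedCohort`: `counts`
#'   (an [ExpressionMatrix()]), `clinical` (a `ClinicalTable`), `truth`
#'   (list with `samples` and `genes` data.frames), `params`.
#' @export
simulate_cohort <- function(params = simulation_params()) {
  n <- params$n_samples
  if (n < 9) stop("n_samples must be >= 3 x number of clusters (9)")
  with_seed(params$seed, {
    sample_ids <- sprintf("S%04d", seq_len(n))
    cluster <- sample(1:3, n, replace = TRUE, prob = params$cluster_proportions)
    while (min(table(factor(cluster, levels = 1:3))) < 3)
      cluster <- sample(1:3, n, replace = TRUE,
                        prob = params$cluster_proportions)
    score <- params$cluster_offsets[cluster] + rnorm(n, 0, params$score_sd)
    sim <- simulate_expression(params, cluster, score, sample_ids)
    rate0 <- log(2) / params$baseline_median_months
    t_event <- rexp(n, rate0 * exp(params$hazard_coefficient * score))
    if (params$censoring_fraction > 0) {
      cens_at <- quantile(t_event, 1 - params$censoring_fraction, names = FALSE)
      event <- as.integer(t_event <= cens_at)
      time <- pmin(t_event, cens_at)
    } else {
      event <- rep(1L, n)
      time <- t_event
    }
    grade_probs <- rbind(c(0.35, 0.30, 0.20, 0.10, 0.05),
                         c(0.20, 0.25, 0.25, 0.20, 0.10),
                         c(0.05, 0.15, 0.25, 0.30, 0.25))
    stage_probs <- rbind(c(0.45, 0.35, 0.15, 0.05),
                         c(0.30, 0.35, 0.25, 0.10),
                         c(0.10, 0.30, 0.35, 0.25))
    grade <- vapply(cluster, function(c3)
      sample(1:5, 1, prob = grade_probs[c3, ]), integer(1))
    stage <- vapply(cluster, function(c3)
      sample(1:4, 1, prob = stage_probs[c3, ]), integer(1))
    clinical <- data.frame(sample_id = sample_ids, time_months = time,
                           event = event, grade = grade, stage = stage,
                           survival_ok = TRUE, stringsAsFactors = FALSE)
    class(clinical) <- c("ClinicalTable", "data.frame")
    structure(list(
      counts = sim$counts,
      clinical = clinical,
      truth = list(
        samples = data.frame(sample_id = sample_ids, cluster = cluster,
                             score = score, stringsAsFactors = FALSE),
        genes = sim$gene_truth),
      params = params
    ), class = "SimulatedCohort")
  })
}

#' Simulate cell lines with score-linked drug response
#'
#' Expression is generated exactly as in [simulate_cohort()] (clusters,
#' planted score, negative-binomial counts) without survival; each
#' compound's IC50 is `link_strength * score + noise`, with noise variance
#' `1 - link_strength^2` so IC50 is standardized.
#'
#' @param n_lines number of cell lines (default 200).
#' @param n_compounds number of compounds (default 24).
#' @param link_strengths per-compound correlation targets in `[-1, 1]`;
#'   default: evenly spaced over `[-0.9, 0.9]`.
#' @param seed integer RNG seed.
#' @param params a [simulation_params()] for the expression model (its
#'   `n_samples` and `seed` are overridden).
#' @return list: `expr` (counts [ExpressionMatrix()]), `drugs`
#'   (`DrugResponseTable`), `truth` (samples + genes + link strengths).
#' @export
simulate_cell_lines <- function(n_lines = 200, n_compounds = 24,
                                link_strengths = NULL, seed = 1,
                                params = simulation_params()) {
  link_strengths <- link_strengths %||%
    seq(-0.9, 0.9, length.out = n_compounds)
  if (length(link_strengths) != n_compounds)
    stop("need one link strength per compound")
  if (any(abs(link_strengths) > 1))
    stop("link strengths must lie in [-1, 1]")
  with_seed(seed, {
    ids <- sprintf("CL%04d", seq_len(n_lines))
    cluster <- sample(1:3, n_lines, replace = TRUE,
                      prob = params$cluster_proportions)
    score <- params$cluster_offsets[cluster] + rnorm(n_lines, 0, params$score_sd)
    sim <- simulate_expression(params, cluster, score, ids)
    zsc <- as.vector(scale(score))
    compounds <- sprintf("drug_%02d", seq_len(n_compounds))
    drugs <- do.call(rbind, lapply(seq_len(n_compounds), function(ci) {
      rho <- link_strengths[ci]
      data.frame(cell_line_id = ids, compound = compounds[ci],
                 ic50 = rho * zsc + rnorm(n_lines, 0, sqrt(1 - rho^2)),
                 stringsAsFactors = FALSE)
    }))
    class(drugs) <- c("DrugResponseTable", "data.frame")
    list(expr = sim$counts, drugs = drugs,
         truth = list(samples = data.frame(cell_line_id = ids,
                                           cluster = cluster, score = score,
                                           stringsAsFactors = FALSE),
                      genes = sim$gene_truth,
                      link_strengths = setNames(link_strengths, compounds)))
  })
}

#' Fixture gene-set collection from simulated truth
#'
#' Emits one set per planted gene role (roles with fewer than 5 genes are
#' omitted with a warning), 28 disjoint pseudo-TIL sets partitioning a
#' subset of the immune-role genes, and 7 pseudo-immunity-step sets drawn
#' from the immune-role genes.
#'
#' @param gene_truth the `truth$genes` data.frame of a [simulate_cohort()]
#'   result (columns `gene`, `role`).
#' @param seed seed for the partition shuffle (default 1).
#' @return a named list of class `GeneSetCollection`.
#' @export
fixture_gene_sets <- function(gene_truth, seed = 1) {
  sets <- list()
  for (r in unique(gene_truth$role)) {
    g <- gene_truth$gene[gene_truth$role == r]
    if (length(g) < 5) {
      warning(sprintf("role '%s' has <5 genes; set omitted", r))
      next
    }
    sets[[paste0("role_", gsub("-", "_", r))]] <- toupper(g)
  }
  immune <- gene_truth$gene[gene_truth$role == "immune"]
  if (length(immune) >= 56) {
    with_seed(seed, {
      shuffled <- sample(immune)
      chunks <- split(shuffled, cut(seq_along(shuffled), 28, labels = FALSE))
      for (i in seq_len(28))
        sets[[sprintf("TIL_%02d", i)]] <- toupper(chunks[[i]])
      shuffled2 <- sample(immune)
      steps <- split(shuffled2, cut(seq_along(shuffled2), 7, labels = FALSE))
      for (i in seq_len(7))
        sets[[sprintf("immunity_step%d", i)]] <- toupper(steps[[i]])
    })
  } else {
    warning("fewer than 56 immune-role genes; TIL/immunity-step sets omitted")
  }
  structure(sets, descriptions = setNames(rep("synthetic fixture", length(sets)),
                                          names(sets)),
            class = c("GeneSetCollection", "list"))
}
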