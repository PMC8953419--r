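#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization (Newton-Raphson, Efron tie handling)
#' via [survival::coxph()], returning a tidy per-covariate table of Wald
#' statistics. Monotone-likelihood (perfect separation) fits are flagged.
#'
#' @param covariates numeric vector, matrix or data.frame of covariates.
#' @param time survival times (> 0).
#' @param event 0/1 event indicators.
#' @param ties tie-handling method (default `"efron"`).
#' @return a `data.frame` of class `CoxFit`: term, beta, hr, se, z, p,
#'   lower95, upper95, with attributes `n`, `n_events`, `flagged`.
#' @export
cox_fit <- function(covariates, time, event, ties = "efron") {
  X <- as.matrix(covariates)
  if (is.null(colnames(X)))
    colnames(X) <- if (ncol(X) == 1) "x" else paste0("x", seq_len(ncol(X)))
  if (!all(is.finite(X))) stop("covariates must be finite")
  if (sum(event) < 2) stop("need >= 2 events")
  consts <- matrixStats::colSds(X) == 0
  if (any(consts))
    stop("constant covariate(s): ", paste(colnames(X)[consts], collapse = ", "))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ X, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (flagged)
    m6a_log("cox_fit: monotone likelihood suspected; coefficients capped by coxph")
  s <- summary(fit)
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  out <- data.frame(
    term = colnames(X),
    beta = unname(beta),
    hr = unname(exp(beta)),
    se = unname(se),
    z = unname(beta / se),
    p = unname(2 * pnorm(-abs(beta / se))),
    lower95 = unname(exp(beta - qnorm(0.975) * se)),
    upper95 = unname(exp(beta + qnorm(0.975) * se)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n") <- s$n
  attr(out, "n_events") <- s$nevent
  attr(out, "flagged") <- flagged
  class(out) <- c("CoxFit", "data.frame")
  out
}

#' Univariate Cox screen over a gene panel
#'
#' Fits one Cox model per gene on its z-scored expression, keeps genes with
#' Wald `p < p_max`, and partitions them into risk (HR > 1) and protective
#' (HR < 1) lists. Genes with HR exactly 1 or failed fits are excluded and
#' logged.
#'
#' @param expr_zscores a zscore-scale [ExpressionMatrix()].
#' @param genes genes to screen (matched case-insensitively).
#' @param time,event survival data aligned with the matrix columns.
#' @param p_max Wald p-value cutoff (default 0.05).
#' @return list with `risk_genes`, `protective_genes` and `fits` (a
#'   per-gene `data.frame`: gene, beta, hr, se, p, retained).
#' @export
univariate_screen <- function(expr_zscores, genes, time, event, p_max = 0.05) {
  genes <- match_genes(expr_zscores, genes, "univariate screen")
  if (length(genes) == 0) stop("no screen genes present in matrix")
  v <- em_values(expr_zscores)
  rows <- lapply(genes, function(g) {
    f <- tryCatch(cox_fit(setNames(data.frame(v[g, ]), g), time, event),
                  error = function(e) NULL)
    if (is.null(f)) {
      m6a_log("univariate_screen: fit failed for %s, excluded", g)
      return(NULL)
    }
    data.frame(gene = g, beta = f$beta, hr = f$hr, se = f$se, p = f$p,
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  if (is.null(fits)) stop("all univariate fits failed")
  fits$retained <- fits$p < p_max & fits$hr != 1
  n_hr1 <- sum(fits$p < p_max & fits$hr == 1)
  if (n_hr1 > 0)
    m6a_log("univariate_screen: %d gene(s) with HR exactly 1 excluded", n_hr1)
  list(risk_genes = fits$gene[fits$retained & fits$hr > 1],
       protective_genes = fits$gene[fits$retained & fits$hr < 1],
       fits = fits)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit estimator per group plus the k-group log-rank chi-square
#' with hypergeometric variance, via [survival::survfit()] and
#' [survival::survdiff()].
#'
#' @param groups per-sample group labels.
#' @param time,event survival data.
#' @return list of class `KMResult`: `curves` (data.frame group, time, surv,
#'   n_risk, n_event), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(groups, time, event) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  if (sum(event) < 1) stop("need >= 1 event overall")
  df <- data.frame(time = time, event = event, group = groups)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(
    group = sub("^group=", "", strata),
    time = sf$time, surv = sf$surv,
    n_risk = sf$n.risk, n_event = sf$n.event,
    stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- nlevels(groups) - 1
  structure(list(curves = curves, chisq = sd$chisq, df = dfree,
                 p = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE)),
            class = "KMResult")
}

# Standardized two-group log-rank statistic (O - E) / sqrt(V) for the group
# with indicator == TRUE, computed over distinct event times.
logrank_z <- function(high, time, event) {
  ev_times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & high)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & high)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(NA_real_)
  (O - E) / sqrt(V)
}

#' Maximally selected rank-statistic cutpoint
#'
#' Evaluates the standardized two-group log-rank statistic at every candidate
#' cutoff (midpoints of consecutive distinct score values) whose induced
#' groups both hold at least `min_group_fraction` of the cohort, and returns
#' the cutoff maximizing the absolute statistic (ties: lower cutoff).
#'
#' @param score numeric per-sample score (>= 2 distinct values).
#' @param time,event survival data.
#' @param min_group_fraction minimum group size as a fraction of n
#'   (default 0.1).
#' @return list of class `CutpointResult`: `cutoff`, `statistic`
#'   (standardized, signed for the high group), `n_low`, `n_high`.
#' @export
maxstat_cutpoint <- function(score, time, event, min_group_fraction = 0.1) {
  n <- length(score)
  if (n < 10) stop("maxstat_cutpoint needs >= 10 samples")
  us <- sort(unique(score))
  if (length(us) < 2) stop("score must have >= 2 distinct values")
  cands <- (us[-length(us)] + us[-1]) / 2
  min_n <- min_group_fraction * n
  best <- NULL
  for (cut in cands) {
    high <- score > cut
    if (sum(high) < min_n || sum(!high) < min_n) next
    z <- logrank_z(high, time, event)
    if (is.na(z)) next
    if (is.null(best) || abs(z) > abs(best$statistic) + 1e-12) {
      best <- list(cutoff = cut, statistic = z,
                   n_low = sum(!high), n_high = sum(high))
    }
  }
  if (is.null(best)) stop("no admissible cutoff under the group-size constraint")
  class(best) <- "CutpointResult"
  best
}

#' Area under the ROC curve
#'
#' Rank formulation (Mann-Whitney), ties counted half.
#'
#' @param score numeric scores.
#' @param binary_outcome 0/1 labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(score, binary_outcome) {
  y <- as.integer(binary_outcome)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
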