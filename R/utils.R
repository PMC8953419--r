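#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rexp rnbinom rmultinom quantile sd cor cor.test
#'   wilcox.test kruskal.test phyper p.adjust runif setNames complete.cases
#'   as.dist hclust cutree dist median pnorm qnorm coef pchisq
#' @importFrom utils write.table head packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage sub-seed from a global seed
#'
#' A counter-based fan-out: each pipeline stage gets an independent stream so
#' adding a stage never perturbs the randomness of earlier stages. Values stay
#' below 2^31 - 1 so they are valid R integer seeds.
#'
#' @param seed integer global seed.
#' @param index non-negative integer stage counter.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index), index >= 0)
  as.integer((abs(as.numeric(seed)) + 99991 * (index + 1)) %% 2147483629 + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the caller's `.Random.seed` afterwards so library
#' code never disturbs user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Minimal run-wide logger: messages go to stderr and, when a log file has been
# registered via m6a_log_file(), are appended there with a timestamp.
.m6a_state <- new.env(parent = emptyenv())

#' Register (or clear) a log file for package messages
#'
#' @param path path to a log file, or `NULL` to disable file logging.
#' @return the previous log path, invisibly.
#' @export
m6a_log_file <- function(path = NULL) {
  old <- .m6a_state$log_file %||% NULL
  .m6a_state$log_file <- path
  invisible(old)
}

m6a_log <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (!is.null(.m6a_state$log_file %||% NULL)) {
    cat(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), msg, "\n",
        sep = "", file = .m6a_state$log_file, append = TRUE)
  }
  message(msg)
  invisible(msg)
}
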