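#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor dnbinom glm ks.test offset p.adjust pchisq
#'   pf pnorm pt qbinom rbinom rgamma rlnorm rmultinom rnbinom rnorm rpois
#'   runif t.test oneway.test dhyper fisher.test model.matrix setNames
#'   quantile var median sd aggregate
#' @importFrom utils write.table read.table head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG state; NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministic per-stage substream seeds derived from one global seed.
stage_seed <- function(seed, stage) {
  stages <- c(cohort = 1L, rdna = 2L, smallrna = 3L, report = 4L,
              refs = 5L, reads = 6L)
  if (!stage %in% names(stages)) stop("unknown stage: ", stage)
  (abs(as.integer(seed)) + 7919L * stages[[stage]]) %% 2147483647L
}

check_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi)) {
    stop(sprintf("'%s' must be numeric in [%g, %g]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

DIET_GROUPS <- c("CTCT", "CTPR", "PRCT", "PRPR")
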