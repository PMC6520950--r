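# derive a reproducible per-key seed from the master seed, so per-cancer
# results do not depend on the order cancers are processed
.deriveSeed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Best-binarized-PC statistic of one random gene set
#'
#' Samples p genes uniformly without replacement from the pool, reuses the
#' already-adjusted expression (adjustment is not recomputed), and runs the
#' full observed pipeline on them: correlation, eigendecomposition, varimax
#' rotation, per-PC sign binarization and KM logrank; returns the maximum
#' chi-squared. No univariate screening happens inside the iteration. If
#' the sampled set is degenerate (a constant vector) it is resampled once;
#' a second degenerate draw is an error.
#'
#' @param adjusted \linkS4class{AdjustedExpression} or residual matrix.
#' @param pool character, the survival gene pool to sample from.
#' @param p gene-set size (the observed number of significant genes).
#' @param time,event survival data.
#' @param mode correlation input mode.
#' @param skel internal precomputed risk-set skeleton (optional).
#' @return numeric chi-squared chi2(b).
#' @export
randomGeneStatistic <- function(adjusted, pool, p, time, event,
                                mode = c("continuous", "binarized"),
                                skel = NULL) {
  mode <- match.arg(mode)
  m <- if (is(adjusted, "AdjustedExpression")) adjusted@residuals else adjusted
  pool <- intersect(pool, rownames(m))
  if (p > length(pool)) stop("p exceeds the pool size")
  if (is.null(skel)) skel <- .survSkeleton(time, event)
  for (attempt in 1:2) {
    genes <- sample(pool, p)
    pp <- .pcPipeline(t(m[genes, , drop = FALSE]), mode)
    if (!is.null(pp)) {
      chis <- .perPCChisq(pp$scores, skel)
      if (!all(is.na(chis))) return(max(chis, na.rm = TRUE))
    }
  }
  stop("degenerate random gene set sampled twice")
}

#' Empirical p-value of the observed best binarized PC
#'
#' Draws B random same-size gene sets from the survival pool, computes each
#' set's best-binarized-PC chi-squared, and reports
#' P = #\{b : chi2(b) > chi2_obs\} / B with strict inequality exactly as
#' defined (so P = 0 is attainable); the add-one corrected
#' (#exceed + 1)/(B + 1) is carried alongside for users who need a proper
#' p-value. The observed genes are not removed from the sampling pool. P is
#' a deterministic function of the data, the seed and B; with a
#' \code{cancerCode} the stream is derived from the master seed by a keyed
#' hash so per-cancer results are order-independent.
#'
#' @param observed a \linkS4class{BestPCResult} or the observed chi-squared.
#' @param adjusted \linkS4class{AdjustedExpression} (same adjustment the
#'   observed statistic used).
#' @param pool survival gene pool (e.g. [survivalGenePool()]).
#' @param p gene-set size; defaults to the observed model's p.
#' @param time,event survival data.
#' @param B iterations (>= 1; 1000 in the reference analysis).
#' @param seed master seed.
#' @param cancerCode optional key for per-cancer stream derivation.
#' @param mode correlation input mode.
#' @return an \linkS4class{EmpiricalTestResult}.
#' @export
empiricalPvalue <- function(observed, adjusted, pool, p = NULL, time, event,
                            B = 1000L, seed = 1L, cancerCode = NULL,
                            mode = c("continuous", "binarized")) {
  mode <- match.arg(mode)
  stopifnot(B >= 1)
  if (is(observed, "BestPCResult")) {
    if (is.null(p)) p <- ncol(observed@model@loadings)
    observed <- observed@chi2
  }
  if (is.null(p)) stop("p (gene-set size) is required")
  m <- if (is(adjusted, "AdjustedExpression")) adjusted@residuals else adjusted
  pool <- intersect(pool, rownames(m))
  if (p > length(pool)) stop("p exceeds the pool size")
  useSeed <- if (is.null(cancerCode)) as.integer(seed)
             else .deriveSeed(seed, cancerCode)
  skel <- .survSkeleton(time, event)
  null <- .withSeed(useSeed, {
    vapply(seq_len(B), function(b)
      randomGeneStatistic(adjusted, pool, p, time, event, mode, skel = skel),
      numeric(1))
  })
  nexceed <- sum(null > observed)
  new("EmpiricalTestResult", observed = observed, B = as.integer(B),
      null = null, pvalue = nexceed / B, addOneP = (nexceed + 1) / (B + 1),
      seed = useSeed)
}

# evaluate expr under a local RNG state seeded with seed, restoring the
# caller's state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
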