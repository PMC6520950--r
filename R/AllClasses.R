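#' @import methods
NULL

#' The eight DNA repair pathway codes
#'
#' Pathway codes, in catalog order: direct reversal repair (DRR), base
#' excision repair (BER), non-homologous end-joining (NHEJ), mismatch repair
#' (MMR), translesion synthesis (TLS), DNA damage signaling (DDS), homologous
#' recombination repair (HRR) and nucleotide excision repair (NER). This
#' order is also the order used for first-occurrence deduplication.
#'
#' @export
PATHWAY_CODES <- c("DRR", "BER", "NHEJ", "MMR", "TLS", "DDS", "HRR", "NER")

#' PathwayCatalog: deduplicated repair-pathway gene catalog
#'
#' An ordered mapping from pathway code to gene symbols in which every gene
#' belongs to exactly one pathway (first occurrence wins), together with a
#' provenance table recording which duplicate listings were dropped.
#'
#' @slot pathways named list of character vectors, names drawn from
#'   \code{\link{PATHWAY_CODES}} and kept in catalog order.
#' @slot provenance data.frame with columns \code{gene}, \code{pathway}
#'   (pathway of first occurrence) and \code{dropped_from} (comma-separated
#'   pathways whose duplicate listings were removed; \code{""} if none).
#'
#' @seealso [loadPathwayCatalog()], [deduplicateFirstOccurrence()],
#'   [survivalGenePool()]
#' @export
setClass("PathwayCatalog",
  representation(pathways = "list", provenance = "data.frame"))

setValidity("PathwayCatalog", function(object) {
  msg <- character(0)
  nm <- names(object@pathways)
  if (is.null(nm) || any(!nzchar(nm)))
    msg <- c(msg, "pathways must be a named list")
  else {
    if (anyDuplicated(nm))
      msg <- c(msg, "duplicate pathway codes")
    bad <- setdiff(nm, PATHWAY_CODES)
    if (length(bad))
      msg <- c(msg, paste0("unknown pathway code(s): ", paste(bad, collapse = ", ")))
  }
  g <- unlist(object@pathways, use.names = FALSE)
  if (anyDuplicated(g))
    msg <- c(msg, "a gene symbol appears in more than one pathway after deduplication")
  if (!all(c("gene", "pathway", "dropped_from") %in% names(object@provenance)))
    msg <- c(msg, "provenance must have columns gene, pathway, dropped_from")
  if (length(msg)) msg else TRUE
})

#' AdjustedExpression: covariate-adjusted VDW expression residuals
#'
#' Per-gene ordinary least-squares residuals of van der Waerden (VDW)
#' expression scores regressed on VDW-transformed covariates (any of age,
#' stage, PCNA metagene). The residuals are the "new" expression values used
#' by every downstream survival step.
#'
#' @slot residuals genes x samples matrix of residuals.
#' @slot covariates samples x k matrix of the VDW covariates used (k may be 0).
#' @slot adjustFor character, subset of c("age","stage","metagene").
#' @slot coefficients genes x (k+1) matrix of regression coefficients
#'   (intercept first), kept for reporting.
#' @slot dropped character, genes dropped because their expression was
#'   constant (no ranks) in this cohort.
#'
#' @seealso [adjustExpression()], [residualize()], [vdwTransform()]
#' @export
setClass("AdjustedExpression",
  representation(residuals = "matrix", covariates = "matrix",
                 adjustFor = "character", coefficients = "matrix",
                 dropped = "character"))

setValidity("AdjustedExpression", function(object) {
  msg <- character(0)
  if (is.null(rownames(object@residuals)))
    msg <- c(msg, "residuals must have gene rownames")
  if (nrow(object@covariates) && nrow(object@covariates) != ncol(object@residuals))
    msg <- c(msg, "covariate rows must match residual columns (samples)")
  bad <- setdiff(object@adjustFor, c("age", "stage", "metagene"))
  if (length(bad))
    msg <- c(msg, paste0("unknown adjustment term(s): ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ScreenResult: per-gene Kaplan-Meier logrank screen
#'
#' @slot table data.frame with one row per tested gene: \code{gene},
#'   \code{chi2}, \code{pvalue}, group sizes \code{n0}/\code{n1}, events per
#'   group \code{events0}/\code{events1}, \code{lowEvents} flag (<5 events in
#'   either group) and \code{significant}.
#' @slot significant character, the ordered significant gene list (the
#'   "p genes" feeding the PC summarization).
#' @slot alpha numeric significance level.
#' @slot skipped character, untestable genes (constant residual or a
#'   degenerate median split).
#'
#' @seealso [screenGenes()], [kmLogrank()]
#' @export
setClass("ScreenResult",
  representation(table = "data.frame", significant = "character",
                 alpha = "numeric", skipped = "character"))

#' PCModel: varimax-rotated principal components of the significant genes
#'
#' @slot corr p x p Pearson correlation matrix of the gene vectors
#'   (continuous residuals or their median-binarized versions, see
#'   \code{mode}).
#' @slot eigenvalues numeric, descending; sums to p.
#' @slot loadings p x p varimax-rotated loading matrix (columns are PCs).
#' @slot rotation p x p orthogonal rotation applied to the unrotated
#'   loadings.
#' @slot scores samples x p PC score matrix (standardized data times rotated
#'   loadings).
#' @slot trace numeric, varimax criterion value per sweep (non-decreasing).
#' @slot iterations integer, varimax sweeps used.
#' @slot mode character, "continuous" or "binarized" correlation input.
#'
#' @seealso [fitPCModel()], [varimaxRotate()]
#' @export
setClass("PCModel",
  representation(corr = "matrix", eigenvalues = "numeric",
                 loadings = "matrix", rotation = "matrix", scores = "matrix",
                 trace = "numeric", iterations = "integer", mode = "character"))

setValidity("PCModel", function(object) {
  msg <- character(0)
  p <- nrow(object@corr)
  if (ncol(object@corr) != p) msg <- c(msg, "corr must be square")
  if (p && max(abs(object@corr - t(object@corr))) > 1e-8)
    msg <- c(msg, "corr must be symmetric")
  if (p && max(abs(diag(object@corr) - 1)) > 1e-8)
    msg <- c(msg, "corr must have unit diagonal")
  if (length(object@eigenvalues) != p)
    msg <- c(msg, "need p eigenvalues")
  else if (p && abs(sum(object@eigenvalues) - p) > 1e-6)
    msg <- c(msg, "eigenvalues must sum to p")
  if (p) {
    RtR <- crossprod(object@rotation)
    if (max(abs(RtR - diag(p))) > 1e-6)
      msg <- c(msg, "rotation must be orthogonal")
  }
  if (length(msg)) msg else TRUE
})

#' BestPCResult: the best binarized principal component
#'
#' The varimax-rotated PC whose sign-binarized score vector maximizes the
#' Kaplan-Meier logrank chi-squared for overall survival, plus the Cox PH
#' directionality fit on its continuous score.
#'
#' @slot model the \linkS4class{PCModel}.
#' @slot index integer index of the best PC (ties broken by lowest index).
#' @slot groups integer 0/1 per sample: positive score -> 1, else 0.
#' @slot chi2,pvalue logrank statistic (1 d.f.) and p-value of the best PC.
#' @slot perPCChisq chi-squared of every binarized PC (NA where degenerate).
#' @slot hr Cox proportional-hazards hazard ratio per unit of the continuous
#'   best-PC score; \code{hrCI} its 95\% Wald interval; \code{coxBeta} the
#'   log hazard ratio.
#'
#' @seealso [bestBinarizedPC()], [coxDirection()], [assignGeneDirections()]
#' @export
setClass("BestPCResult",
  representation(model = "PCModel", index = "integer", groups = "integer",
                 chi2 = "numeric", pvalue = "numeric", perPCChisq = "numeric",
                 hr = "numeric", hrCI = "numeric", coxBeta = "numeric"))

#' EmpiricalTestResult: randomization test of the best binarized PC
#'
#' Holds the observed best-binarized-PC chi-squared, the B null draws
#' obtained from random same-size repair-gene sets, and the empirical
#' p-value P = #\{b : chi2(b) > chi2_obs\} / B (strict inequality, so P = 0
#' is possible); an add-one corrected p-value (#exceed + 1)/(B + 1) is
#' reported alongside.
#'
#' @slot observed observed chi-squared.
#' @slot B integer iteration count.
#' @slot null numeric vector of B null chi-squared draws.
#' @slot pvalue empirical p-value (strict exceedance fraction).
#' @slot addOneP add-one corrected p-value.
#' @slot seed integer seed that generated the null stream.
#'
#' @seealso [empiricalPvalue()], [randomGeneStatistic()]
#' @export
setClass("EmpiricalTestResult",
  representation(observed = "numeric", B = "integer", null = "numeric",
                 pvalue = "numeric", addOneP = "numeric", seed = "integer"))

setValidity("EmpiricalTestResult", function(object) {
  msg <- character(0)
  if (length(object@null) != object@B)
    msg <- c(msg, "null distribution must hold exactly B draws")
  if (object@pvalue < 0 || object@pvalue > 1)
    msg <- c(msg, "empirical p must lie in [0,1]")
  if (length(msg)) msg else TRUE
})
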