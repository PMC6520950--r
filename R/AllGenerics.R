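#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: \code{pathways()}
#' and \code{provenance()} for \linkS4class{PathwayCatalog};
#' \code{catalogGenes()} for the flat ordered gene list; \code{pathwayOf()}
#' to map gene symbols to their pathway; \code{significantGenes()} for
#' \linkS4class{ScreenResult}; \code{bestIndex()}, \code{pcScoreMatrix()},
#' \code{bestLoadings()} for the PC objects; \code{nullDistribution()} and
#' \code{empiricalP()} for \linkS4class{EmpiricalTestResult};
#' \code{adjustedResiduals()} for \linkS4class{AdjustedExpression}.
#'
#' @param object an S4 object of this package.
#' @param ... further arguments for methods.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pathways", function(object) standardGeneric("pathways"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("catalogGenes", function(object) standardGeneric("catalogGenes"))

#' @rdname accessors
#' @export
setGeneric("pathwayOf", function(object, genes) standardGeneric("pathwayOf"))

#' @rdname accessors
#' @export
setGeneric("significantGenes", function(object) standardGeneric("significantGenes"))

#' @rdname accessors
#' @export
setGeneric("adjustedResiduals", function(object) standardGeneric("adjustedResiduals"))

#' @rdname accessors
#' @export
setGeneric("bestIndex", function(object) standardGeneric("bestIndex"))

#' @rdname accessors
#' @export
setGeneric("pcScoreMatrix", function(object) standardGeneric("pcScoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("bestLoadings", function(object) standardGeneric("bestLoadings"))

#' @rdname accessors
#' @export
setGeneric("nullDistribution", function(object) standardGeneric("nullDistribution"))

#' @rdname accessors
#' @export
setGeneric("empiricalP", function(object) standardGeneric("empiricalP"))

#' @rdname accessors
#' @export
setMethod("pathways", "PathwayCatalog", function(object) object@pathways)

#' @rdname accessors
#' @export
setMethod("provenance", "PathwayCatalog", function(object) object@provenance)

#' @rdname accessors
#' @export
setMethod("catalogGenes", "PathwayCatalog",
  function(object) unlist(object@pathways, use.names = FALSE))

#' @rdname accessors
#' @export
setMethod("pathwayOf", "PathwayCatalog", function(object, genes) {
  map <- rep(names(object@pathways), lengths(object@pathways))
  names(map) <- unlist(object@pathways, use.names = FALSE)
  genes <- toupper(trimws(genes))
  miss <- setdiff(genes, names(map))
  if (length(miss))
    stop("gene(s) not in catalog: ", paste(miss, collapse = ", "))
  unname(map[genes])
})

#' @rdname accessors
#' @export
setMethod("significantGenes", "ScreenResult", function(object) object@significant)

#' @rdname accessors
#' @export
setMethod("adjustedResiduals", "AdjustedExpression", function(object) object@residuals)

#' @rdname accessors
#' @export
setMethod("bestIndex", "BestPCResult", function(object) object@index)

#' @rdname accessors
#' @export
setMethod("pcScoreMatrix", "PCModel", function(object) object@scores)

#' @rdname accessors
#' @export
setMethod("pcScoreMatrix", "BestPCResult", function(object) object@model@scores)

#' @rdname accessors
#' @export
setMethod("bestLoadings", "BestPCResult",
  function(object) object@model@loadings[, object@index])

#' @rdname accessors
#' @export
setMethod("nullDistribution", "EmpiricalTestResult", function(object) object@null)

#' @rdname accessors
#' @export
setMethod("empiricalP", "EmpiricalTestResult", function(object) object@pvalue)

setMethod("show", "PathwayCatalog", function(object) {
  n <- lengths(object@pathways)
  cat("PathwayCatalog with", length(n), "pathway(s),",
      sum(n), "unique gene(s)\n")
  cat(paste0("  ", names(n), ": ", n, collapse = "\n"), "\n")
  nd <- sum(nzchar(object@provenance$dropped_from))
  if (nd) cat("  (", nd, " duplicate listing(s) dropped, see provenance())\n", sep = "")
})

setMethod("show", "AdjustedExpression", function(object) {
  cat("AdjustedExpression:", nrow(object@residuals), "gene(s) x",
      ncol(object@residuals), "sample(s)\n")
  cat("  adjusted for:",
      if (length(object@adjustFor)) paste(object@adjustFor, collapse = ", ")
      else "(intercept only)", "\n")
  if (length(object@dropped))
    cat("  dropped constant gene(s):", length(object@dropped), "\n")
})

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult:", nrow(object@table), "gene(s) tested at alpha =",
      object@alpha, "\n")
  cat("  significant:", length(object@significant), "gene(s)\n")
  if (length(object@skipped))
    cat("  skipped (untestable):", length(object@skipped), "\n")
})

setMethod("show", "PCModel", function(object) {
  cat("PCModel: p =", nrow(object@corr), "gene(s),", nrow(object@scores),
      "sample(s); correlation input:", object@mode, "\n")
  cat("  varimax sweeps:", object@iterations, "\n")
})

setMethod("show", "BestPCResult", function(object) {
  cat("BestPCResult: best binarized PC =", object@index, "of",
      ncol(object@model@loadings), "\n")
  cat(sprintf("  KM logrank chi2 = %.3f (p = %.4g)\n", object@chi2, object@pvalue))
  cat(sprintf("  Cox HR per score unit = %.3f [%.3f, %.3f]\n",
              object@hr, object@hrCI[1], object@hrCI[2]))
})

setMethod("show", "EmpiricalTestResult", function(object) {
  cat("EmpiricalTestResult: B =", object@B, "random gene sets\n")
  cat(sprintf("  observed chi2 = %.3f; empirical P = %.4f (add-one %.4f)\n",
              object@observed, object@pvalue, object@addOneP))
})
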