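#' Run the full survival analysis for one cohort
#'
#' The whole chain for a single cancer: covariate adjustment of the repair
#' genes (age / stage / PCNA metagene), per-gene median-binarized KM
#' logrank screen, best binarized varimax PC of the significant set, Cox
#' directionality, gene direction table with pathway composition, and the
#' randomization empirical p-value against same-size random sets from the
#' pool.
#'
#' @param expr genes x samples expression matrix (repair + signature
#'   genes), or a \code{SummarizedExperiment} from [alignCohort()].
#' @param clinical clinical data.frame (ignored for a
#'   SummarizedExperiment).
#' @param pool survival gene pool to screen and to sample random sets from.
#' @param signature proliferation signature symbols.
#' @param catalog optional \linkS4class{PathwayCatalog} for pathway
#'   annotation of the direction table.
#' @param config a [runConfig()]; \code{adjustFor} is intersected with
#'   what the cohort supports (no stage recorded -> no stage term).
#' @param cancerCode optional key for the per-cancer randomization stream.
#' @return list with elements \code{adjusted}, \code{screen}, \code{best}
#'   (NULL when no gene passes the screen), \code{directions},
#'   \code{composition}, \code{empirical} (NULL likewise).
#' @export
runSurvivalAnalysis <- function(expr, clinical = NULL, pool, signature,
                                catalog = NULL, config = runConfig(),
                                cancerCode = NULL) {
  if (is(expr, "SummarizedExperiment")) {
    clinical <- as.data.frame(SummarizedExperiment::colData(expr))
    expr <- SummarizedExperiment::assay(expr, "expr")
  }
  adjustFor <- config$adjustFor
  if ("stage" %in% adjustFor && all(is.na(clinical$stage)))
    adjustFor <- setdiff(adjustFor, "stage")
  adjusted <- adjustExpression(expr, clinical, genes = pool,
                               signature = signature, adjustFor = adjustFor)
  screen <- screenGenes(adjusted, clinical$os_months, clinical$os_event,
                        alpha = config$alpha)
  sig <- significantGenes(screen)
  if (!length(sig))
    return(list(adjusted = adjusted, screen = screen, best = NULL,
                directions = NULL, composition = NULL, empirical = NULL))
  best <- bestBinarizedPC(adjusted, sig, clinical$os_months,
                          clinical$os_event, mode = config$corrMode)
  directions <- assignGeneDirections(best, config$loadingThreshold, catalog)
  composition <- if (!is.null(catalog) && nrow(directions))
    pathwayComposition(directions, catalog) else NULL
  empirical <- empiricalPvalue(best, adjusted, pool,
                               time = clinical$os_months,
                               event = clinical$os_event,
                               B = config$B, seed = config$seed,
                               cancerCode = cancerCode,
                               mode = config$corrMode)
  list(adjusted = adjusted, screen = screen, best = best,
       directions = directions, composition = composition,
       empirical = empirical)
}
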