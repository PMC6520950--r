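#' Genomic event rates per gene-tumor
#'
#' For a gene group, counts pathogenic-flagged mutation records, homozygous
#' deletions (GISTIC score -2) and high-level amplifications (GISTIC score
#' 2) over the cohort and divides each count by (genes in group x tumors),
#' giving rates in events per gene-tumor. Heterozygous losses and low-level
#' gains (scores -1, 1) contribute nothing. By default multiple pathogenic
#' mutations in one gene-sample pair count once (\code{countMode="dedup"}),
#' keeping the rate interpretable as a gene-tumor event fraction; set
#' \code{countMode="all"} to count every record. Driver genes flagged for
#' exclusion (signature overlap) must be removed from \code{group} before
#' calling, or pass the attribute-carrying vector from [readDriverGenes()]
#' and they are removed here.
#'
#' @param events list with \code{mutations} (data.frame gene, sample,
#'   pathogenic) and \code{cna} (genes x samples GISTIC matrix), as read by
#'   [readMutations()] / [readCNA()].
#' @param group character gene vector (possibly with attribute
#'   \code{"excluded_for_ger"}).
#' @param nTumors number of tumors in the cohort.
#' @param samples optional sample ids restricting which records count.
#' @param countMode "dedup" or "all" (mutations only).
#' @return data.frame with one row per event type: \code{eventType},
#'   \code{count}, \code{nGenes}, \code{nTumors}, \code{rate}.
#' @export
computeGER <- function(events, group, nTumors, samples = NULL,
                       countMode = c("dedup", "all")) {
  countMode <- match.arg(countMode)
  stopifnot(nTumors >= 1)
  excl <- attr(group, "excluded_for_ger")
  group <- toupper(trimws(as.character(group)))
  if (!is.null(excl)) group <- setdiff(group, toupper(trimws(excl)))
  if (!length(group)) stop("empty gene group after exclusions")
  mut <- events$mutations
  mut <- mut[mut$pathogenic == 1L & mut$gene %in% group, , drop = FALSE]
  if (!is.null(samples)) mut <- mut[mut$sample %in% samples, , drop = FALSE]
  nMut <- if (countMode == "dedup")
    nrow(unique(mut[, c("gene", "sample")])) else nrow(mut)
  cna <- events$cna
  rows <- intersect(group, rownames(cna))
  cnaSub <- cna[rows, , drop = FALSE]
  if (!is.null(samples))
    cnaSub <- cnaSub[, intersect(colnames(cnaSub), samples), drop = FALSE]
  nDel <- sum(cnaSub == -2L, na.rm = TRUE)
  nAmp <- sum(cnaSub == 2L, na.rm = TRUE)
  ng <- length(group)
  data.frame(eventType = c("mutation", "deletion", "amplification"),
             count = c(nMut, nDel, nAmp),
             nGenes = ng, nTumors = nTumors,
             rate = c(nMut, nDel, nAmp) / (ng * nTumors),
             stringsAsFactors = FALSE)
}

#' GER feature matrix across cancers
#'
#' Builds the cancers x 27 rate matrix (3 event types x 9 gene groups: the
#' driver set plus the 8 repair pathways) that feeds the cluster analysis.
#'
#' @param eventsByCancer named list (cancer code -> events list as for
#'   [computeGER()]).
#' @param nTumorsByCancer named numeric, tumors per cancer.
#' @param catalog a \linkS4class{PathwayCatalog} supplying the 8 pathway
#'   groups.
#' @param drivers named list of per-cancer driver gene vectors (from
#'   [readDriverGenes()]; signature-overlap exclusions respected).
#' @param countMode see [computeGER()].
#' @return numeric matrix, rows = cancers, columns like \code{"mut_dr"},
#'   \code{"del_BER"}, \code{"amp_NER"}.
#' @export
gerFeatureMatrix <- function(eventsByCancer, nTumorsByCancer, catalog,
                             drivers, countMode = "dedup") {
  cancers <- names(eventsByCancer)
  stopifnot(!is.null(cancers), all(cancers %in% names(nTumorsByCancer)))
  groups <- pathways(catalog)
  short <- c(mutation = "mut", deletion = "del", amplification = "amp")
  rows <- lapply(cancers, function(cc) {
    gl <- c(list(dr = drivers[[cc]]), groups)
    vals <- unlist(lapply(names(gl), function(gn) {
      t <- computeGER(eventsByCancer[[cc]], gl[[gn]], nTumorsByCancer[[cc]],
                      countMode = countMode)
      stats::setNames(t$rate, paste0(short[t$eventType], "_", gn))
    }))
    vals
  })
  m <- do.call(rbind, rows)
  rownames(m) <- cancers
  m
}

#' Euclidean distance matrix between cancers
#'
#' Plain (unstandardized) Euclidean distances between the GER feature rows;
#' no feature scaling is applied. Missing features are an error.
#'
#' @param rates cancers x features numeric matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
euclideanDistanceMatrix <- function(rates) {
  if (any(!is.finite(rates))) stop("missing or non-finite feature values")
  as.matrix(stats::dist(rates, method = "euclidean"))
}

#' UPGMA clustering of cancers
#'
#' Agglomerative clustering in which the distance between clusters is the
#' unweighted arithmetic mean over all cross pairs (average linkage),
#' yielding an ultrametric tree with non-decreasing merge heights.
#'
#' @param dist symmetric distance matrix (or \code{dist} object) over at
#'   least two leaves.
#' @return an \code{hclust} object.
#' @export
upgmaCluster <- function(dist) {
  if (is.matrix(dist)) {
    if (nrow(dist) != ncol(dist) || max(abs(dist - t(dist))) > 1e-12)
      stop("distance matrix must be symmetric")
    if (nrow(dist) < 2L) stop("need at least two leaves")
    dist <- stats::as.dist(dist)
  }
  stats::hclust(dist, method = "average")
}

#' Serialize a dendrogram as Newick
#'
#' @param hc an \code{hclust} tree (e.g. from [upgmaCluster()]).
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogramNewick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
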