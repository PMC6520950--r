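#' Correlation matrix of the significant genes
#'
#' Pearson correlation matrix of the p significant gene vectors. Mode
#' "continuous" (default) correlates the adjusted residuals; mode
#' "binarized" correlates their median-binarized 0/1 versions (the
#' workflow-diagram variant). A constant vector is an error naming the
#' gene.
#'
#' @param x samples x p matrix (columns are genes).
#' @param mode "continuous" or "binarized".
#' @return p x p correlation matrix.
#' @export
correlationMatrix <- function(x, mode = c("continuous", "binarized")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), ncol(x) >= 1L)
  if (mode == "binarized")
    x <- apply(x, 2, medianBinarize)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant gene vector(s): ",
         paste(colnames(x)[sds == 0] %||% which(sds == 0), collapse = ", "))
  stats::cor(x)
}

#' Eigendecomposition with a deterministic sign convention
#'
#' Eigenvalues in descending order, unit-norm eigenvectors, and each
#' eigenvector's largest-magnitude element made positive (eigenvectors are
#' only defined up to sign; the convention makes results reproducible).
#'
#' @param corr symmetric matrix (correlation matrix of the gene set).
#' @return list with \code{values} and \code{vectors}.
#' @export
eigenDecompose <- function(corr) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8) stop("matrix is not symmetric")
  e <- eigen(corr, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- rownames(corr)
  list(values = e$values, vectors = V)
}

# varimax criterion: sum over columns of the variance of squared loadings
.varimaxCriterion <- function(L) {
  p <- nrow(L)
  sum(colSums(L^4) / p - (colSums(L^2) / p)^2)
}

#' Varimax orthogonal rotation
#'
#' Iteratively maximizes the varimax simplicity criterion (sum of
#' per-column variances of squared loadings) over orthogonal rotations,
#' with Kaiser row normalization, using the SVD-based update. Convergence
#' when the criterion gain falls below \code{eps} (default 1e-6) or after
#' \code{maxIter} sweeps, in which case the best iterate is returned with a
#' warning. The criterion trace is recorded and non-decreasing; rotation
#' preserves per-row communalities and total variance.
#'
#' @param L p x k loading matrix (typically eigenvectors scaled by the
#'   square roots of their eigenvalues).
#' @param normalize apply Kaiser normalization (rows scaled to unit
#'   communality during rotation).
#' @param eps convergence tolerance on the criterion gain.
#' @param maxIter maximum sweeps.
#' @return list with \code{loadings} (rotated), \code{rotation}
#'   (orthogonal k x k), \code{trace} (criterion per sweep),
#'   \code{iterations}.
#' @export
varimaxRotate <- function(L, normalize = TRUE, eps = 1e-6, maxIter = 1000L) {
  stopifnot(is.matrix(L))
  p <- nrow(L); k <- ncol(L)
  if (k < 2L)
    return(list(loadings = L, rotation = diag(1, k),
                trace = .varimaxCriterion(L), iterations = 0L))
  h <- if (normalize) sqrt(rowSums(L^2)) else rep(1, p)
  h[h == 0] <- 1
  x <- L / h
  R <- diag(k)
  trace <- .varimaxCriterion(x)
  bestR <- R
  bestV <- trace
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    B <- x %*% R
    G <- crossprod(x, B^3 - B %*% diag(drop(colSums(B^2)) / p, k))
    s <- svd(G)
    R <- s$u %*% t(s$v)
    v <- .varimaxCriterion(x %*% R)
    gain <- v - trace[length(trace)]
    trace <- c(trace, v)
    if (v > bestV) { bestV <- v; bestR <- R }
    if (gain < eps) { converged <- TRUE; break }
  }
  if (!converged)
    warning("varimax did not converge in ", maxIter, " sweeps; returning best iterate")
  R <- bestR
  rot <- (x %*% R) * h
  dimnames(rot) <- dimnames(L)
  list(loadings = rot, rotation = R, trace = trace, iterations = it)
}

#' PC scores from rotated loadings
#'
#' Scores are the standardized data times the rotated loading matrix.
#' Because the data columns are centered, every score column has mean zero.
#'
#' @param z samples x p standardized data matrix (columns mean 0, sd 1).
#' @param loadings p x k rotated loading matrix.
#' @return samples x k score matrix.
#' @export
pcScores <- function(z, loadings) {
  if (ncol(z) != nrow(loadings))
    stop("dimension mismatch between data columns and loading rows")
  z %*% loadings
}

# full PC pipeline on a residual submatrix (samples x p), shared by the
# observed analysis and the randomization iterations. Returns NULL parts
# lazily to stay cheap inside loops.
.pcPipeline <- function(x, mode) {
  M <- if (mode == "binarized") apply(x, 2, medianBinarize) else x
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) return(NULL)  # degenerate sampled set
  Z <- scale(M)
  C <- crossprod(Z) / (nrow(Z) - 1)
  C <- (C + t(C)) / 2
  e <- eigenDecompose(C)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), ncol(C))
  rownames(L) <- colnames(x)
  vr <- varimaxRotate(L)
  S <- Z %*% vr$loadings
  list(corr = C, values = e$values, loadings = vr$loadings,
       rotation = vr$rotation, scores = S, trace = vr$trace,
       iterations = vr$iterations)
}

# binarize scores (positive -> 1, zero and negative -> 0) and return the
# per-PC logrank chi2 (NA where a group is empty)
.perPCChisq <- function(scores, skel) {
  vapply(seq_len(ncol(scores)), function(j) {
    g <- as.integer(scores[, j] > 0)
    if (all(g == 0L) || all(g == 1L)) return(NA_real_)
    .logrankChisq(g, skel)
  }, numeric(1))
}

#' Cox proportional-hazards directionality of a PC score
#'
#' Univariate Cox PH fit (Efron ties) of survival on the continuous PC
#' score; the hazard ratio per unit score and its 95\% Wald interval
#' determine whether positive scores shorten (HR > 1) or prolong (HR < 1)
#' overall survival. Negating the score maps HR to 1/HR exactly.
#'
#' @param time,event survival months and 0/1 status.
#' @param score continuous, non-constant score vector.
#' @return list with \code{hr}, \code{ci} (length 2), \code{beta},
#'   \code{se}, \code{pvalue}.
#' @export
coxDirection <- function(time, event, score) {
  if (sum(event) < 1) stop("no events: Cox fit undefined")
  if (stats::sd(score) == 0) stop("constant score")
  fit <- survival::coxph(survival::Surv(time, event) ~ score,
                         ties = "efron")
  beta <- unname(stats::coef(fit))
  if (!is.finite(beta)) stop("Cox fit did not converge")
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  list(hr = exp(beta), ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       beta = beta, se = se,
       pvalue = 2 * stats::pnorm(-abs(beta / se)))
}

#' Fit the varimax-rotated PC model of a gene set
#'
#' Correlation matrix, eigendecomposition, loadings (eigenvectors scaled by
#' sqrt eigenvalues), varimax rotation and PC scores for the given genes of
#' an adjusted expression object.
#'
#' @param adjusted \linkS4class{AdjustedExpression} or genes x samples
#'   matrix.
#' @param genes gene symbols (rows) to include, in order.
#' @param mode correlation input mode, see [correlationMatrix()].
#' @return a \linkS4class{PCModel}.
#' @export
fitPCModel <- function(adjusted, genes = NULL,
                       mode = c("continuous", "binarized")) {
  mode <- match.arg(mode)
  m <- if (is(adjusted, "AdjustedExpression")) adjusted@residuals else adjusted
  if (is.null(genes)) genes <- rownames(m)
  miss <- setdiff(genes, rownames(m))
  if (length(miss)) stop("gene(s) not adjusted: ", paste(miss, collapse = ", "))
  x <- t(m[genes, , drop = FALSE])
  pp <- .pcPipeline(x, mode)
  if (is.null(pp)) stop("degenerate gene set: constant vector after binarization")
  new("PCModel", corr = pp$corr, eigenvalues = pp$values,
      loadings = pp$loadings, rotation = pp$rotation, scores = pp$scores,
      trace = pp$trace, iterations = as.integer(pp$iterations), mode = mode)
}

#' Select the best binarized principal component
#'
#' Every rotated PC score vector is binarized (positive values to 1, zero
#' and negative to 0) and tested with the KM logrank test; the PC with the
#' greatest chi-squared is the "best binarized PC" (ties broken by lowest
#' PC index). Its continuous score is then passed to Cox PH regression for
#' survival directionality. PCs whose binarization empties a group are
#' skipped; if all are degenerate this is an error.
#'
#' @param adjusted \linkS4class{AdjustedExpression} or residual matrix.
#' @param genes the p significant gene symbols.
#' @param time,event survival months and 0/1 status.
#' @param mode correlation input mode.
#' @return a \linkS4class{BestPCResult}.
#' @export
bestBinarizedPC <- function(adjusted, genes, time, event,
                            mode = c("continuous", "binarized")) {
  mode <- match.arg(mode)
  model <- fitPCModel(adjusted, genes, mode)
  skel <- .survSkeleton(time, event)
  chis <- .perPCChisq(model@scores, skel)
  if (all(is.na(chis))) stop("all binarized PCs are degenerate")
  idx <- which.max(chis)        # NA-safe: which.max ignores NA; ties -> lowest
  groups <- as.integer(model@scores[, idx] > 0)
  cox <- coxDirection(time, event, model@scores[, idx])
  new("BestPCResult", model = model, index = as.integer(idx),
      groups = groups, chi2 = chis[idx],
      pvalue = stats::pchisq(chis[idx], 1, lower.tail = FALSE),
      perPCChisq = chis, hr = cox$hr, hrCI = cox$ci, coxBeta = cox$beta)
}

#' Per-gene survival directionality from the best binarized PC
#'
#' A gene prolongs OS when upregulated iff the sign of its loading on the
#' best binarized PC is opposite to the sign of the Cox log hazard ratio:
#' with HR < 1 (positive scores protective), positively loading genes are
#' beneficial upregulated; with HR > 1, positively loading genes must be
#' downregulated to be beneficial. Jointly flipping the PC's sign (loadings
#' and scores) leaves every direction unchanged. Genes with |loading| below
#' the threshold are omitted. HR exactly 1 leaves directions undefined and
#' is an error.
#'
#' @param best a \linkS4class{BestPCResult}.
#' @param threshold minimum absolute loading (default 0.4).
#' @param catalog optional \linkS4class{PathwayCatalog} to annotate each
#'   gene's pathway.
#' @return data.frame with columns \code{gene}, \code{loading},
#'   \code{direction} ("upregulation-prolongs-OS" or
#'   "downregulation-prolongs-OS") and, with a catalog, \code{pathway}.
#' @export
assignGeneDirections <- function(best, threshold = 0.4, catalog = NULL) {
  if (best@hr == 1) stop("HR = 1: survival directionality undefined")
  l <- bestLoadings(best)
  keep <- abs(l) >= threshold
  l <- l[keep]
  beneficialUp <- sign(l) * sign(best@coxBeta) < 0
  out <- data.frame(gene = names(l), loading = unname(l),
                    direction = ifelse(beneficialUp,
                                       "upregulation-prolongs-OS",
                                       "downregulation-prolongs-OS"),
                    stringsAsFactors = FALSE)
  if (!is.null(catalog)) out$pathway <- pathwayOf(catalog, out$gene)
  rownames(out) <- NULL
  out
}

#' Pathway percentage composition of a direction table
#'
#' For each survival direction, the percentage of its gene list falling in
#' each repair pathway, to one decimal. Percentages within a direction sum
#' to 100 up to rounding. A gene absent from the catalog is an error.
#'
#' @param directions data.frame from [assignGeneDirections()] (or any with
#'   \code{gene} and \code{direction} columns); alternatively a character
#'   vector of genes treated as a single direction.
#' @param catalog a \linkS4class{PathwayCatalog}.
#' @return data.frame with columns \code{direction}, \code{pathway},
#'   \code{n}, \code{percent}.
#' @examples
#' cat123 <- loadPathwayCatalog(repairPathwaysFile())
#' pathwayComposition(c("CUL4A", "POLQ"), cat123)  # NER 50.0, TLS 50.0
#' @export
pathwayComposition <- function(directions, catalog) {
  if (is.character(directions))
    directions <- data.frame(gene = directions, direction = "all",
                             stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "direction") %in% names(directions)))
  out <- lapply(split(directions$gene, directions$direction), function(g) {
    pw <- pathwayOf(catalog, g)
    tab <- table(factor(pw, levels = names(pathways(catalog))))
    tab <- tab[tab > 0]
    data.frame(pathway = names(tab), n = as.integer(tab),
               percent = round(100 * as.integer(tab) / length(g), 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, Map(function(d, df) cbind(direction = d, df),
                            names(out), out))
  rownames(res) <- NULL
  res
}
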