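#' Van der Waerden (VDW) rank-normal scores
#'
#' Maps a vector to standard-normal quantiles of its percentiles:
#' \eqn{Z_i = \Phi^{-1}(r_i/(n+1))} with midranks for ties. The
#' \eqn{r/(n+1)} percentile scheme keeps the extremes finite and yields
#' scores with mean exactly zero (by symmetry) and variance slightly below
#' one, approaching one as n grows. The transform depends only on ranks, so
#' any strictly monotone transform of the input (for example a log) yields
#' identical scores.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return numeric vector of VDW scores.
#' @examples
#' vdwTransform(c(10, 20, 30))  # middle value maps to qnorm(0.5) = 0
#' @export
vdwTransform <- function(x) {
  if (anyNA(x) || any(!is.finite(x)))
    stop("VDW transform needs complete finite input")
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L)
    stop("VDW transform undefined for a constant vector")
  stats::qnorm(rank(x, ties.method = "average") / (n + 1))
}

#' PCNA proliferation metagene
#'
#' Per-sample median of raw normalized expression across the signature
#' genes present in the matrix (a proxy for tumor proliferation). Absent
#' signature genes are counted and reported with a message; the median is
#' taken over those present. The metagene is computed on the raw expression
#' scale and VDW-transformed later when used as a regression covariate.
#'
#' @param expr genes x samples matrix.
#' @param signature character vector of signature gene symbols.
#' @return numeric vector, one value per sample.
#' @export
computeMetagene <- function(expr, signature) {
  signature <- unique(toupper(trimws(signature)))
  present <- intersect(signature, rownames(expr))
  if (!length(present))
    stop("no signature genes present in the expression matrix")
  absent <- length(signature) - length(present)
  if (absent) message(absent, " signature gene(s) absent from the matrix")
  apply(expr[present, , drop = FALSE], 2, stats::median)
}

.STAGE_SUB <- c(A = 0.1, B = 0.2, C = 0.3)

.parseStageKey <- function(labels) {
  s <- toupper(trimws(labels))
  s <- sub("^STAGE", "", s)
  s <- gsub("[[:space:]]", "", s)
  m <- regmatches(s, regexec("^(IV|III|II|I)([ABC])?$", s))
  key <- vapply(m, function(g) {
    if (!length(g)) return(NA_real_)
    base <- c(I = 1, II = 2, III = 3, IV = 4)[g[2]]
    base + if (nzchar(g[3])) .STAGE_SUB[g[3]] else 0
  }, numeric(1))
  key
}

#' Encode pathological stage as ordinal ranks
#'
#' Normalizes stage labels ("Stage IIIA", "IIIA", "iii a", ...) and encodes
#' them as midranks ordered I < II < III < IV with sub-stages A < B < C
#' within each stage. The ranks are then suitable for VDW transformation.
#' Missing labels stay missing; unrecognized labels are an error listing
#' the offenders.
#'
#' @param labels character vector of stage labels.
#' @return numeric vector of midranks (NA where the label was missing).
#' @examples
#' encodeStage(c("I", "II", "II", "IV"))  # 1, 2.5, 2.5, 4
#' @export
encodeStage <- function(labels) {
  key <- .parseStageKey(labels)
  bad <- !is.na(labels) & nzchar(trimws(labels)) & is.na(key)
  if (any(bad))
    stop("unrecognized stage label(s): ",
         paste(unique(labels[bad]), collapse = ", "))
  out <- rep(NA_real_, length(key))
  ok <- !is.na(key)
  out[ok] <- rank(key[ok], ties.method = "average")
  out
}

.checkCollinear <- function(X, names) {
  if (ncol(X) < 2L) return(invisible())
  C <- suppressWarnings(stats::cor(X))
  C[!is.finite(C)] <- 0
  diag(C) <- 0
  if (any(abs(C) > 1 - 1e-10)) {
    ij <- which(abs(C) > 1 - 1e-10, arr.ind = TRUE)[1, ]
    stop("collinear covariates: ", names[ij[1]], " and ", names[ij[2]])
  }
  invisible()
}

#' Residualize a vector on covariates by OLS
#'
#' Ordinary least-squares residuals of \code{y} on an intercept plus the
#' given covariates; with an empty covariate list this is mean-centering.
#' Residuals are orthogonal to every covariate (correlation below 1e-8).
#' Exactly collinear covariates are an error naming the offending pair.
#'
#' @param y numeric response (typically VDW scores of one gene).
#' @param covariates list (or matrix columns) of numeric covariate vectors,
#'   same length as \code{y}.
#' @return numeric residual vector; regression coefficients in attribute
#'   \code{"coefficients"}.
#' @export
residualize <- function(y, covariates = list()) {
  if (is.matrix(covariates)) covariates <- as.data.frame(covariates)
  stopifnot(all(vapply(covariates, length, 1L) == length(y)))
  X <- cbind(`(Intercept)` = rep(1, length(y)),
             do.call(cbind, covariates))
  if (ncol(X) > 1L)
    .checkCollinear(X[, -1, drop = FALSE],
                    colnames(X)[-1] %||% paste0("cov", seq_len(ncol(X) - 1)))
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(fit$residuals, coefficients = fit$coefficients)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# residualize many response rows on one shared design; returns list(res, coef)
.residualizeMatrix <- function(Y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  res <- t(qr.resid(qrX, t(Y)))
  coef <- t(qr.coef(qrX, t(Y)))
  dimnames(res) <- dimnames(Y)
  rownames(coef) <- rownames(Y)
  colnames(coef) <- colnames(X)
  list(res = res, coef = coef)
}

#' Adjust repair-gene expression for age, stage and the PCNA metagene
#'
#' The full adjustment chain: each repair gene's expression is VDW
#' rank-normalized and regressed on the VDW scores of the chosen covariates
#' (age at diagnosis; ordinal-encoded pathological stage; the PCNA
#' metagene, computed first on raw expression and then VDW-transformed).
#' Residuals are the new, proliferation/confounder-free expression values.
#' Genes with constant expression are dropped with a warning.
#'
#' @param expr genes x samples expression matrix, or a
#'   \code{SummarizedExperiment} from [alignCohort()] (assay \code{"expr"},
#'   clinical columns in \code{colData}).
#' @param clinical data.frame with columns \code{age_years}, \code{stage};
#'   ignored when \code{expr} is a SummarizedExperiment.
#' @param genes gene symbols to adjust (default: all rows of \code{expr}
#'   when a plain matrix; required pool recommended).
#' @param signature proliferation signature symbols for the metagene
#'   (needed when "metagene" is in \code{adjustFor}).
#' @param adjustFor subset of c("age","stage","metagene"). Use
#'   [autoAdjustSet()] to pick \{age, metagene\} or \{age, stage, metagene\}
#'   from stage availability.
#' @return an \linkS4class{AdjustedExpression}.
#' @export
adjustExpression <- function(expr, clinical = NULL, genes = NULL,
                             signature = NULL,
                             adjustFor = c("age", "stage", "metagene")) {
  if (is(expr, "SummarizedExperiment")) {
    clinical <- as.data.frame(SummarizedExperiment::colData(expr))
    expr <- SummarizedExperiment::assay(expr, "expr")
  }
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  adjustFor <- match.arg(adjustFor, several.ok = TRUE)
  if (anyNA(expr))
    stop("expression has missing values; run imputeExpression() first")
  if (is.null(genes)) genes <- rownames(expr)
  genes <- intersect(toupper(trimws(genes)), rownames(expr))
  if (!length(genes)) stop("none of the requested genes are in the matrix")

  n <- ncol(expr)
  covs <- list()
  if ("age" %in% adjustFor) {
    stopifnot(!anyNA(clinical$age_years))
    covs$age <- vdwTransform(clinical$age_years)
  }
  if ("stage" %in% adjustFor) {
    if (all(is.na(clinical$stage)))
      stop("stage adjustment requested but no stage labels available")
    covs$stage <- vdwTransform(encodeStage(clinical$stage))
  }
  if ("metagene" %in% adjustFor) {
    if (is.null(signature)) stop("metagene adjustment needs a signature")
    covs$metagene <- vdwTransform(computeMetagene(expr, signature))
  }
  Xcov <- if (length(covs)) do.call(cbind, covs) else
    matrix(numeric(0), nrow = n, ncol = 0)
  if (length(covs)) .checkCollinear(Xcov, names(covs))

  Y <- expr[genes, , drop = FALSE]
  ok <- apply(Y, 1, function(v) length(unique(v)) > 1L)
  if (any(!ok))
    warning("dropped constant gene(s): ", paste(genes[!ok], collapse = ", "))
  Y <- Y[ok, , drop = FALSE]
  if (!nrow(Y)) stop("no non-constant genes to adjust")
  Z <- t(apply(Y, 1, vdwTransform))
  dimnames(Z) <- dimnames(Y)
  X <- cbind(`(Intercept)` = rep(1, n), Xcov)
  fit <- .residualizeMatrix(Z, X)
  new("AdjustedExpression", residuals = fit$res, covariates = Xcov,
      adjustFor = adjustFor, coefficients = fit$coef,
      dropped = genes[!ok])
}

#' Choose the adjustment set from stage availability
#'
#' Cohorts without recorded pathological stage are adjusted for age and the
#' PCNA metagene; cohorts with stage additionally for stage.
#'
#' @param clinical data.frame with a \code{stage} column.
#' @return character vector of adjustment terms.
#' @export
autoAdjustSet <- function(clinical) {
  if (all(is.na(clinical$stage))) c("age", "metagene")
  else c("age", "stage", "metagene")
}

#' Pearson correlation of adjusted genes with the metagene
#'
#' One Pearson r per gene between its adjusted (or any) expression vector
#' and the metagene vector; the genes x cancers collection of these columns
#' is the heat-map input relating repair genes to proliferation. A
#' zero-variance residual yields NA rather than an error.
#'
#' @param adjusted an \linkS4class{AdjustedExpression} or a genes x samples
#'   matrix.
#' @param metagene numeric per-sample metagene vector.
#' @return named numeric vector of correlations in [-1, 1].
#' @export
correlateWithMetagene <- function(adjusted, metagene) {
  m <- if (is(adjusted, "AdjustedExpression")) adjusted@residuals else adjusted
  stopifnot(ncol(m) == length(metagene))
  apply(m, 1, function(v) {
    if (stats::sd(v) == 0 || stats::sd(metagene) == 0) return(NA_real_)
    stats::cor(v, metagene)
  })
}
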