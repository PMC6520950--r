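#' Read a cBioPortal-style expression matrix
#'
#' Tab-delimited, first column the gene symbol, header row of sample
#' identifiers, values normalized (non-negative) RNA-Seq expression.
#' Duplicate gene rows are collapsed to the first occurrence with a warning;
#' empty cells and "NA" become missing values. Ragged rows and files with
#' zero sample columns are format errors.
#'
#' @param path file path.
#' @return numeric matrix, genes (uppercased symbols) x samples.
#' @seealso [writeExpression()], [alignCohort()]
#' @export
readExpression <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "#")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in expression file: ", path)
  d <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("expression file has zero sample columns: ", path)
  genes <- toupper(trimws(as.character(d[[1]])))
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("duplicate gene row(s) collapsed to first occurrence: ",
            paste(dup, collapse = ", "))
    keep <- !duplicated(genes)
    m <- m[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(m) <- genes
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (any(!is.finite(m) & !is.na(m))) stop("non-finite expression values")
  m
}

#' Write an expression matrix in the dialect readExpression() consumes
#'
#' @param mat genes x samples numeric matrix with dimnames.
#' @param path output path.
#' @param geneColumn header for the first column.
#' @return invisibly, \code{path}.
#' @export
writeExpression <- function(mat, path, geneColumn = "Hugo_Symbol") {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  d <- data.frame(rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- geneColumn
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.parseOsStatus <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("1", "DECEASED", "1:DECEASED", "DEAD")] <- 1L
  out[x %in% c("0", "LIVING", "0:LIVING", "ALIVE")] <- 0L
  bad <- unique(x[is.na(out) & nzchar(x) & x != "NA"])
  if (length(bad))
    stop("unknown survival status token(s): ", paste(bad, collapse = ", "))
  out
}

.findColumn <- function(nms, candidates, required = TRUE, what = candidates[1]) {
  i <- which(tolower(nms) %in% candidates)
  if (!length(i)) {
    if (required) stop("clinical table lacks a ", what, " column")
    return(NA_integer_)
  }
  i[1]
}

#' Read a clinical table
#'
#' TSV with named columns. Sample id, overall-survival months and status
#' columns are required; age, stage and cancer code are optional (some
#' cohorts have no recorded stage). Status accepts the 0/1, LIVING/DECEASED
#' and 0:LIVING/1:DECEASED dialects. Rows with negative survival time are
#' rejected with a message, not an error.
#'
#' @param path file path.
#' @return data.frame with columns \code{sample}, \code{os_months},
#'   \code{os_event}, \code{age_years}, \code{stage} (raw label or NA),
#'   \code{cancer_code} (or NA).
#' @export
readClinical <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  nms <- names(d)
  si <- .findColumn(nms, c("sample", "sample_id", "patient_id", "id"), what = "sample id")
  ti <- .findColumn(nms, c("os_months", "os_time", "overall_survival_months"),
                    what = "os_months")
  ei <- .findColumn(nms, c("os_event", "os_status", "status"), what = "os_status")
  ai <- .findColumn(nms, c("age", "age_years", "age_at_diagnosis"), required = FALSE)
  gi <- .findColumn(nms, c("stage", "ajcc_pathologic_tumor_stage", "pathologic_stage"),
                    required = FALSE)
  ci <- .findColumn(nms, c("cancer_code", "cancer", "study"), required = FALSE)
  out <- data.frame(
    sample = trimws(as.character(d[[si]])),
    os_months = as.numeric(d[[ti]]),
    os_event = .parseOsStatus(d[[ei]]),
    age_years = if (!is.na(ai)) as.numeric(d[[ai]]) else NA_real_,
    stage = if (!is.na(gi)) {
      s <- trimws(as.character(d[[gi]])); s[!nzchar(s) | toupper(s) == "NA"] <- NA
      s
    } else NA_character_,
    cancer_code = if (!is.na(ci)) as.character(d[[ci]]) else NA_character_,
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample)) stop("duplicate sample ids in clinical table")
  neg <- !is.na(out$os_months) & out$os_months < 0
  if (any(neg)) {
    message("rejected ", sum(neg), " record(s) with negative survival time")
    out <- out[!neg, , drop = FALSE]
  }
  out
}

#' Write a clinical table
#' @param clin data.frame as returned by [readClinical()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeClinical <- function(clin, path) {
  utils::write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read somatic mutation records
#'
#' Only gene, sample and pathogenicity columns are consumed (the
#' pathogenicity flag is an input, e.g. a FATHMM call made upstream).
#'
#' @param path TSV with columns gene, sample, pathogenic (0/1 or
#'   TRUE/FALSE).
#' @return data.frame with columns \code{gene}, \code{sample},
#'   \code{pathogenic} (integer 0/1).
#' @export
readMutations <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  nms <- tolower(names(d))
  gi <- which(nms %in% c("gene", "hugo_symbol"))[1]
  si <- which(nms %in% c("sample", "sample_id", "tumor_sample_barcode"))[1]
  pi <- which(nms %in% c("pathogenic", "fathmm", "is_pathogenic"))[1]
  if (any(is.na(c(gi, si, pi))))
    stop("mutation table needs gene, sample and pathogenic columns")
  p <- d[[pi]]
  p <- if (is.logical(p)) as.integer(p) else as.integer(as.numeric(p))
  if (any(!p %in% c(0L, 1L))) stop("pathogenic flag must be binary")
  data.frame(gene = toupper(trimws(d[[gi]])), sample = trimws(d[[si]]),
             pathogenic = p, stringsAsFactors = FALSE)
}

#' Read a discrete (GISTIC-scored) copy-number matrix
#'
#' Same layout as the expression matrix; values must be in
#' \{-2, -1, 0, 1, 2\}. A deletion event is a score of -2 (homozygous
#' loss), an amplification a score of 2 (high-level gain); -1 and 1 are
#' carried but never counted as events.
#'
#' @param path file path.
#' @return integer matrix, genes x samples.
#' @export
readCNA <- function(path) {
  m <- readExpression(path)
  v <- m[!is.na(m)]
  if (any(!v %in% -2:2))
    stop("copy-number values must be GISTIC scores in {-2,-1,0,1,2}")
  storage.mode(m) <- "integer"
  m
}

#' Median-impute or drop genes with missing expression
#'
#' VDW ranking needs complete vectors. Genes missing in more than
#' \code{maxMissing} of samples are dropped (with a message); remaining
#' missing cells are imputed with the gene's median.
#'
#' @param mat genes x samples matrix.
#' @param maxMissing maximum tolerated missing fraction per gene.
#' @return complete matrix (possibly fewer rows).
#' @export
imputeExpression <- function(mat, maxMissing = 0.2) {
  frac <- rowMeans(is.na(mat))
  if (any(frac > maxMissing)) {
    message("dropped ", sum(frac > maxMissing),
            " gene(s) with >", round(100 * maxMissing), "% missing values")
    mat <- mat[frac <= maxMissing, , drop = FALSE]
  }
  na <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(na)) {
    med <- apply(mat, 1, stats::median, na.rm = TRUE)
    mat[na] <- med[na[, 1]]
  }
  mat
}

#' Align expression and clinical data into a cohort
#'
#' Intersects the samples present in both tables, drops samples missing any
#' required covariate (with a message), imputes or drops genes with missing
#' expression, and returns a \code{SummarizedExperiment} with the expression
#' assay and the clinical columns as \code{colData}. An empty intersection
#' is an error. Alignment never invents samples.
#'
#' @param expr genes x samples matrix from [readExpression()].
#' @param clinical data.frame from [readClinical()].
#' @param requireCovariates character subset of c("age","stage"); samples
#'   missing one of these are dropped. Survival time and status are always
#'   required.
#' @param maxMissing per-gene missing-fraction tolerance, see
#'   [imputeExpression()].
#' @return a \code{SummarizedExperiment} (assay \code{"expr"}).
#' @export
alignCohort <- function(expr, clinical, requireCovariates = "age",
                        maxMissing = 0.2) {
  stopifnot(all(requireCovariates %in% c("age", "stage")))
  common <- intersect(colnames(expr), clinical$sample)
  if (!length(common)) stop("no samples shared between expression and clinical data")
  dropped <- (ncol(expr) - length(common)) + (nrow(clinical) - length(common))
  clin <- clinical[match(common, clinical$sample), , drop = FALSE]
  ok <- !is.na(clin$os_months) & !is.na(clin$os_event)
  if ("age" %in% requireCovariates) ok <- ok & !is.na(clin$age_years)
  if ("stage" %in% requireCovariates) ok <- ok & !is.na(clin$stage)
  if (any(!ok))
    message("dropped ", sum(!ok), " sample(s) with missing survival data or covariates")
  if (dropped)
    message("dropped ", dropped, " sample(s) absent from one of the tables")
  clin <- clin[ok, , drop = FALSE]
  if (!nrow(clin)) stop("no samples left after alignment")
  m <- imputeExpression(expr[, clin$sample, drop = FALSE], maxMissing)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = m),
    colData = S4Vectors::DataFrame(clin, row.names = clin$sample))
}

#' Run configuration
#'
#' Validated bundle of the analysis knobs: the adjustment set, the KM
#' significance level, the randomization iteration count B, the master
#' seed, the correlation-input mode and the loading threshold for
#' direction tables.
#'
#' @param adjustFor subset of c("age","stage","metagene").
#' @param alpha significance level in (0,1).
#' @param B randomization iterations, >= 1.
#' @param seed integer master seed.
#' @param corrMode "continuous" (residuals) or "binarized".
#' @param loadingThreshold minimum |loading| for direction tables.
#' @param paths optional named list of input file paths.
#' @return list with class \code{"runConfig"}.
#' @export
runConfig <- function(adjustFor = c("age", "stage", "metagene"), alpha = 0.05,
                      B = 1000, seed = 1L, corrMode = c("continuous", "binarized"),
                      loadingThreshold = 0.4, paths = list()) {
  corrMode <- match.arg(corrMode)
  stopifnot(all(adjustFor %in% c("age", "stage", "metagene")),
            alpha > 0, alpha < 1, B >= 1, loadingThreshold >= 0)
  structure(list(adjustFor = adjustFor, alpha = alpha, B = as.integer(B),
                 seed = as.integer(seed), corrMode = corrMode,
                 loadingThreshold = loadingThreshold, paths = paths),
            class = "runConfig")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [runConfig()] arguments (\code{adjust} is accepted as an
#' alias of \code{adjustFor}; a comma-separated string is split).
#'
#' @param path YAML file.
#' @return a \code{runConfig}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$adjust) && is.null(y$adjustFor)) y$adjustFor <- y$adjust
  y$adjust <- NULL
  if (is.character(y$adjustFor) && length(y$adjustFor) == 1L)
    y$adjustFor <- trimws(strsplit(y$adjustFor, ",")[[1]])
  known <- names(formals(runConfig))
  do.call(runConfig, y[intersect(names(y), known)])
}

#' Write a result table with a reproducibility header
#'
#' Writes tab-separated values preceded by \code{#}-comment lines recording
#' the seed and configuration used, so every emitted table is traceable.
#'
#' @param x data.frame.
#' @param path output path.
#' @param config optional \code{runConfig} whose seed/settings go in the
#'   header.
#' @return invisibly, \code{path}.
#' @export
writeResultTable <- function(x, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(sprintf("# seed: %d", config$seed), con)
    writeLines(sprintf("# alpha: %g; B: %d; adjustFor: %s; corrMode: %s",
                       config$alpha, config$B,
                       paste(config$adjustFor, collapse = ","),
                       config$corrMode), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
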