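#' Load a repair-pathway gene catalog from a gene-set file
#'
#' Reads pathway gene sets from either a GMT file (set name, description,
#' genes...) or a two-column TSV (\code{pathway}, \code{gene}) and builds a
#' deduplicated \linkS4class{PathwayCatalog}. Symbols are matched
#' case-insensitively after trimming; aliases are not resolved. Genes listed
#' in more than one pathway are kept only at their first occurrence, taking
#' pathways in the order they appear in the file (the packaged catalog uses
#' DRR, BER, NHEJ, MMR, TLS, DDS, HRR, NER order); dropped listings are
#' recorded in \code{provenance()}.
#'
#' The packaged catalog (the 8 repair pathways and their 123 unique genes)
#' is at \code{repairPathwaysFile()}.
#'
#' @param path path to a GMT or two-column TSV gene-set file.
#' @return a \linkS4class{PathwayCatalog}.
#' @examples
#' cat123 <- loadPathwayCatalog(repairPathwaysFile())
#' length(catalogGenes(cat123))  # 123
#' @export
loadPathwayCatalog <- function(path) {
  raw <- readGeneSets(path)
  bad <- setdiff(names(raw), PATHWAY_CODES)
  if (length(bad))
    stop("unknown pathway code(s): ", paste(bad, collapse = ", "))
  if (any(lengths(raw) == 0))
    stop("empty pathway: ", paste(names(raw)[lengths(raw) == 0], collapse = ", "))
  deduplicateFirstOccurrence(raw)
}

#' Read gene sets from a GMT or two-column TSV file
#'
#' A line with three or more tab-separated fields is treated as GMT
#' (name, description, genes...); otherwise the file must be a two-column
#' TSV mapping set name to gene, with an optional header row. A set name
#' appearing on two separate GMT lines is a format error (in the TSV dialect
#' consecutive rows of one set are the normal encoding, but a set whose rows
#' are interleaved with another set's is rejected as a duplicate listing).
#'
#' @param path file path.
#' @return named list of character gene vectors, in file order; symbols
#'   uppercased and trimmed.
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene-set file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  clean <- function(x) toupper(trimws(x))
  if (all(nf >= 3)) {                     # GMT
    nm <- vapply(fields, function(f) trimws(f[1]), "")
    if (anyDuplicated(nm))
      stop("duplicate set listed twice: ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
    sets <- lapply(fields, function(f) clean(f[-(1:2)]))
    names(sets) <- nm
  } else {                                # two-column TSV
    if (any(nf != 2))
      stop("gene-set TSV must have exactly two columns (pathway, gene)")
    m <- do.call(rbind, fields)
    if (tolower(m[1, 1]) %in% c("pathway", "set", "name"))
      m <- m[-1, , drop = FALSE]
    code <- trimws(m[, 1])
    # reject a set whose rows re-start after another set began (double listing)
    runs <- rle(code)$values
    if (anyDuplicated(runs))
      stop("duplicate set listed twice: ",
           paste(unique(runs[duplicated(runs)]), collapse = ", "))
    sets <- split(clean(m[, 2]), factor(code, levels = unique(code)))
    sets <- lapply(sets, unname)
  }
  sets
}

#' First-occurrence deduplication of pathway gene lists
#'
#' Genes listed under several pathways (or twice within one pathway) are
#' kept only at their first occurrence, scanning pathways in list order and
#' genes in within-pathway order. Every dropped listing is recorded in the
#' catalog's provenance. The operation is idempotent.
#'
#' @param raw named list of character gene vectors (pathway -> genes),
#'   possibly with repeats; names must be pathway codes
#'   (\code{\link{PATHWAY_CODES}}).
#' @return a \linkS4class{PathwayCatalog}.
#' @examples
#' dedup <- deduplicateFirstOccurrence(list(BER = c("PCNA", "LIG1"),
#'                                          HRR = "LIG1"))
#' pathways(dedup)$HRR  # character(0): LIG1 stays in BER
#' @export
deduplicateFirstOccurrence <- function(raw) {
  stopifnot(is.list(raw), !is.null(names(raw)))
  raw <- lapply(raw, function(g) toupper(trimws(g)))
  seen <- character(0)
  kept <- vector("list", length(raw))
  names(kept) <- names(raw)
  dropped <- list()
  for (pw in names(raw)) {
    g <- raw[[pw]]
    new <- !(g %in% seen) & !duplicated(g)
    kept[[pw]] <- g[new]
    if (any(!new))
      dropped[[pw]] <- unique(g[!new])
    seen <- c(seen, g[new])
  }
  first <- rep(names(kept), lengths(kept))
  names(first) <- unlist(kept, use.names = FALSE)
  prov <- data.frame(gene = names(first), pathway = unname(first),
                     dropped_from = "", stringsAsFactors = FALSE)
  if (length(dropped)) {
    for (pw in names(dropped))
      for (g in dropped[[pw]]) {
        i <- match(g, prov$gene)
        prov$dropped_from[i] <- if (nzchar(prov$dropped_from[i]))
          paste(prov$dropped_from[i], pw, sep = ",") else pw
      }
  }
  new("PathwayCatalog", pathways = kept, provenance = prov)
}

#' Exclusion rules for the survival gene pool
#'
#' By default PCNA (the proliferation gene whose genome-wide co-regulation
#' the adjustment removes) and TP53 (a near-universal driver) are excluded
#' globally from survival analysis; per-cancer driver-overlap exclusions can
#' be supplied in addition.
#'
#' @param always character, symbols always excluded from survival analysis.
#' @param perCancer named list (cancer code -> character) of additional
#'   per-cancer exclusions, e.g. repair genes that double as that cancer's
#'   drivers.
#' @return a list with class \code{"exclusionRules"}.
#' @export
exclusionRules <- function(always = c("PCNA", "TP53"), perCancer = list()) {
  structure(list(always = toupper(trimws(always)),
                 perCancer = lapply(perCancer, function(x) toupper(trimws(x)))),
            class = "exclusionRules")
}

#' Survival-analysis gene pool
#'
#' The catalog genes minus the exclusion rules: the packaged 123-gene
#' catalog minus PCNA and TP53 yields the 121-gene pool used for survival
#' screening and as the sampling pool of the randomization test. Order is
#' catalog order. Exclusion symbols absent from the catalog produce a
#' warning, not an error.
#'
#' @param catalog a \linkS4class{PathwayCatalog}.
#' @param rules an \code{\link{exclusionRules}} object.
#' @param cancerCode optional cancer code selecting per-cancer exclusions.
#' @return character vector of gene symbols.
#' @examples
#' pool <- survivalGenePool(loadPathwayCatalog(repairPathwaysFile()))
#' length(pool)  # 121
#' @export
survivalGenePool <- function(catalog, rules = exclusionRules(),
                             cancerCode = NULL) {
  stopifnot(is(catalog, "PathwayCatalog"))
  genes <- catalogGenes(catalog)
  excl <- rules$always
  if (!is.null(cancerCode) && cancerCode %in% names(rules$perCancer))
    excl <- c(excl, rules$perCancer[[cancerCode]])
  excl <- unique(excl)
  absent <- setdiff(excl, genes)
  if (length(absent))
    warning("exclusion symbol(s) not in catalog: ",
            paste(absent, collapse = ", "))
  setdiff(genes, excl)
}

#' Paths to packaged gene-set fixtures
#'
#' \code{repairPathwaysFile()}: the 8-pathway / 123-gene repair catalog.
#' \code{rawRepairPathwaysFile()}: a synthetic pre-deduplication variant in
#' which the 12 genes known to be multiply listed (POLD1, POLE, POLH, POLM,
#' WRN, PCNA, LIG1, BLM, BRCA1, FANCA, FANCC, ERCC4) appear a second time;
#' the second placements are invented, hence the synthetic label.
#' \code{pcnaSignatureFile()}: a synthetic 131-symbol stand-in for the
#' PCNA-correlated proliferation signature (the real signature is a
#' supplementary object not bundled here); its symbols are what the
#' synthetic cohort generator uses.
#' \code{driverGenesFile()}: synthetic per-cancer driver lists (<= 20 genes).
#' \code{cancerManifestFile()}: the 18-cancer manifest with per-cancer stage
#' availability.
#'
#' @return a file path.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
repairPathwaysFile <- function()
  system.file("extdata", "repair_pathways.tsv", package = "repairSurv",
              mustWork = TRUE)

#' @rdname fixtures
#' @export
rawRepairPathwaysFile <- function()
  system.file("extdata", "repair_pathways_raw_synthetic.tsv",
              package = "repairSurv", mustWork = TRUE)

#' @rdname fixtures
#' @export
pcnaSignatureFile <- function()
  system.file("extdata", "pcna_signature_synthetic.gmt",
              package = "repairSurv", mustWork = TRUE)

#' @rdname fixtures
#' @export
driverGenesFile <- function()
  system.file("extdata", "driver_genes_synthetic.gmt",
              package = "repairSurv", mustWork = TRUE)

#' @rdname fixtures
#' @export
cancerManifestFile <- function()
  system.file("extdata", "cancer_manifest.tsv", package = "repairSurv",
              mustWork = TRUE)

#' Read the PCNA proliferation signature gene set
#'
#' @param path a GMT file whose first set is the signature; defaults to the
#'   packaged synthetic stand-in.
#' @return character vector of unique gene symbols, with the source
#'   description attached as attribute \code{"source_threshold"}.
#' @export
readMetageneSignature <- function(path = pcnaSignatureFile()) {
  lines <- readLines(path, warn = FALSE)
  f <- strsplit(lines[nzchar(lines)][1], "\t", fixed = TRUE)[[1]]
  if (length(f) < 3) stop("signature file must be GMT")
  genes <- unique(toupper(trimws(f[-(1:2)])))
  if (!length(genes)) stop("empty signature")
  attr(genes, "source_threshold") <- f[2]
  genes
}

#' Read per-cancer driver gene lists
#'
#' @param path GMT file, one set per cancer code; defaults to the packaged
#'   synthetic stand-in.
#' @param signature optional character vector; drivers also present in the
#'   proliferation signature are recorded in attribute
#'   \code{"excluded_for_ger"} per cancer (they are removed before genomic
#'   event-rate computation).
#' @return named list of character vectors.
#' @export
readDriverGenes <- function(path = driverGenesFile(), signature = NULL) {
  sets <- readGeneSets(path)
  toolong <- names(sets)[lengths(sets) > 20]
  if (length(toolong))
    warning("driver list(s) longer than 20 genes: ",
            paste(toolong, collapse = ", "))
  lapply(sets, function(g) {
    g <- unique(g)
    if (!is.null(signature))
      attr(g, "excluded_for_ger") <- intersect(g, toupper(trimws(signature)))
    g
  })
}

#' Read the cancer manifest
#'
#' @param path TSV with columns cancer_code, cancer_name, has_stage;
#'   defaults to the packaged 18-cancer manifest.
#' @return data.frame.
#' @export
readCancerManifest <- function(path = cancerManifestFile()) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cancer_code", "cancer_name", "has_stage") %in% names(m)))
  m$has_stage <- as.logical(m$has_stage)
  m
}
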