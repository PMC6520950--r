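#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates the generative model's parameters. The generator
#' emulates the data structure the survival pipeline assumes: a latent
#' proliferation factor co-regulating a metagene block (and, configurably,
#' the repair genes), age and stage confounding, proportional-hazards
#' survival carried by a planted gene subset, right-censoring, and
#' per-gene mutation / deletion / amplification tables.
#'
#' Mediation modes: \code{"residual-signal"} plants a survival effect
#' (\code{beta} per SD) on a latent residual component u carried by the
#' planted genes, on top of the proliferation effect — the scenario in
#' which adjustment must NOT remove significance; \code{"fully-mediated"}
#' sets beta = 0 so survival depends on proliferation f only — adjustment
#' should then remove all signal; \code{"null"} removes both effects.
#'
#' @param nSamples cohort size.
#' @param repairGenes repair gene symbols (default: the packaged 121-gene
#'   survival pool).
#' @param metageneGenes proliferation signature symbols (default: the
#'   packaged synthetic 131-gene signature).
#' @param prolifLoading loading of each metagene gene on f, in [0,1].
#' @param repairProlifLoading loading of each repair gene on f.
#' @param plantedGenes number (taken from the head of \code{repairGenes})
#'   or symbols of the genes carrying the residual signal.
#' @param signalLoading loading of planted genes on the residual component
#'   u.
#' @param beta per-SD log hazard of u (active in residual-signal mode).
#' @param prolifLogHazard per-SD log hazard of f.
#' @param ageEffect log hazard per year of age (centered at 60).
#' @param stageEffect log hazard per ordinal stage step (centered at II).
#' @param stageProbs stage I..IV probabilities; ignored when
#'   \code{hasStage = FALSE}.
#' @param hasStage whether the cohort records pathological stage.
#' @param stageProlifCoupling how strongly stage shifts f (confounding).
#' @param baselineRate exponential baseline hazard, per month.
#' @param censoringRate target fraction censored, in [0,1).
#' @param mediationMode "residual-signal", "fully-mediated" or "null".
#' @param eventProbs per-group event probabilities: a list with elements
#'   \code{repair} and \code{driver}, each a named vector with
#'   \code{mutation}, \code{deletion}, \code{amplification}.
#' @param driverGenes driver symbols for the event tables.
#' @param seed integer seed; the cohort is bit-identical for a fixed seed.
#' @return list with class \code{"simulationConfig"}.
#' @export
simulationConfig <- function(nSamples = 400,
                             repairGenes = NULL,
                             metageneGenes = NULL,
                             prolifLoading = 0.8,
                             repairProlifLoading = 0.4,
                             plantedGenes = 10,
                             signalLoading = 0.8,
                             beta = 0.5,
                             prolifLogHazard = 0.5,
                             ageEffect = 0.02,
                             stageEffect = 0.3,
                             stageProbs = c(0.3, 0.3, 0.25, 0.15),
                             hasStage = TRUE,
                             stageProlifCoupling = 0.15,
                             baselineRate = 0.01,
                             censoringRate = 0.6,
                             mediationMode = c("residual-signal",
                                               "fully-mediated", "null"),
                             eventProbs = list(
                               repair = c(mutation = 0.02, deletion = 0.005,
                                          amplification = 0.01),
                               driver = c(mutation = 0.15, deletion = 0.02,
                                          amplification = 0.05)),
                             driverGenes = NULL,
                             seed = 1L) {
  mediationMode <- match.arg(mediationMode)
  if (is.null(repairGenes))
    repairGenes <- survivalGenePool(loadPathwayCatalog(repairPathwaysFile()))
  if (is.null(metageneGenes))
    metageneGenes <- as.character(readMetageneSignature())
  if (is.null(driverGenes))
    driverGenes <- as.character(readDriverGenes()[[1]])
  if (is.numeric(plantedGenes) && length(plantedGenes) == 1L)
    plantedGenes <- utils::head(repairGenes, plantedGenes)
  stopifnot(nSamples >= 10,
            all(plantedGenes %in% repairGenes),
            prolifLoading >= 0, prolifLoading <= 1,
            repairProlifLoading >= 0, repairProlifLoading <= 1,
            signalLoading >= 0, signalLoading <= 1,
            censoringRate >= 0, censoringRate < 1,
            baselineRate > 0,
            abs(sum(stageProbs) - 1) < 1e-8,
            all(unlist(eventProbs) >= 0), all(unlist(eventProbs) <= 1))
  if (repairProlifLoading^2 + signalLoading^2 > 1)
    stop("repairProlifLoading^2 + signalLoading^2 must not exceed 1")
  structure(list(nSamples = as.integer(nSamples), repairGenes = repairGenes,
                 metageneGenes = metageneGenes, prolifLoading = prolifLoading,
                 repairProlifLoading = repairProlifLoading,
                 plantedGenes = plantedGenes, signalLoading = signalLoading,
                 beta = beta, prolifLogHazard = prolifLogHazard,
                 ageEffect = ageEffect, stageEffect = stageEffect,
                 stageProbs = stageProbs, hasStage = hasStage,
                 stageProlifCoupling = stageProlifCoupling,
                 baselineRate = baselineRate, censoringRate = censoringRate,
                 mediationMode = mediationMode, eventProbs = eventProbs,
                 driverGenes = driverGenes, seed = as.integer(seed)),
            class = "simulationConfig")
}

.STAGE_LABELS <- c("I", "II", "III", "IV")

#' Simulate a TCGA-like cohort
#'
#' Draws a latent proliferation factor f ~ N(0,1) per sample (shifted by
#' stage to create confounding), expresses each metagene gene as
#' lambda f + noise and each repair gene as rho f (+ delta u for planted
#' genes) + noise on a latent normal scale that is exponentiated to mimic
#' non-negative normalized RNA-Seq values (the rank-based VDW transform
#' makes this marginal choice immaterial downstream). Survival times are
#' exponential proportional hazards with linear predictor
#' beta u + gamma f + age and stage terms; administrative censoring at the
#' empirical quantile of the time distribution hits the target censoring
#' rate. Event tables are Bernoulli draws per gene-sample with the
#' configured per-group probabilities.
#'
#' @param config a [simulationConfig()].
#' @return list of class \code{"syntheticCohort"} with elements
#'   \code{expr} (genes x samples), \code{clinical}, \code{events}
#'   (mutations + cna), \code{truth} (latent f and u, true effects,
#'   planted genes, event probabilities) and \code{config}.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  .withSeed(config$seed, {
    n <- config$nSamples
    samples <- sprintf("S%04d", seq_len(n))

    age <- pmax(20, stats::rnorm(n, 60, 10))
    stageNum <- if (config$hasStage)
      sample(1:4, n, replace = TRUE, prob = config$stageProbs) else rep(NA, n)
    stageLabel <- if (config$hasStage) {
      sub <- sample(c("", "A", "B"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
      paste0(.STAGE_LABELS[stageNum], sub)
    } else NA_character_

    f <- stats::rnorm(n)
    if (config$hasStage)
      f <- f + config$stageProlifCoupling * (stageNum - mean(stageNum))
    u <- stats::rnorm(n)

    lam <- config$prolifLoading
    nm <- length(config$metageneGenes)
    metaLatent <- lam * matrix(f, nm, n, byrow = TRUE) +
      sqrt(1 - lam^2) * matrix(stats::rnorm(nm * n), nm, n)

    rho <- config$repairProlifLoading
    del <- config$signalLoading
    nr <- length(config$repairGenes)
    planted <- config$repairGenes %in% config$plantedGenes
    loadU <- ifelse(planted, del, 0)
    noiseSD <- sqrt(pmax(0, 1 - rho^2 - loadU^2))
    repairLatent <- rho * matrix(f, nr, n, byrow = TRUE) +
      loadU * matrix(u, nr, n, byrow = TRUE) +
      noiseSD * matrix(stats::rnorm(nr * n), nr, n)

    expr <- exp(rbind(repairLatent, metaLatent))
    rownames(expr) <- c(config$repairGenes, config$metageneGenes)
    colnames(expr) <- samples

    beta <- if (config$mediationMode == "residual-signal") config$beta else 0
    gamma <- if (config$mediationMode == "null") 0 else config$prolifLogHazard
    lp <- beta * u + gamma * f + config$ageEffect * (age - 60)
    if (config$hasStage) lp <- lp + config$stageEffect * (stageNum - 2)
    T <- stats::rexp(n, rate = config$baselineRate * exp(lp))
    cens <- if (config$censoringRate > 0)
      stats::quantile(T, 1 - config$censoringRate) else Inf
    time <- pmin(T, cens)
    event <- as.integer(T <= cens)

    clinical <- data.frame(sample = samples, os_months = time,
                           os_event = event, age_years = age,
                           stage = stageLabel, cancer_code = "synthetic",
                           stringsAsFactors = FALSE)

    events <- simulateEventTables(config,
      groups = list(repair = config$repairGenes, driver = config$driverGenes),
      samples = samples)

    structure(list(expr = expr, clinical = clinical, events = events,
                   truth = list(f = f, u = u, beta = beta, gamma = gamma,
                                plantedGenes = config$plantedGenes,
                                eventProbs = config$eventProbs,
                                censorTime = cens),
                   config = config),
              class = "syntheticCohort")
  })
}

#' Simulate per-gene genomic event tables
#'
#' Independent Bernoulli draws per gene-sample and event type, so the
#' expected genomic event rate equals the configured probability. The
#' copy-number matrix holds a single GISTIC score per gene-sample, so a
#' deletion and an amplification can never co-occur in one pair. A small
#' number of non-pathogenic mutation records is included to exercise the
#' pathogenicity filter.
#'
#' @param config a [simulationConfig()] (supplies \code{eventProbs}).
#' @param groups named list of gene vectors; each name must match an
#'   element of \code{config$eventProbs} (unmatched groups use the
#'   \code{repair} probabilities).
#' @param samples sample identifiers.
#' @return list with \code{mutations} (gene, sample, pathogenic) and
#'   \code{cna} (genes x samples integer GISTIC matrix).
#' @export
simulateEventTables <- function(config, groups, samples) {
  allGenes <- unique(unlist(groups, use.names = FALSE))
  nG <- length(allGenes); nS <- length(samples)
  probOf <- function(g) {
    for (nm in names(groups))
      if (g %in% groups[[nm]])
        return(config$eventProbs[[nm]] %||% config$eventProbs$repair)
    config$eventProbs$repair
  }
  pm <- vapply(allGenes, function(g) probOf(g)["mutation"], numeric(1))
  pd <- vapply(allGenes, function(g) probOf(g)["deletion"], numeric(1))
  pa <- vapply(allGenes, function(g) probOf(g)["amplification"], numeric(1))

  mutHit <- matrix(stats::runif(nG * nS) < pm, nG, nS)
  idx <- which(mutHit, arr.ind = TRUE)
  mutations <- data.frame(gene = allGenes[idx[, 1]], sample = samples[idx[, 2]],
                          pathogenic = 1L, stringsAsFactors = FALSE)
  nonpath <- matrix(stats::runif(nG * nS) < 0.005, nG, nS)
  idx2 <- which(nonpath, arr.ind = TRUE)
  if (nrow(idx2))
    mutations <- rbind(mutations,
                       data.frame(gene = allGenes[idx2[, 1]],
                                  sample = samples[idx2[, 2]],
                                  pathogenic = 0L, stringsAsFactors = FALSE))

  u <- matrix(stats::runif(nG * nS), nG, nS)
  cna <- matrix(0L, nG, nS, dimnames = list(allGenes, samples))
  cna[u < pd] <- -2L
  cna[u >= pd & u < pd + pa] <- 2L
  low <- u >= pd + pa & u < pd + pa + 0.05
  cna[low] <- sample(c(-1L, 1L), sum(low), replace = TRUE)
  list(mutations = mutations, cna = cna)
}

#' Write a synthetic cohort as cBioPortal-style flat files
#'
#' Emits exactly the dialects the readers consume: \code{expression.tsv},
#' \code{clinical.tsv} (with \code{0:LIVING} / \code{1:DECEASED} status
#' tokens), \code{mutations.tsv}, \code{cna.tsv} and \code{truth.json}
#' (ground-truth latents and effects).
#'
#' @param cohort a \code{syntheticCohort} from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "syntheticCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpression(cohort$expr, file.path(dir, "expression.tsv"))
  clin <- cohort$clinical
  clin$os_status <- ifelse(clin$os_event == 1L, "1:DECEASED", "0:LIVING")
  clin$os_event <- NULL
  writeClinical(clin, file.path(dir, "clinical.tsv"))
  utils::write.table(cohort$events$mutations, file.path(dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeExpression(cohort$events$cna, file.path(dir, "cna.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
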