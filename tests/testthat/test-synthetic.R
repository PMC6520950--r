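test_that("simulation is bit-identical under a fixed seed", {
  cfg <- simulationConfig(nSamples = 60, seed = 42)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$events, b$events)
  c2 <- simulateCohort(simulationConfig(nSamples = 60, seed = 43))
  expect_false(identical(a$expr, c2$expr))
})

test_that("cohort dimensions, gene identities and censoring hit the configuration", {
  cfg <- simulationConfig(nSamples = 400, censoringRate = 0.6, seed = 2)
  coh <- simulateCohort(cfg)
  expect_identical(dim(coh$expr), c(121L + 131L, 400L))
  expect_true(all(cfg$plantedGenes %in% rownames(coh$expr)))
  expect_true(all(coh$expr > 0))                      # RNA-Seq-like positivity
  cens <- mean(coh$clinical$os_event == 0)
  expect_lt(abs(cens - 0.6), 0.05)
  expect_true(all(coh$clinical$os_months >= 0))
  # no-censoring configuration
  coh0 <- simulateCohort(simulationConfig(nSamples = 50, censoringRate = 0,
                                          seed = 3))
  expect_true(all(coh0$clinical$os_event == 1))
})

test_that("the metagene tracks the latent proliferation factor", {
  cfg <- simulationConfig(nSamples = 300, prolifLoading = 0.8, seed = 4)
  coh <- simulateCohort(cfg)
  mg <- computeMetagene(coh$expr, cfg$metageneGenes)
  # on the VDW scale (how the adjustment consumes the metagene) tracking is
  # near perfect; the raw scale is an exponentiated latent, so its Pearson
  # r is attenuated to ~ lambda / sqrt(exp(lambda^2) - 1) by the lognormal
  # marginal while the rank correlation stays high
  expect_gt(cor(vdwTransform(mg), coh$truth$f), 0.9)
  expect_gt(cor(mg, coh$truth$f, method = "spearman"), 0.9)
  expect_equal(cor(mg, coh$truth$f), 0.8 / sqrt(exp(0.64) - 1),
               tolerance = 0.05)
})

test_that("event tables are Bernoulli with the configured rates", {
  cfg <- simulationConfig(nSamples = 200, seed = 6,
                          eventProbs = list(
                            repair = c(mutation = 0.05, deletion = 0.02,
                                       amplification = 0.03),
                            driver = c(mutation = 0.3, deletion = 0,
                                       amplification = 0)))
  coh <- simulateCohort(cfg)
  ev <- coh$events
  q <- 0.02
  N <- 121 * 200
  nDel <- sum(ev$cna[cfg$repairGenes, ] == -2L)
  ci <- qbinom(c(0.005, 0.995), N, q)
  expect_gte(nDel, ci[1]); expect_lte(nDel, ci[2])
  # probability-zero events never occur
  expect_identical(sum(ev$cna[intersect(cfg$driverGenes, rownames(ev$cna)),
                              ] == -2L), 0L)
  # a single CNA value per gene-sample: deletion and amplification exclusive
  expect_true(all(ev$cna %in% -2:2))
  # mutation rate for drivers ~ 0.3
  drMut <- ev$mutations[ev$mutations$pathogenic == 1L &
                          ev$mutations$gene %in% setdiff(cfg$driverGenes,
                                                         cfg$repairGenes), ]
  nDr <- length(setdiff(cfg$driverGenes, cfg$repairGenes)) * 200
  ciDr <- qbinom(c(0.005, 0.995), nDr, 0.3)
  expect_gte(nrow(unique(drMut[, 1:2])), ciDr[1])
  expect_lte(nrow(unique(drMut[, 1:2])), ciDr[2])
})

test_that("null mode carries no gene-survival association", {
  coh <- simulateCohort(simulationConfig(nSamples = 1000,
                                         mediationMode = "null", seed = 7))
  # survival is independent of u and f up to age/stage effects; the planted
  # component must not predict survival
  fit <- coxDirection(coh$clinical$os_months, coh$clinical$os_event,
                      coh$truth$u)
  expect_gt(fit$pvalue, 0.01)
})

test_that("mediated mode removes the screen signal while residual mode keeps it", {
  pool <- survivalGenePool(loadPathwayCatalog(repairPathwaysFile()))
  sig <- readMetageneSignature()
  frac <- function(mode, seed) {
    coh <- simulateCohort(simulationConfig(nSamples = 400, plantedGenes = 10,
                                           mediationMode = mode, seed = seed))
    adj <- adjustExpression(coh$expr, coh$clinical, genes = pool,
                            signature = sig,
                            adjustFor = c("age", "stage", "metagene"))
    scr <- screenGenes(adj, coh$clinical$os_months, coh$clinical$os_event)
    length(significantGenes(scr)) / nrow(scr@table)
  }
  med <- vapply(1:5, function(s) frac("fully-mediated", 500 + s), numeric(1))
  res <- vapply(1:5, function(s) frac("residual-signal", 500 + s), numeric(1))
  # mediated: significant fraction within the 99% binomial band of alpha
  band <- qbinom(c(0.005, 0.995), 5 * 121, 0.05) / (5 * 121)
  expect_gte(mean(med), band[1]); expect_lte(mean(med), band[2])
  # residual signal: clearly above the band (planted genes push it up)
  expect_gt(mean(res), band[2])
})

test_that("unadjusted expression shows the proliferation confounding that adjustment removes", {
  coh <- simulateCohort(simulationConfig(nSamples = 400,
                                         mediationMode = "fully-mediated",
                                         seed = 9))
  pool <- coh$config$repairGenes
  # without metagene adjustment many repair genes "predict" survival through f
  adjN <- adjustExpression(coh$expr, coh$clinical, genes = pool,
                           adjustFor = "age")
  scrN <- screenGenes(adjN, coh$clinical$os_months, coh$clinical$os_event)
  adjM <- adjustExpression(coh$expr, coh$clinical, genes = pool,
                           signature = coh$config$metageneGenes,
                           adjustFor = c("age", "stage", "metagene"))
  scrM <- screenGenes(adjM, coh$clinical$os_months, coh$clinical$os_event)
  expect_gt(length(significantGenes(scrN)),
            2 * length(significantGenes(scrM)))
})
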