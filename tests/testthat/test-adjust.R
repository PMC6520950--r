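test_that("VDW scores are normal quantiles of rank/(n+1) percentiles", {
  expect_equal(vdwTransform(c(10, 20, 30)),
               qnorm(c(0.25, 0.5, 0.75)))
  expect_equal(vdwTransform(c(1, 2, 3, 4)),
               qnorm(c(0.2, 0.4, 0.6, 0.8)))
  expect_equal(vdwTransform(c(1, 2, 3, 4)),
               c(-0.8416, -0.2533, 0.2533, 0.8416), tolerance = 1e-4)
  # midranks for ties
  expect_equal(vdwTransform(c(5, 5, 9)), qnorm(c(0.375, 0.375, 0.75)))
  expect_error(vdwTransform(rep(3, 10)), "constant")
  expect_error(vdwTransform(c(1, NA, 3)), "finite")
})

test_that("VDW depends only on ranks and is centered", {
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(50)
    z <- vdwTransform(x)
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(vdwTransform(exp(x)), z)          # strictly monotone map
    expect_identical(order(z), order(x))           # rank preserving
  }
})

test_that("VDW variance sits in [0.9, 1] for tie-free n >= 100 and grows with n", {
  vfor <- function(n) {
    z <- qnorm(seq_len(n) / (n + 1))
    sum(z^2) / (n - 1)
  }
  vs <- vapply(c(100, 300, 1000, 5000), vfor, numeric(1))
  expect_true(all(vs >= 0.9 & vs <= 1.0))
  expect_true(all(diff(vs) > 0))
})

test_that("metagene is the per-sample median over present signature genes", {
  m <- matrix(c(1, 5, 9, 2, 2, 2), 3, 2,
              dimnames = list(c("PCS001", "PCS002", "PCS003"), c("S1", "S2")))
  expect_equal(unname(computeMetagene(m, c("PCS001", "PCS002", "PCS003"))),
               c(5, 2))
  # invariant to gene ordering, absent genes only reduce the median set
  expect_message(
    mg <- computeMetagene(m, c("PCS003", "PCS001", "NOPE")), "absent")
  expect_equal(unname(mg), c(median(c(1, 9)), 2))
  expect_error(computeMetagene(m, "ZZZ"), "no signature genes")
})

test_that("stage encoding is ordinal with substages ordered within stage", {
  expect_equal(encodeStage(c("I", "II", "II", "IV")), c(1, 2.5, 2.5, 4))
  expect_true(encodeStage(c("IIIA", "IIIB"))[1] < encodeStage(c("IIIA", "IIIB"))[2])
  expect_equal(encodeStage(c("Stage IIIA", "iii a"))[1],
               encodeStage(c("Stage IIIA", "iii a"))[2])
  expect_true(is.na(encodeStage(c("I", NA))[2]))
  expect_error(encodeStage("Stage X"), "unrecognized stage")
})

test_that("residualization is exact OLS with intercept", {
  x <- rnorm(100)
  expect_equal(as.numeric(residualize(2 * x, list(x = x))), rep(0, 100),
               tolerance = 1e-12)
  expect_equal(unname(attr(residualize(2 * x, list(x = x)), "coefficients")),
               c(0, 2), tolerance = 1e-10)
  y <- rnorm(100)
  expect_equal(as.numeric(residualize(y)), y - mean(y))
  # orthogonality at n = 200 against the normal-equations oracle
  set.seed(7)
  y <- rnorm(200); x <- rnorm(200)
  r <- residualize(y, list(x = x))
  expect_lt(abs(cor(r, x)), 1e-8)
  expect_lt(abs(mean(r)), 1e-10)
  X <- cbind(1, x)
  expect_equal(as.numeric(r),
               as.numeric(y - X %*% solve(crossprod(X), crossprod(X, y))),
               tolerance = 1e-10)
  # idempotence
  expect_equal(as.numeric(residualize(as.numeric(r), list(x = x))),
               as.numeric(r), tolerance = 1e-10)
  expect_error(residualize(y, list(a = x, b = 2 * x)), "collinear")
})

test_that("the adjustment chain removes covariates and is permutation equivariant", {
  coh <- simulateCohort(simulationConfig(nSamples = 120, seed = 3))
  sig <- readMetageneSignature()
  pool <- survivalGenePool(loadPathwayCatalog(repairPathwaysFile()))
  adj <- adjustExpression(coh$expr, coh$clinical, genes = pool,
                          signature = sig,
                          adjustFor = c("age", "stage", "metagene"))
  R <- adjustedResiduals(adj)
  expect_identical(dim(R), c(121L, 120L))
  for (j in seq_len(ncol(adj@covariates)))
    expect_true(all(abs(apply(R, 1, cor, adj@covariates[, j])) < 1e-8))
  expect_true(all(abs(rowMeans(R)) < 1e-10))
  # permuting samples permutes residuals identically
  perm <- sample(ncol(coh$expr))
  adj2 <- adjustExpression(coh$expr[, perm], coh$clinical[perm, ],
                           genes = pool, signature = sig,
                           adjustFor = c("age", "stage", "metagene"))
  expect_equal(adjustedResiduals(adj2), R[, perm], tolerance = 1e-10)
})

test_that("auto adjustment set follows stage availability", {
  expect_identical(autoAdjustSet(data.frame(stage = c("I", NA))),
                   c("age", "stage", "metagene"))
  expect_identical(autoAdjustSet(data.frame(stage = c(NA_character_, NA))),
                   c("age", "metagene"))
})

test_that("metagene correlation hits the exact and null cases", {
  mg <- rnorm(300)
  m <- rbind(G1 = mg, G2 = -mg, G3 = rep(1, 300))
  r <- correlateWithMetagene(m, mg)
  expect_equal(unname(r[1:2]), c(1, -1))
  expect_true(is.na(r[3]))
  # independent genes: |r| small in most seeds at n = 1000
  set.seed(11)
  rs <- replicate(40, cor(rnorm(1000), rnorm(1000)))
  expect_gte(mean(abs(rs) < 0.1), 0.95)
})

test_that("estimated metagene correlations reorder like the configured loadings", {
  # genes with larger proliferation loading must correlate more with the
  # metagene; checked via two cohorts differing only in loading
  coh <- simulateCohort(simulationConfig(nSamples = 500, seed = 21))
  mg <- computeMetagene(coh$expr, coh$config$metageneGenes)
  pool <- coh$config$repairGenes
  adjA <- adjustExpression(coh$expr, coh$clinical, genes = pool,
                           signature = coh$config$metageneGenes,
                           adjustFor = "age")
  r <- correlateWithMetagene(adjA, vdwTransform(mg))
  # all repair genes share loading 0.4 on f here: correlations concentrate
  # around a clearly positive value
  expect_gt(median(r), 0.2)
})
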