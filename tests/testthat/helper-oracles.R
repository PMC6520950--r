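# Independent oracles used to cross-check the package's statistics. These
# are deliberately naive (explicit loops over risk sets / cluster pairs) and
# share no code with the implementation.

# logrank chi-squared from explicit per-event-time risk-set tables
oracleLogrank <- function(time, event, group) {
  taus <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tau in taus) {
    at <- time >= tau
    n <- sum(at)
    n1 <- sum(at & group == 1)
    d <- sum(time == tau & event == 1)
    d1 <- sum(time == tau & event == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) 0 else (O - E)^2 / V
}

# UPGMA cophenetic distance matrix by exhaustive agglomeration; inter-cluster
# distance recomputed each round as the mean over all cross leaf pairs
oracleUpgmaCophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  C <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_len(length(clusters) - 1))
      for (j in (i + 1):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    for (a in clusters[[bi]]) for (b in clusters[[bj]]) {
      C[a, b] <- best; C[b, a] <- best
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  C
}

# varimax simplicity criterion (sum over columns of variance of squared
# loadings), evaluated directly
oracleVarimaxCriterion <- function(L) {
  sum(apply(L, 2, function(col) mean(col^4) - mean(col^2)^2))
}

# small survival dataset generator for oracle comparisons
randomSurvData <- function(n, pEvent = 0.7, tieProb = 0) {
  t <- rexp(n)
  if (tieProb > 0) t <- round(t, 1)  # induce ties
  list(time = t, event = rbinom(n, 1, pEvent), group = rbinom(n, 1, 0.5))
}

# minimal aligned test cohort: k genes x n samples plus survival columns
tinyCohort <- function(n = 60, k = 5, seed = 42) {
  set.seed(seed)
  expr <- matrix(rexp(k * n, 0.2), k, n,
                 dimnames = list(paste0("G", seq_len(k)),
                                 paste0("S", seq_len(n))))
  clin <- data.frame(sample = colnames(expr),
                     os_months = rexp(n, 0.02),
                     os_event = rbinom(n, 1, 0.6),
                     age_years = rnorm(n, 60, 8),
                     stage = sample(c("I", "II", "IIIA", "IV"), n, TRUE),
                     cancer_code = "test", stringsAsFactors = FALSE)
  list(expr = expr, clinical = clin)
}
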