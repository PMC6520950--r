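#' Median binarization
#'
#' Splits a continuous vector at its median: values strictly above the
#' median become group 1, the rest group 0. Values tied with the median
#' therefore fall in group 0; for continuous residuals a tie-free vector of
#' even length 2k yields exactly k samples per group.
#'
#' @param x numeric vector with at least two distinct values.
#' @return integer 0/1 vector.
#' @export
medianBinarize <- function(x) {
  if (length(unique(x)) < 2L)
    stop("cannot median-binarize a constant vector")
  as.integer(x > stats::median(x))
}

# Precomputed risk-set skeleton: everything about (time, event) that the
# logrank statistic needs, so repeated tests on the same survival data only
# tally the group vector. Positions are sorted by time; tid maps each sorted
# position to its distinct-time id.
.survSkeleton <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% c(0, 1)))
  o <- order(time)
  t <- time[o]
  d <- as.integer(event[o])
  first <- !duplicated(t)
  tid <- cumsum(first)
  nt <- tid[length(tid)]
  cnt <- tabulate(tid, nt)               # subjects entering each distinct time
  atrisk <- rev(cumsum(rev(cnt)))        # n_j
  dj <- tabulate(tid[d == 1L], nt)       # events per distinct time
  keep <- dj > 0L
  list(o = o, tid = tid, nt = nt, d = d, n = length(t),
       atrisk = atrisk[keep], dj = dj[keep], keep = keep,
       eventIdx = which(d == 1L), nevent = sum(d))
}

# chi-squared for group vector g (0/1, original sample order)
.logrankChisq <- function(g, skel) {
  gs <- as.integer(g[skel$o])
  cnt1 <- tabulate(skel$tid[gs == 1L], skel$nt)
  n1 <- rev(cumsum(rev(cnt1)))[skel$keep]
  d1 <- tabulate(skel$tid[skel$eventIdx][gs[skel$eventIdx] == 1L], skel$nt)[skel$keep]
  nj <- skel$atrisk
  dj <- skel$dj
  O <- sum(d1)
  E <- sum(dj * n1 / nj)
  ok <- nj > 1L
  V <- sum((dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1))[ok])
  if (V <= 0) return(0)
  (O - E)^2 / V
}

#' Two-sample Kaplan-Meier logrank test
#'
#' Standard logrank chi-squared (1 d.f.): observed minus expected events
#' summed over the distinct event times, with hypergeometric variance
#' (tied events are all counted at their common time). Significance at
#' level alpha is equivalent to chi2 exceeding [kmCriticalValue()] (3.84
#' at alpha = 0.05).
#'
#' @param time non-negative survival times.
#' @param event 0/1 event indicators (1 = deceased).
#' @param group 0/1 group labels; both groups must be non-empty.
#' @return list with \code{chi2}, \code{pvalue}, \code{n} (per-group
#'   sizes), \code{events} (per-group event counts).
#' @export
kmLogrank <- function(time, event, group) {
  stopifnot(length(group) == length(time))
  g <- as.integer(group)
  if (!all(g %in% c(0L, 1L))) stop("group must be binary 0/1")
  if (length(unique(g)) < 2L) stop("both groups must be non-empty")
  if (sum(event) < 1) stop("no events: logrank test undefined")
  skel <- .survSkeleton(time, event)
  chi2 <- .logrankChisq(g, skel)
  list(chi2 = chi2,
       pvalue = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       n = c(n0 = sum(g == 0L), n1 = sum(g == 1L)),
       events = c(events0 = sum(event[g == 0L]), events1 = sum(event[g == 1L])))
}

#' KM significance boundary
#'
#' The 1-d.f. chi-squared critical value used throughout the screen;
#' 3.84 (to two decimals) at the default alpha = 0.05.
#'
#' @param alpha significance level.
#' @return numeric critical value.
#' @export
kmCriticalValue <- function(alpha = 0.05) stats::qchisq(1 - alpha, df = 1)

#' Per-gene Kaplan-Meier screen of adjusted expression
#'
#' Median-binarizes each gene's adjusted residual vector and runs the
#' logrank test against overall survival. Genes with a constant residual or
#' a degenerate split are skipped with a message and listed in the result.
#' Genes with fewer than five events in either group are flagged
#' (\code{lowEvents}) but still tested. The ordered list of genes with
#' p-value below alpha is the significant set feeding the PC summarization.
#' No multiplicity correction is applied here; the randomization test is
#' the calibration step.
#'
#' @param adjusted an \linkS4class{AdjustedExpression} (or genes x samples
#'   residual matrix).
#' @param time,event overall survival months and 0/1 status, aligned to the
#'   residual columns.
#' @param alpha significance level.
#' @return a \linkS4class{ScreenResult}.
#' @export
screenGenes <- function(adjusted, time, event, alpha = 0.05) {
  m <- if (is(adjusted, "AdjustedExpression")) adjusted@residuals else adjusted
  stopifnot(ncol(m) == length(time), length(time) == length(event))
  if (nrow(m) < 1L) stop("no genes to screen")
  skel <- .survSkeleton(time, event)
  if (skel$nevent < 1) stop("no events in the cohort")
  rows <- vector("list", nrow(m))
  skipped <- character(0)
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    if (length(unique(v)) < 2L) { skipped <- c(skipped, rownames(m)[i]); next }
    g <- as.integer(v > stats::median(v))
    if (length(unique(g)) < 2L) { skipped <- c(skipped, rownames(m)[i]); next }
    chi2 <- .logrankChisq(g, skel)
    ev0 <- sum(event[g == 0L]); ev1 <- sum(event[g == 1L])
    rows[[i]] <- data.frame(
      gene = rownames(m)[i], chi2 = chi2,
      pvalue = stats::pchisq(chi2, 1, lower.tail = FALSE),
      n0 = sum(g == 0L), n1 = sum(g == 1L),
      events0 = ev0, events1 = ev1,
      lowEvents = ev0 < 5 || ev1 < 5, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(tab) || !nrow(tab)) stop("no testable genes")
  if (length(skipped))
    message("skipped ", length(skipped), " untestable gene(s)")
  tab$significant <- tab$pvalue < alpha
  rownames(tab) <- NULL
  new("ScreenResult", table = tab, significant = tab$gene[tab$significant],
      alpha = alpha, skipped = skipped)
}
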