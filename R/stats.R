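#' Welch's t-test from summary statistics
#'
#' Unequal-variance two-sample t-test computed from group means, sample
#' standard deviations (denominator n-1) and sizes:
#' `t = (mean2 - mean1) / sqrt(sd1^2/n1 + sd2^2/n2)`, with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' t distribution. All arguments are vectorised.
#'
#' When both SDs are zero the statistic is undefined; by convention the
#' result is `p = 1` if the means are equal and `p = 0` otherwise (with
#' `df = n1 + n2 - 2`), and a warning is emitted.
#'
#' @param mean1,sd1,n1 summary statistics of the first (reference) group.
#' @param mean2,sd2,n2 summary statistics of the second (test) group.
#' @return A data.frame with columns `tStat`, `df`, `pValue`.
#' @examples
#' welchT(5.0, 0.1, 3, 5.5, 0.1, 3)
#' @export
welchT <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2), all(sd1 >= 0), all(sd2 >= 0))
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se2 <- v1 + v2
  diff <- mean2 - mean1
  t <- diff / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  degenerate <- se2 == 0
  if (any(degenerate, na.rm = TRUE)) {
    warning("welchT: zero variance in both groups for ",
            sum(degenerate, na.rm = TRUE),
            " case(s); applying the means-equal convention")
    dfPooled <- rep_len(n1 + n2 - 2, length(t))
    df[degenerate] <- dfPooled[degenerate]
    t[degenerate] <- ifelse(diff[degenerate] == 0, 0,
                            sign(diff[degenerate]) * Inf)
  }
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[degenerate & diff == 0] <- 1
  p[degenerate & diff != 0] <- 0
  data.frame(tStat = t, df = df, pValue = p)
}

# Per-cell summary arrays for one state of a matched table:
# mean, sd (ddof = 1) and n over the replicate dimension.
cellStats <- function(arr3) {
  n <- apply(!is.na(arr3), c(1, 2), sum)
  m <- apply(arr3, c(1, 2), mean, na.rm = TRUE)
  s <- apply(arr3, c(1, 2), stats::sd, na.rm = TRUE)
  m[n == 0] <- NA_real_
  list(mean = m, sd = s, n = n)
}

#' Global critical interval for one state comparison
#'
#' The dataset-wide threshold on the uptake difference used by the hybrid
#' significance test. Per-cell replicate variances (cells = peptide x
#' timepoint, replicate count >= 2) are averaged per state over the whole
#' comparison and the pooled SD is their square root; the critical interval
#' is
#' `ci = t(1 - alpha/2, nRef + nTest - 2) * sqrt(spRef^2/nRef + spTest^2/nTest)`
#' where the per-state n is the minimum replicate count among pooled cells
#' (conservative under unequal replication). Undeuterated (0 s) timepoints
#' are excluded.
#'
#' @param table a [MatchedUptake-class].
#' @param comparison test-state label (compared against the table's
#'   reference, its first state).
#' @param alpha significance level (default 0.01).
#' @return A one-row data.frame: `comparison`, `alpha`, `sdPooledRef`,
#'   `sdPooledTest`, `nRef`, `nTest`, `dfPool`, `ciDa`.
#' @export
criticalInterval <- function(table, comparison, alpha = 0.01) {
  stopifnot(methods::is(table, "MatchedUptake"))
  states <- table@states
  if (!comparison %in% states[-1])
    stop("comparison must be a non-reference state; got ", shQuote(comparison))
  tested <- table@timepoints > 0
  if (!any(tested)) stop("no nonzero exposure times to test")
  u <- table@uptake[, , tested, , drop = FALSE]
  poolState <- function(si) {
    st <- cellStats(u[, si, , , drop = TRUE] |>
                      array(dim = dim(u)[c(1, 3, 4)]))
    use <- st$n >= 2
    if (!any(use)) stop("state ", shQuote(states[si]),
                        ": no cell has >= 2 replicates")
    list(sp = sqrt(mean(st$sd[use]^2)), n = min(st$n[use]))
  }
  ref <- poolState(1L)
  tst <- poolState(match(comparison, states))
  dfPool <- ref$n + tst$n - 2
  ci <- stats::qt(1 - alpha / 2, dfPool) *
    sqrt(ref$sp^2 / ref$n + tst$sp^2 / tst$n)
  data.frame(comparison = comparison, alpha = alpha,
             sdPooledRef = ref$sp, sdPooledTest = tst$sp,
             nRef = ref$n, nTest = tst$n, dfPool = dfPool, ciDa = ci,
             stringsAsFactors = FALSE)
}

#' Hybrid differential test of all states against the reference
#'
#' Runs the full hybrid significance analysis: every non-reference state is
#' compared to the reference (the matched table's first state). For each
#' (peptide, timepoint) cell a Welch's t-test on replicate uptake values
#' gives a p-value, and each comparison gets one global critical interval
#' from [criticalInterval()]. A cell is flagged significant only when both
#' `pValue < alpha` and `|deltaDa| > ciDa`. Cells with fewer than two
#' replicates in either state are kept in the results for plotting
#' (`tested = FALSE`) but never flagged. Undeuterated (0 s) timepoints are
#' excluded from testing.
#'
#' No multiple-testing correction is applied across peptides: in the hybrid
#' framework the global critical interval is the guard against multiplicity.
#'
#' @param table a [MatchedUptake-class] with at least two states.
#' @param alpha significance level for both filters (default 0.01).
#' @return An [HDXComparisonSet-class].
#' @examples
#' sim <- simulateHDXExport(hdxSimConfig(
#'   nStates = 2, nPeptides = 20, seed = 3,
#'   effects = data.frame(peptide = 4, state = 2, deltaDa = 1.0)))
#' cs <- compareStates(matchPeptides(sim$records))
#' cs
#' @export
compareStates <- function(table, alpha = 0.01) {
  stopifnot(methods::is(table, "MatchedUptake"))
  states <- table@states
  if (length(states) < 2) stop("need at least two states to compare")
  tested <- table@timepoints > 0
  if (!any(tested)) stop("no nonzero exposure times to test")
  tps <- table@timepoints[tested]
  pep <- table@peptides
  nPep <- nrow(pep)
  nTp <- length(tps)

  subArr <- function(a, si) array(a[, si, tested, , drop = TRUE],
                                  dim = c(nPep, nTp, dim(a)[4]))
  refU <- cellStats(subArr(table@uptake, 1L))
  refP <- cellStats(subArr(table@percentD, 1L))

  resList <- vector("list", length(states) - 1L)
  ciList <- vector("list", length(states) - 1L)
  for (k in seq_along(states[-1])) {
    s <- states[k + 1L]
    tstU <- cellStats(subArr(table@uptake, k + 1L))
    tstP <- cellStats(subArr(table@percentD, k + 1L))
    ciRow <- criticalInterval(table, s, alpha)
    testable <- refU$n >= 2 & tstU$n >= 2
    delta <- tstU$mean - refU$mean
    t <- df <- p <- matrix(NA_real_, nPep, nTp)
    if (any(testable)) {
      wt <- suppressWarnings(welchT(
        refU$mean[testable], refU$sd[testable], refU$n[testable],
        tstU$mean[testable], tstU$sd[testable], tstU$n[testable]))
      t[testable] <- wt$tStat
      df[testable] <- wt$df
      p[testable] <- wt$pValue
    }
    sig <- testable & !is.na(p) & p < alpha & abs(delta) > ciRow$ciDa
    resList[[k]] <- data.frame(
      comparison = s,
      sequence = rep(pep$sequence, nTp),
      start = rep(pep$start, nTp),
      end = rep(pep$end, nTp),
      timepoint = rep(tps, each = nPep),
      meanRef = as.vector(refU$mean), meanTest = as.vector(tstU$mean),
      deltaDa = as.vector(delta),
      sdRef = as.vector(refU$sd), sdTest = as.vector(tstU$sd),
      nRef = as.vector(refU$n), nTest = as.vector(tstU$n),
      tStat = as.vector(t), df = as.vector(df), pValue = as.vector(p),
      ciDa = ciRow$ciDa,
      tested = as.vector(testable), significant = as.vector(sig),
      meanPctRef = as.vector(refP$mean), meanPctTest = as.vector(tstP$mean),
      sdPctRef = as.vector(refP$sd), sdPctTest = as.vector(tstP$sd),
      stringsAsFactors = FALSE)
    ciList[[k]] <- ciRow
  }
  methods::new("HDXComparisonSet",
               results = do.call(rbind, resList),
               intervals = do.call(rbind, ciList),
               alpha = alpha, states = states)
}

#' Peptides significant at one or more timepoints
#'
#' For each comparison, the set of peptides flagged significant by the
#' hybrid test at at least one exposure time. This is the filter behind
#' significant-only Woods plots, robot plots and PyMOL scripts.
#'
#' @param x an [HDXComparisonSet-class].
#' @param comparison optional test-state label; default all comparisons.
#' @return A named list (one element per comparison) of data.frames with
#'   columns `sequence`, `start`, `end`.
#' @export
significantPeptides <- function(x, comparison = NULL) {
  stopifnot(methods::is(x, "HDXComparisonSet"))
  r <- x@results
  cmps <- if (is.null(comparison)) unique(r$comparison) else comparison
  out <- lapply(cmps, function(cmp) {
    sub <- r[r$comparison == cmp & r$significant %in% TRUE,
             c("sequence", "start", "end"), drop = FALSE]
    sub <- unique(sub)
    sub <- sub[order(sub$start, sub$end, sub$sequence), , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  stats::setNames(out, cmps)
}
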