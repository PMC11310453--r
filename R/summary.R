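#' Sequence coverage and redundancy of a peptide map
#'
#' Per-residue peptide depth `d(r)` is the number of peptides whose span
#' covers residue `r`. Coverage is the percentage of protein residues with
#' `d(r) >= 1`; redundancy is the mean depth over *covered* residues only
#' (the convention used in HDX summary tables).
#'
#' @param peptides data.frame with integer columns `start`, `end`
#'   (1-based, inclusive), e.g. [peptideKeys()] of a matched table.
#' @param proteinLength protein length in residues; must be at least the
#'   largest peptide end.
#' @return A list with `coveragePct`, `avgRedundancy` and the integer
#'   per-residue `depth` vector.
#' @examples
#' coverageRedundancy(data.frame(start = c(1, 6), end = c(10, 15)), 20)
#' @export
coverageRedundancy <- function(peptides, proteinLength) {
  stopifnot(nrow(peptides) > 0, proteinLength >= 1)
  bad <- peptides$end > proteinLength
  if (any(bad))
    stop("peptide(s) exceed protein length ", proteinLength, ": ",
         paste(sprintf("%d-%d", peptides$start[bad], peptides$end[bad])[
           seq_len(min(3, sum(bad)))], collapse = ", "))
  # difference-array accumulation of interval depth
  delta <- integer(proteinLength + 1L)
  for (i in seq_len(nrow(peptides))) {
    delta[peptides$start[i]] <- delta[peptides$start[i]] + 1L
    delta[peptides$end[i] + 1L] <- delta[peptides$end[i] + 1L] - 1L
  }
  depth <- cumsum(delta[seq_len(proteinLength)])
  covered <- depth >= 1L
  list(coveragePct = 100 * sum(covered) / proteinLength,
       avgRedundancy = if (any(covered)) mean(depth[covered]) else NA_real_,
       depth = depth)
}

#' Maximum exchangeable backbone amides of a peptide
#'
#' The theoretical maximum deuterium uptake used to normalise percent
#' deuteration and back exchange. Two conventions are supported:
#' `"L-2-P"` (default) excludes the first two backbone amides as
#' fast-exchanging plus prolines at positions >= 3;
#' `"L-1-P"` excludes only the N-terminal residue plus prolines at
#' positions >= 2.
#'
#' @param sequence character vector of 1-letter amino-acid sequences.
#' @param convention `"L-2-P"` or `"L-1-P"`.
#' @return Integer vector of exchangeable amide counts (may be 0 for very
#'   short peptides).
#' @examples
#' maxExchangeableAmides("ACDEFGHIK")  # 9 - 2 - 0 = 7
#' @export
maxExchangeableAmides <- function(sequence, convention = c("L-2-P", "L-1-P")) {
  convention <- match.arg(convention)
  skip <- if (convention == "L-2-P") 2L else 1L
  vapply(toupper(sequence), function(s) {
    L <- nchar(s)
    if (L <= skip) return(0L)
    tail <- substring(s, skip + 1L, L)
    nPro <- lengths(regmatches(tail, gregexpr("P", tail, fixed = TRUE)))
    max(0L, L - skip - as.integer(nPro))
  }, integer(1), USE.NAMES = FALSE)
}

#' Back exchange from a fully-deuterated control
#'
#' Back exchange is the deuterium lost during sample handling, estimated
#' per peptide from the fully-deuterated (FD) control as
#' `BE% = 100 * (1 - uptakeFD / (maxUptake * dFraction))`, where
#' `maxUptake` is the exchangeable-amide count of the peptide (see
#' [maxExchangeableAmides()]) and `dFraction` the deuterium fraction of the
#' labeling buffer. FD rows of the same peptide (replicates, charge states)
#' are averaged first. Peptides with zero exchangeable amides are skipped
#' with a warning.
#'
#' @param x an [HDXDataSet-class] (or records data.frame) containing FD
#'   control rows (`isFD == TRUE`).
#' @param dFraction deuterium fraction of the labeling buffer (default 1.0).
#' @param convention exchangeable-amide convention, see
#'   [maxExchangeableAmides()].
#' @return A list with `perPeptide` (data.frame `sequence`, `start`, `end`,
#'   `uptakeFD`, `maxUptake`, `backExchangePct`), `meanPct`, `rangePct`
#'   (length-2 numeric), or `NULL` when no FD rows exist.
#' @export
backExchange <- function(x, dFraction = 1.0, convention = "L-2-P") {
  rec <- if (methods::is(x, "HDXDataSet")) peptideRecords(x) else x
  fd <- rec[rec$isFD & !is.na(rec$uptake), , drop = FALSE]
  if (nrow(fd) == 0) return(NULL)
  per <- stats::aggregate(uptake ~ sequence + start + end, data = fd, FUN = mean)
  per$maxUptake <- maxExchangeableAmides(per$sequence, convention)
  zero <- per$maxUptake == 0
  if (any(zero)) {
    warning("backExchange: skipping ", sum(zero),
            " peptide(s) with no exchangeable amides")
    per <- per[!zero, , drop = FALSE]
  }
  if (nrow(per) == 0) return(NULL)
  per$backExchangePct <- 100 * (1 - per$uptake / (per$maxUptake * dFraction))
  per <- per[order(per$start, per$end), , drop = FALSE]
  names(per)[names(per) == "uptake"] <- "uptakeFD"
  rownames(per) <- NULL
  list(perPeptide = per,
       meanPct = mean(per$backExchangePct),
       rangePct = range(per$backExchangePct))
}

#' Publication summary statistics per protein state
#'
#' Computes the standard HDX-MS summary-table fields for each state:
#' exposure times, replicate count, peptide count, sequence coverage,
#' average peptide length, average redundancy, pooled replicate SD, the
#' critical interval of the state's default comparison against the
#' reference (reported as `NA` for the reference itself), and back-exchange
#' mean and range when an FD control is present. Back-exchange fields are
#' `NA` (rendered "n.d." by [writePublicationTable()]) when no FD control
#' exists.
#'
#' @param table a [MatchedUptake-class].
#' @param raw the [HDXDataSet-class] (or records data.frame) the table was
#'   built from; used for FD control rows. May be `NULL` (no back exchange).
#' @param proteinLength protein length in residues; default: largest
#'   peptide end observed across all states.
#' @param alpha significance level for the critical intervals.
#' @param dFraction,convention passed to [backExchange()].
#' @return A data.frame with one row per state.
#' @export
buildSummary <- function(table, raw = NULL, proteinLength = NULL,
                         alpha = 0.01, dFraction = 1.0,
                         convention = "L-2-P") {
  stopifnot(methods::is(table, "MatchedUptake"))
  states <- table@states
  pep <- table@peptides
  if (is.null(proteinLength)) proteinLength <- max(pep$end)
  cov <- coverageRedundancy(pep, proteinLength)
  be <- if (is.null(raw)) NULL else
    backExchange(raw, dFraction = dFraction, convention = convention)
  nrep <- replicateCounts(table)
  tested <- table@timepoints > 0

  pooledSd <- vapply(seq_along(states), function(si) {
    u <- table@uptake[, si, tested, , drop = TRUE]
    u <- array(u, dim = c(nrow(pep), sum(tested), dim(table@uptake)[4]))
    st <- cellStats(u)
    use <- st$n >= 2
    if (!any(use)) NA_real_ else sqrt(mean(st$sd[use]^2))
  }, numeric(1))

  ciDa <- rep(NA_real_, length(states))
  if (length(states) >= 2) {
    for (k in seq_along(states[-1]))
      ciDa[k + 1L] <- criticalInterval(table, states[k + 1L], alpha)$ciDa
  }

  data.frame(
    state = states,
    timepoints = paste(table@timepoints, collapse = "; "),
    nReplicates = as.integer(nrep),
    nPeptides = nrow(pep),
    coveragePct = cov$coveragePct,
    avgPeptideLength = mean(pep$end - pep$start + 1),
    avgRedundancy = cov$avgRedundancy,
    pooledSdDa = pooledSd,
    criticalIntervalDa = ciDa,
    avgBackExchangePct = if (is.null(be)) NA_real_ else be$meanPct,
    backExchangeMinPct = if (is.null(be)) NA_real_ else be$rangePct[1],
    backExchangeMaxPct = if (is.null(be)) NA_real_ else be$rangePct[2],
    stringsAsFactors = FALSE, row.names = NULL)
}
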