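#' Write the matched-peptide table as CSV
#'
#' One row per (peptide, timepoint); columns `sequence`, `start`, `end`,
#' `timepoint`, then one uptake column per state x replicate, named
#' `<state>_rep<i>` with states in comparison order (reference first) and
#' replicates ascending. Values are written with full precision
#' (`format = "%.10g"`), so re-reading the file reproduces the table values
#' exactly at written precision.
#'
#' @param table a non-empty [MatchedUptake-class].
#' @param path output file path.
#' @param what `"uptake"` (Da) or `"percentD"`.
#' @return Invisibly, the written data.frame.
#' @export
writeMatchedCsv <- function(table, path, what = c("uptake", "percentD")) {
  stopifnot(methods::is(table, "MatchedUptake"))
  what <- match.arg(what)
  if (nrow(table@peptides) == 0) stop("matched table is empty; nothing to write")
  a <- if (what == "uptake") table@uptake else table@percentD
  d <- dim(a)
  pep <- table@peptides
  grid <- expand.grid(p = seq_len(d[1]), t = seq_len(d[3]))
  out <- data.frame(sequence = pep$sequence[grid$p],
                    start = pep$start[grid$p], end = pep$end[grid$p],
                    timepoint = table@timepoints[grid$t],
                    stringsAsFactors = FALSE)
  for (si in seq_len(d[2])) {
    for (ri in seq_len(d[4])) {
      col <- sprintf("%s_rep%d", table@states[si], ri)
      out[[col]] <- a[cbind(grid$p, si, grid$t, ri)]
    }
  }
  out <- out[order(out$start, out$end, out$sequence, out$timepoint), ]
  rownames(out) <- NULL
  writeNumericCsv(out, path)
  invisible(out)
}

#' Write per-peptide differential statistics as verbose CSV
#'
#' One row per (peptide, comparison, timepoint) carrying the group means,
#' standard deviations, replicate counts, uptake difference, Welch's t
#' statistic, degrees of freedom, p-value, the comparison-wide critical
#' interval and the hybrid significance flag. p-values are serialized with
#' at least 6 significant digits.
#'
#' @param x a non-empty [HDXComparisonSet-class].
#' @param path output file path.
#' @param comparison optional test-state label to restrict the output to.
#' @return Invisibly, the written data.frame.
#' @export
writeVerboseCsv <- function(x, path, comparison = NULL) {
  stopifnot(methods::is(x, "HDXComparisonSet"))
  r <- x@results
  if (!is.null(comparison)) r <- r[r$comparison %in% comparison, , drop = FALSE]
  if (nrow(r) == 0) stop("no comparison results to write")
  writeNumericCsv(r, path)
  invisible(r)
}

#' Write the publication summary table
#'
#' States as columns, the ten standard HDX summary fields as rows with
#' human-readable labels. Fields that are not determined (critical interval
#' of the reference state, back exchange without an FD control) are emitted
#' as `"n.d."` rather than omitted.
#'
#' @param summary per-state summary data.frame from [buildSummary()].
#' @param path output file path.
#' @param format only `"csv"` is supported; requesting `"xlsx"` raises an
#'   informative error.
#' @return Invisibly, the written character matrix.
#' @export
writePublicationTable <- function(summary, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx")
    stop("xlsx output is not supported by this build; use format = \"csv\"")
  stopifnot(nrow(summary) >= 1)
  fmt <- function(v, digits = 2) ifelse(is.na(v), "n.d.",
                                        formatC(v, format = "f", digits = digits))
  beRange <- ifelse(is.na(summary$backExchangeMinPct), "n.d.",
                    sprintf("%s - %s", fmt(summary$backExchangeMinPct),
                            fmt(summary$backExchangeMaxPct)))
  rows <- rbind(
    "Time points (s)" = summary$timepoints,
    "Number of replicates" = as.character(summary$nReplicates),
    "Number of peptides" = as.character(summary$nPeptides),
    "Peptide coverage (%)" = fmt(summary$coveragePct, 1),
    "Average peptide length" = fmt(summary$avgPeptideLength, 1),
    "Average redundancy" = fmt(summary$avgRedundancy, 2),
    "Standard deviation (Da)" = fmt(summary$pooledSdDa, 4),
    "Critical interval (Da)" = fmt(summary$criticalIntervalDa, 4),
    "Average back exchange (%)" = fmt(summary$avgBackExchangePct, 1),
    "Back exchange range (%)" = beRange)
  colnames(rows) <- summary$state
  out <- cbind(Parameter = rownames(rows), rows)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double")
  invisible(out)
}

# Full-precision CSV writer shared by the tabular outputs: numerics are
# formatted with %.10g so a write -> read round trip is lossless at the
# written precision.
writeNumericCsv <- function(df, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  fdf <- df
  for (j in seq_along(fdf)) {
    if (is.numeric(fdf[[j]]) && !is.integer(fdf[[j]]))
      fdf[[j]] <- ifelse(is.na(df[[j]]), "NA", sprintf("%.10g", df[[j]]))
  }
  utils::write.table(fdf, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
}
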