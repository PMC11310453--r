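#' Residue-level aggregation of peptide uptake differences
#'
#' Projects peptide-level differential results onto residues: for each
#' residue the value is the unweighted mean deltaD (Da) of the qualifying
#' peptides covering it. With `mode = "significant"` only peptides flagged
#' by the hybrid test qualify. Residues covered by no qualifying peptide
#' are `NA` ("uncovered") — distinguishable from a true deltaD of 0.
#'
#' Two layouts are produced: a time-course matrix (one comparison, columns
#' = timepoints) when `comparison` is given, or a multi-state matrix (one
#' timepoint, columns = comparisons) when `timepoint` is given. Giving both
#' yields a single-column matrix.
#'
#' @param x an [HDXComparisonSet-class].
#' @param comparison test-state label (time-course layout).
#' @param timepoint exposure in seconds (multi-state layout).
#' @param mode `"all"` or `"significant"`.
#' @param proteinLength number of rows; default largest peptide end.
#' @return Numeric matrix, rows = residues `1..L`, with `NA` for uncovered
#'   residues; column names are timepoints or comparison labels.
#' @export
residueMatrix <- function(x, comparison = NULL, timepoint = NULL,
                          mode = c("all", "significant"),
                          proteinLength = NULL) {
  stopifnot(methods::is(x, "HDXComparisonSet"))
  mode <- match.arg(mode)
  if (is.null(comparison) && is.null(timepoint))
    stop("give a comparison (time-course layout) and/or a timepoint ",
         "(multi-state layout)")
  r <- x@results
  if (!is.null(comparison)) {
    if (!all(comparison %in% r$comparison))
      stop("unknown comparison label")
    r <- r[r$comparison %in% comparison, , drop = FALSE]
  }
  if (!is.null(timepoint)) {
    if (!all(timepoint %in% r$timepoint)) stop("unknown timepoint")
    r <- r[r$timepoint %in% timepoint, , drop = FALSE]
  }
  if (is.null(proteinLength)) proteinLength <- max(x@results$end)

  if (!is.null(comparison) && length(comparison) == 1 && is.null(timepoint)) {
    colVals <- sort(unique(r$timepoint))
    colOf <- function(sub, v) sub[sub$timepoint == v, , drop = FALSE]
  } else {
    colVals <- unique(x@results$comparison)
    colVals <- colVals[colVals %in% r$comparison]
    colOf <- function(sub, v) sub[sub$comparison == v, , drop = FALSE]
  }
  m <- matrix(NA_real_, nrow = proteinLength, ncol = length(colVals),
              dimnames = list(seq_len(proteinLength), colVals))
  for (j in seq_along(colVals)) {
    sub <- colOf(r, colVals[j])
    if (mode == "significant") sub <- sub[sub$significant %in% TRUE, , drop = FALSE]
    if (nrow(sub) == 0) next
    sums <- counts <- numeric(proteinLength)
    for (i in seq_len(nrow(sub))) {
      if (is.na(sub$deltaDa[i])) next
      span <- sub$start[i]:sub$end[i]
      sums[span] <- sums[span] + sub$deltaDa[i]
      counts[span] <- counts[span] + 1
    }
    m[counts > 0, j] <- sums[counts > 0] / counts[counts > 0]
  }
  m
}
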