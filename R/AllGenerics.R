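#' Accessors for HDXdelta objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an `HDXDataSet`, `MatchedUptake`, `HDXComparisonSet` or
#'   `PymolScript` object (see individual methods).
#' @return The requested component; see Details of each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peptideRecords", function(x) standardGeneric("peptideRecords"))

#' @rdname accessors
#' @export
setGeneric("nSkipped", function(x) standardGeneric("nSkipped"))

#' @rdname accessors
#' @export
setGeneric("peptideKeys", function(x) standardGeneric("peptideKeys"))

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname accessors
#' @export
setGeneric("referenceState", function(x) standardGeneric("referenceState"))

#' @rdname accessors
#' @export
setGeneric("exposureTimes", function(x) standardGeneric("exposureTimes"))

#' @rdname accessors
#' @export
setGeneric("uptakeArray", function(x) standardGeneric("uptakeArray"))

#' @rdname accessors
#' @export
setGeneric("percentDArray", function(x) standardGeneric("percentDArray"))

#' @rdname accessors
#' @export
setGeneric("replicateCounts", function(x) standardGeneric("replicateCounts"))

#' @rdname accessors
#' @export
setGeneric("droppedPeptides", function(x) standardGeneric("droppedPeptides"))

#' @rdname accessors
#' @export
setGeneric("comparisonResults", function(x) standardGeneric("comparisonResults"))

#' @rdname accessors
#' @export
setGeneric("criticalIntervals", function(x) standardGeneric("criticalIntervals"))

#' @rdname accessors
#' @export
setGeneric("alphaLevel", function(x) standardGeneric("alphaLevel"))

#' @rdname accessors
#' @export
setGeneric("scriptLines", function(x) standardGeneric("scriptLines"))

# ---- HDXDataSet ----

#' @describeIn accessors data.frame of validated peptide records.
#' @export
setMethod("peptideRecords", "HDXDataSet", function(x) x@records)

#' @describeIn accessors number of input rows skipped during parsing.
#' @export
setMethod("nSkipped", "HDXDataSet", function(x) x@nSkipped)

#' @describeIn accessors state labels present in the records (FD controls
#'   excluded), in order of first appearance.
#' @export
setMethod("stateLabels", "HDXDataSet", function(x)
  unique(x@records$state[!x@records$isFD]))

setMethod("show", "HDXDataSet", function(object) {
  r <- object@records
  cat("HDXDataSet with", nrow(r), "records",
      sprintf("(%d skipped at parse)\n", object@nSkipped))
  cat("  states:    ", paste(unique(r$state[!r$isFD]), collapse = ", "), "\n")
  if (any(r$isFD))
    cat("  FD control:", paste(unique(r$state[r$isFD]), collapse = ", "), "\n")
  cat("  exposures: ", paste(sort(unique(r$exposure[!r$isFD])), collapse = ", "),
      "s\n")
  cat("  peptides:  ",
      nrow(unique(r[!r$isFD, c("sequence", "start", "end")])), "\n")
})

# ---- MatchedUptake ----

#' @describeIn accessors data.frame of matched peptide keys
#'   (`sequence`, `start`, `end`), sorted by start then end.
#' @export
setMethod("peptideKeys", "MatchedUptake", function(x) x@peptides)

#' @describeIn accessors state labels, reference first.
#' @export
setMethod("stateLabels", "MatchedUptake", function(x) x@states)

#' @describeIn accessors the reference state label.
#' @export
setMethod("referenceState", "MatchedUptake", function(x) x@states[1])

#' @describeIn accessors shared exposure times in seconds.
#' @export
setMethod("exposureTimes", "MatchedUptake", function(x) x@timepoints)

#' @describeIn accessors 4-d array (peptide x state x timepoint x replicate)
#'   of uptake in Daltons.
#' @export
setMethod("uptakeArray", "MatchedUptake", function(x) x@uptake)

#' @describeIn accessors 4-d array of percent deuteration.
#' @export
setMethod("percentDArray", "MatchedUptake", function(x) x@percentD)

#' @describeIn accessors named integer, maximum replicate count per state.
#' @export
setMethod("replicateCounts", "MatchedUptake", function(x) {
  n <- apply(!is.na(x@uptake), 2, function(m) {
    counts <- apply(m, c(1, 2), sum)
    if (length(counts) == 0) 0L else max(counts)
  })
  stats::setNames(as.integer(n), x@states)
})

#' @describeIn accessors named integer, peptides dropped per state by the
#'   matching intersection.
#' @export
setMethod("droppedPeptides", "MatchedUptake", function(x) x@dropped)

setMethod("show", "MatchedUptake", function(object) {
  cat("MatchedUptake:", nrow(object@peptides), "peptides x",
      length(object@states), "states x",
      length(object@timepoints), "timepoints\n")
  cat("  reference: ", object@states[1], "\n")
  cat("  states:    ", paste(object@states, collapse = ", "), "\n")
  cat("  timepoints:", paste(object@timepoints, collapse = ", "), "s\n")
  cat("  replicates:", paste(replicateCounts(object), collapse = ", "), "\n")
  if (sum(object@dropped) > 0)
    cat("  dropped:   ", paste(sprintf("%s=%d", names(object@dropped),
                                       object@dropped), collapse = ", "), "\n")
})

# ---- HDXComparisonSet ----

#' @describeIn accessors data.frame of per-peptide, per-timepoint
#'   differential statistics. `deltaDa` is test minus reference (Da);
#'   `tested` is FALSE for cells with fewer than 2 replicates, which are
#'   kept for plotting but never flagged significant.
#' @export
setMethod("comparisonResults", "HDXComparisonSet", function(x) x@results)

#' @describeIn accessors data.frame of per-comparison pooled SDs and
#'   critical intervals (Da).
#' @export
setMethod("criticalIntervals", "HDXComparisonSet", function(x) x@intervals)

#' @describeIn accessors significance level of the hybrid test.
#' @export
setMethod("alphaLevel", "HDXComparisonSet", function(x) x@alpha)

#' @describeIn accessors state labels, reference first.
#' @export
setMethod("stateLabels", "HDXComparisonSet", function(x) x@states)

#' @describeIn accessors the reference state label.
#' @export
setMethod("referenceState", "HDXComparisonSet", function(x) x@states[1])

setMethod("show", "HDXComparisonSet", function(object) {
  r <- object@results
  cat("HDXComparisonSet:", length(unique(r$comparison)), "comparisons vs",
      shQuote(object@states[1]), "at alpha =", object@alpha, "\n")
  for (cmp in unique(r$comparison)) {
    sub <- r[r$comparison == cmp, ]
    ci <- object@intervals$ciDa[object@intervals$comparison == cmp]
    cat(sprintf("  %s: %d peptides x %d timepoints, CI = %.4g Da, %d significant cells\n",
                cmp, length(unique(paste(sub$sequence, sub$start, sub$end))),
                length(unique(sub$timepoint)), ci,
                sum(sub$significant, na.rm = TRUE)))
  }
})

# ---- PymolScript ----

#' @describeIn accessors character vector of PyMOL command lines.
#' @export
setMethod("scriptLines", "PymolScript", function(x) x@lines)

setMethod("show", "PymolScript", function(object) {
  cat("PymolScript (", object@mode, " mode, comparison ",
      shQuote(object@comparison), ", ", length(object@lines), " lines)\n",
      sep = "")
  utils::head(object@lines, 8) |> cat(sep = "\n")
  if (length(object@lines) > 8) cat("...\n")
})
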