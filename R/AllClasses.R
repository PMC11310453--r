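#' @import methods
NULL

#' HDXDataSet: validated peptide-level HDX-MS records
#'
#' Container for one parsed HDExaminer-style export: one row per peptide x
#' charge state x exposure time x replicate x protein state. Rows that failed
#' numeric parsing or violated record invariants are dropped at read time and
#' counted in `nSkipped`.
#'
#' @slot records data.frame with columns `state`, `sequence`, `start`, `end`,
#'   `charge`, `exposure`, `replicate`, `uptake`, `percentD`, `isFD`.
#'   Coordinates are 1-based and inclusive; `exposure` is in seconds;
#'   `uptake` is deuterium uptake in Daltons.
#' @slot nSkipped integer, number of input data rows dropped during parsing.
#' @slot dialect list, the [hdxDialect()] used to read the file.
#'
#' @seealso [readHDExaminer()], [matchPeptides()]
#' @export
setClass("HDXDataSet",
  slots = c(records = "data.frame", nSkipped = "integer", dialect = "list"))

setValidity("HDXDataSet", function(object) {
  req <- c("state", "sequence", "start", "end", "charge", "exposure",
           "replicate", "uptake", "percentD", "isFD")
  miss <- setdiff(req, names(object@records))
  if (length(miss) > 0)
    return(paste("records missing columns:", paste(miss, collapse = ", ")))
  r <- object@records
  if (nrow(r) > 0) {
    if (any(r$end < r$start)) return("end < start in records")
    if (any(nchar(r$sequence) != r$end - r$start + 1))
      return("sequence length does not match residue span")
    if (any(!is.na(r$uptake) & r$uptake < 0)) return("negative uptake")
    if (any(r$exposure < 0)) return("negative exposure")
    if (any(is.na(r$uptake) & is.na(r$percentD)))
      return("rows with neither uptake nor percent deuteration")
  }
  TRUE
})

#' MatchedUptake: peptides aligned across all protein states
#'
#' The intersection of peptides (sequence + residue span) observed in every
#' protein state at every shared exposure time, with replicate-level uptake
#' values organised as a 4-d array `peptide x state x timepoint x replicate`.
#' The first state is the reference for downstream comparisons. Cells may
#' hold unequal replicate counts; unused replicate positions are `NA`, but
#' every cell holds at least one value.
#'
#' @slot peptides data.frame (`sequence`, `start`, `end`), sorted by start
#'   then end.
#' @slot states character, state labels, reference first.
#' @slot timepoints numeric, sorted shared exposure times in seconds
#'   (may include 0; 0 s rows are kept for plotting, never tested).
#' @slot uptake 4-d numeric array of uptake in Daltons.
#' @slot percentD 4-d numeric array of percent deuteration.
#' @slot dropped named integer, per-state count of peptides excluded by the
#'   intersection.
#'
#' @seealso [matchPeptides()], [compareStates()], [reorderReference()]
#' @export
setClass("MatchedUptake",
  slots = c(peptides = "data.frame", states = "character",
            timepoints = "numeric", uptake = "array", percentD = "array",
            dropped = "integer"))

setValidity("MatchedUptake", function(object) {
  d <- dim(object@uptake)
  if (length(d) != 4) return("uptake must be a 4-d array")
  if (!identical(d, dim(object@percentD)))
    return("uptake and percentD dimensions differ")
  if (d[1] != nrow(object@peptides)) return("peptide dimension mismatch")
  if (d[2] != length(object@states)) return("state dimension mismatch")
  if (d[3] != length(object@timepoints)) return("timepoint dimension mismatch")
  if (length(object@states) < 1) return("no states")
  if (anyDuplicated(object@states)) return("duplicated state labels")
  if (is.unsorted(object@timepoints, strictly = TRUE))
    return("timepoints must be strictly increasing")
  if (d[1] > 0) {
    n <- apply(!is.na(object@uptake), c(1, 2, 3), sum)
    if (any(n == 0))
      return("matching must leave no empty (peptide, state, timepoint) cell")
  }
  TRUE
})

#' HDXComparisonSet: differential statistics versus the reference state
#'
#' Per-peptide, per-timepoint Welch's t-tests of each non-reference state
#' against the reference, together with one global critical interval per
#' comparison. A peptide is flagged significant at a timepoint only if it
#' passes both filters of the hybrid test: `p < alpha` and
#' `|deltaD| > criticalInterval`.
#'
#' @slot results data.frame, one row per (comparison, peptide, timepoint);
#'   see [comparisonResults()] for the column contract.
#' @slot intervals data.frame, one row per comparison with pooled SDs,
#'   replicate counts, degrees of freedom and the critical interval in Da.
#' @slot alpha numeric significance level of the hybrid test.
#' @slot states character, state labels with the reference first.
#'
#' @seealso [compareStates()], [significantPeptides()]
#' @export
setClass("HDXComparisonSet",
  slots = c(results = "data.frame", intervals = "data.frame",
            alpha = "numeric", states = "character"))

setValidity("HDXComparisonSet", function(object) {
  if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be a single value in (0, 1)")
  req <- c("comparison", "sequence", "start", "end", "timepoint",
           "meanRef", "meanTest", "deltaDa", "sdRef", "sdTest",
           "nRef", "nTest", "tStat", "df", "pValue", "ciDa",
           "tested", "significant")
  miss <- setdiff(req, names(object@results))
  if (length(miss) > 0)
    return(paste("results missing columns:", paste(miss, collapse = ", ")))
  p <- object@results$pValue
  if (any(!is.na(p) & (p < 0 | p > 1))) return("p-values outside [0, 1]")
  if (any(object@intervals$ciDa < 0)) return("negative critical interval")
  TRUE
})

#' PymolScript: residue-coloring commands for PyMOL
#'
#' A self-contained PyMOL command script (custom colors defined before use,
#' no `load` line, no absolute paths) coloring residues by differential-HDX
#' significance or by a Delta-D gradient.
#'
#' @slot lines character, the script lines.
#' @slot mode `"significant"` or `"gradient"`.
#' @slot comparison character, test-state label the script describes.
#' @slot timepoint numeric, exposure in seconds (NA for time-course summaries).
#'
#' @seealso [pymolScript()], [writePymolScript()]
#' @export
setClass("PymolScript",
  slots = c(lines = "character", mode = "character",
            comparison = "character", timepoint = "numeric"))

setValidity("PymolScript", function(object) {
  if (!object@mode %in% c("significant", "gradient"))
    return("mode must be 'significant' or 'gradient'")
  if (any(grepl("[^\x01-\x7F]", object@lines)))
    return("script lines must be ASCII")
  TRUE
})
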