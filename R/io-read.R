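#' Read an HDExaminer-style long-format HDX-MS export
#'
#' Parses a delimited text export (comma- or tab-separated, auto-sniffed)
#' with one row per peptide x charge state x exposure time x replicate x
#' protein state into a validated [HDXDataSet-class]. Exposure times are
#' normalised to seconds. Rows whose numeric fields cannot be parsed, or
#' that violate record invariants (end < start, sequence length mismatch,
#' negative uptake), are skipped and counted; the skip count is reported via
#' a message and available through [nSkipped()].
#'
#' If the export has no replicate column, replicates are enumerated in file
#' order within each (state, peptide, exposure) group. Non-numeric replicate
#' identifiers (e.g. raw-file names) are converted to indices per state.
#'
#' @param path path to the export file.
#' @param dialect an [hdxDialect()] describing headers, time unit, decimal
#'   separator and FD-control state labels.
#' @return An [HDXDataSet-class].
#' @examples
#' sim <- simulateHDXExport(hdxSimConfig(nStates = 2, nPeptides = 10, seed = 1),
#'                          path = tempfile(fileext = ".csv"))
#' ds <- readHDExaminer(sim$path)
#' ds
#' @export
readHDExaminer <- function(path, dialect = hdxDialect()) {
  if (!file.exists(path)) stop("cannot read input file: ", path)
  firstLine <- readLines(path, n = 1L)
  if (length(firstLine) == 0) stop("empty input file: ", path)
  sep <- if (lengths(regmatches(firstLine, gregexpr("\t", firstLine))) >
             lengths(regmatches(firstLine, gregexpr(",", firstLine)))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = TRUE,
                           stringsAsFactors = FALSE)
  cols <- resolveColumns(names(raw), dialect)
  required <- c("state", "sequence", "start", "end", "exposure")
  miss <- required[vapply(cols[required], is.na, logical(1))]
  if (length(miss) > 0)
    stop("export header does not resolve canonical column(s): ",
         paste(miss, collapse = ", "))
  if (is.na(cols$uptake) && is.na(cols$percentD))
    stop("export header resolves neither an uptake (#D) nor a percent ",
         "deuteration (%D) column")

  num <- function(x) {
    if (dialect$decimalSeparator != ".")
      x <- gsub(dialect$decimalSeparator, ".", x, fixed = TRUE)
    suppressWarnings(as.numeric(trimws(x)))
  }
  getcol <- function(field) if (is.na(cols[[field]])) NULL else raw[[cols[[field]]]]

  n <- nrow(raw)
  if (n == 0) stop("no data rows in input file: ", path)
  state <- trimws(getcol("state"))
  sequence <- toupper(trimws(getcol("sequence")))
  start <- num(getcol("start"))
  end <- num(getcol("end"))
  exposure <- parseExposure(getcol("exposure"), dialect$timeUnit)
  uptake <- if (is.null(getcol("uptake"))) rep(NA_real_, n) else num(getcol("uptake"))
  percentD <- if (is.null(getcol("percentD"))) rep(NA_real_, n) else num(getcol("percentD"))
  charge <- if (is.null(getcol("charge"))) rep(NA_integer_, n)
            else as.integer(num(getcol("charge")))

  ok <- !is.na(start) & !is.na(end) & !is.na(exposure) &
        !(is.na(uptake) & is.na(percentD)) &
        state != "" & sequence != "" &
        end >= start & nchar(sequence) == end - start + 1 &
        (is.na(uptake) | uptake >= 0) & exposure >= 0
  skipped <- sum(!ok)
  if (sum(ok) == 0) stop("no valid data rows in input file: ", path)

  repRaw <- getcol("replicate")
  if (is.null(repRaw)) {
    replicate <- rep(NA_integer_, n)
  } else {
    repNum <- num(repRaw)
    if (all(!is.na(repNum[ok]))) {
      replicate <- as.integer(repNum)
    } else {
      # raw-file names: index unique values within each state
      replicate <- as.integer(stats::ave(seq_len(n), state, FUN = function(i)
        match(repRaw[i], unique(repRaw[i]))))
    }
  }

  rec <- data.frame(state = state, sequence = sequence,
                    start = as.integer(start), end = as.integer(end),
                    charge = charge, exposure = exposure,
                    replicate = replicate, uptake = uptake,
                    percentD = percentD, stringsAsFactors = FALSE)[ok, ]
  rownames(rec) <- NULL
  # enumerate replicates in file order where no identifier was available
  noRep <- is.na(rec$replicate)
  if (any(noRep)) {
    grp <- paste(rec$state, rec$sequence, rec$start, rec$end, rec$exposure,
                 rec$charge, sep = "\r")
    rec$replicate[noRep] <- as.integer(
      stats::ave(seq_len(nrow(rec)), grp, FUN = seq_along))[noRep]
  }
  rec$isFD <- rec$state %in% dialect$fdStates
  if (skipped > 0)
    message("readHDExaminer: skipped ", skipped, " unparseable/invalid row(s)")
  methods::new("HDXDataSet", records = rec, nSkipped = as.integer(skipped),
               dialect = dialect)
}
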